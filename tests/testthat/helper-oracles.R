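# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: explicit double loops, normal equations, eigen instead of
# svd, and a naive agglomerative clusterer.

oracle_two_pass_variance <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

# two-way additive decomposition by explicit loops
oracle_two_way_ss <- function(m) {
  g <- nrow(m); n <- ncol(m)
  gmean <- sum(m) / (g * n)
  rmean <- sapply(seq_len(g), function(i) sum(m[i, ]) / n)
  cmean <- sapply(seq_len(n), function(j) sum(m[, j]) / g)
  ss_env <- 0; ss_gen <- 0; ss_ge <- 0
  for (j in seq_len(n)) ss_env <- ss_env + g * (cmean[j] - gmean)^2
  for (i in seq_len(g)) ss_gen <- ss_gen + n * (rmean[i] - gmean)^2
  for (i in seq_len(g)) for (j in seq_len(n))
    ss_ge <- ss_ge + (m[i, j] - rmean[i] - cmean[j] + gmean)^2
  list(env = ss_env, gen = ss_gen, ge = ss_ge, grand = gmean,
       rmean = rmean, cmean = cmean)
}

oracle_wricke <- function(m, i) {
  dec <- oracle_two_way_ss(m)
  s <- 0
  for (j in seq_len(ncol(m)))
    s <- s + (m[i, j] - dec$rmean[i] - dec$cmean[j] + dec$grand)^2
  s
}

oracle_shukla_classical <- function(m, i) {
  g <- nrow(m); n <- ncol(m)
  w <- sapply(seq_len(g), function(k) oracle_wricke(m, k))
  (g * (g - 1) * w[i] - sum(w)) / ((g - 1) * (g - 2) * (n - 1))
}

# least squares by normal equations
oracle_lstsq <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(b = beta[2], s2d = ss_res / (length(y) - 2),
       r2 = 1 - ss_res / ss_tot, fitted = drop(fitted))
}

# singular values / vectors via the eigen decomposition of Z'Z
oracle_svd <- function(z) {
  e <- eigen(t(z) %*% z, symmetric = TRUE)
  d <- sqrt(pmax(e$values, 0))
  v <- e$vectors
  u <- sapply(seq_along(d), function(k)
    if (d[k] > 1e-12) z %*% v[, k] / d[k] else rep(0, nrow(z)))
  list(d = d, u = u, v = v)
}

# naive O(n^3) agglomerative clustering, complete linkage, returning merge
# heights in order
oracle_complete_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  groups <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      h <- max(d[groups[[a]], groups[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  heights
}

# which-won-where oracle: the winner for an environment is the genotype
# maximizing the projection onto the environment's direction; equivalently
# scan directions at 0.1 degree resolution to map sectors
oracle_sector_winner <- function(gscores, env_point) {
  a <- atan2(env_point[2], env_point[1])
  dirv <- c(cos(a), sin(a))
  rownames(gscores)[which.max(gscores %*% dirv)]
}

random_met_matrix <- function(g, n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(g * n, mean = 7, sd = 1.2), g, n,
              dimnames = list(paste0("G", 1:g), paste0("E", 1:n)))
  met_matrix(m)
}

write_toy_long_csv <- function(path, dup = FALSE) {
  df <- expand.grid(genotype = c("A", "B"), environment = c("E1", "E2"),
                    stringsAsFactors = FALSE)
  df$block <- "B1"
  df$role <- "line"
  df$yield <- c(5.1, 6.2, 4.8, 7.3)
  if (dup) df <- rbind(df, df[1, ])
  write.csv(df[, c("environment", "genotype", "block", "role", "yield")],
            path, row.names = FALSE)
  path
}
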