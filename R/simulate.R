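#' Simulate an augmented-design multi-environment trial
#'
#' Draws a MET with known ground truth: additive genotype and environment
#' effects, an exact low-rank multiplicative genotype x environment
#' interaction with planted singular-value shares, replicated check
#' cultivars nested in blocks within environments, unreplicated test lines,
#' and i.i.d. Gaussian plot error. Every estimator in the package recovers
#' its planted parameter exactly at `sd_noise = 0`.
#'
#' Defaults emulate the augmented wheat-trial setting the package targets:
#' 4 environments, 4 check cultivars in quadruplicate, a grand mean near
#' 7 t/ha, environment effects dominating genotype effects, and a plot
#' error giving a trial CV near 11%.
#'
#' @param g_lines number of unreplicated test lines.
#' @param n_env number of environments.
#' @param n_checks number of replicated check cultivars.
#' @param reps_per_check check replicates (= blocks) per environment.
#' @param mu grand mean yield, t/ha.
#' @param sd_gen,sd_env SDs of the additive genotype / environment effects
#'   (t/ha); draws are exactly centered.
#' @param interaction_rank number of multiplicative interaction terms
#'   (0 = purely additive).
#' @param lambda_shares proportions of the interaction sum of squares per
#'   term (descending; default equal shares); must sum to 1.
#' @param sd_int root-mean-square interaction per interacting cell (t/ha).
#' @param sd_noise plot-error SD (t/ha).
#' @param planted_stable number of lines forced to zero interaction (the
#'   first `planted_stable` line labels); they are perfectly stable by
#'   construction.
#' @param stable_yield_bonus additive yield advantage (t/ha) given to the
#'   planted-stable lines, default 0.
#' @param check_interaction give checks interaction scores too (default
#'   `FALSE`: checks are stability references).
#' @param seed integer seed; same seed, same records.
#'
#' @return list of class `met_simulation`:
#'   \describe{
#'     \item{records}{`met_trial` plot data (lines once per cell, checks
#'       replicated in blocks).}
#'     \item{true_matrix}{noise-free cell-mean [met_matrix] (all
#'       genotypes).}
#'     \item{genotype_effects, environment_effects}{planted additive
#'       effects.}
#'     \item{lambda, genotype_vectors, environment_vectors,
#'       lambda_shares}{the planted multiplicative structure (orthonormal,
#'       centered, AMMI sign convention).}
#'     \item{stable_genotypes}{labels of planted-stable lines.}
#'   }
#'
#' @examples
#' sim <- simulate_met(g_lines = 10, n_env = 4, sd_noise = 0, seed = 1)
#' wricke_ecovalence(as_met_matrix(sim$records, keep_checks = FALSE))
#' @export
simulate_met <- function(g_lines = 30, n_env = 4, n_checks = 4,
                         reps_per_check = 4, mu = 7, sd_gen = 1.2,
                         sd_env = 1.5, interaction_rank = 2,
                         lambda_shares = NULL, sd_int = 0.6,
                         sd_noise = 0.8, planted_stable = 0,
                         stable_yield_bonus = 0,
                         check_interaction = FALSE, seed = NULL) {
  stopifnot(g_lines >= 2, n_env >= 2, n_checks >= 0, reps_per_check >= 1,
            sd_gen >= 0, sd_env >= 0, sd_int >= 0, sd_noise >= 0,
            planted_stable >= 0, planted_stable <= g_lines)
  if (!is.null(seed)) set.seed(seed)

  line_ids <- paste0("G", seq_len(g_lines))
  check_ids <- if (n_checks > 0) paste0("CHK", seq_len(n_checks)) else
    character(0)
  gl <- c(line_ids, check_ids)
  g <- length(gl)
  el <- paste0("E", seq_len(n_env))
  stable_ids <- if (planted_stable > 0) line_ids[seq_len(planted_stable)]
    else character(0)

  G <- stats::rnorm(g, 0, sd_gen); G <- G - mean(G)
  names(G) <- gl
  G[stable_ids] <- G[stable_ids] + stable_yield_bonus
  E <- stats::rnorm(n_env, 0, sd_env); E <- E - mean(E)
  names(E) <- el

  # exact low-rank interaction on the "active" genotypes only
  active <- if (check_interaction) setdiff(gl, stable_ids) else
    setdiff(line_ids, stable_ids)
  a <- length(active)
  r <- interaction_rank
  if (r > 0 && (r > a - 1L || r > n_env - 1L))
    stop("interaction_rank must be <= min(active genotypes - 1, n_env - 1) ",
         "= ", min(a - 1L, n_env - 1L), call. = FALSE)
  if (is.null(lambda_shares)) lambda_shares <- rep(1 / max(r, 1), max(r, 1))
  if (r > 0) {
    if (length(lambda_shares) != r)
      stop("lambda_shares must have length interaction_rank", call. = FALSE)
    if (abs(sum(lambda_shares) - 1) > 1e-8)
      stop("lambda_shares must sum to 1", call. = FALSE)
    lambda_shares <- sort(lambda_shares, decreasing = TRUE)
  }

  zmat <- matrix(0, g, n_env, dimnames = list(gl, el))
  lambda <- numeric(0)
  uu <- matrix(0, g, 0, dimnames = list(gl, NULL))
  vv <- matrix(0, n_env, 0, dimnames = list(el, NULL))
  if (r > 0 && sd_int > 0) {
    u0 <- matrix(stats::rnorm(a * r), a, r)
    u0 <- sweep(u0, 2L, colMeans(u0)) # orthogonal to the ones vector
    u0 <- qr.Q(qr(u0))
    v0 <- matrix(stats::rnorm(n_env * r), n_env, r)
    v0 <- sweep(v0, 2L, colMeans(v0))
    v0 <- qr.Q(qr(v0))
    # same deterministic sign convention as the AMMI decomposition
    for (k in seq_len(r)) {
      j <- which.max(abs(v0[, k]))
      if (v0[j, k] < 0) { v0[, k] <- -v0[, k]; u0[, k] <- -u0[, k] }
    }
    total_ss <- sd_int^2 * a * n_env
    lambda <- sqrt(lambda_shares * total_ss)
    uu <- matrix(0, g, r, dimnames = list(gl, NULL))
    uu[active, ] <- u0
    vv <- v0
    dimnames(vv) <- list(el, NULL)
    zmat <- uu %*% diag(lambda, r) %*% t(vv)
  }

  true_cells <- mu + outer(G, rep(1, n_env)) + outer(rep(1, g), E) + zmat
  dimnames(true_cells) <- list(gl, el)

  recs <- vector("list", n_env)
  for (j in seq_len(n_env)) {
    blocks <- paste0("B", seq_len(reps_per_check))
    line_block <- blocks[(seq_len(g_lines) - 1L) %% reps_per_check + 1L]
    env_rows <- data.frame(
      environment = el[j],
      genotype = c(line_ids, rep(check_ids, each = reps_per_check)),
      block = c(line_block, rep(blocks, times = n_checks)),
      role = c(rep("line", g_lines),
               rep("check", n_checks * reps_per_check)),
      stringsAsFactors = FALSE)
    env_rows$yield <- true_cells[cbind(env_rows$genotype, env_rows$environment)] +
      if (sd_noise > 0) stats::rnorm(nrow(env_rows), 0, sd_noise) else 0
    recs[[j]] <- env_rows
  }
  records <- do.call(rbind, recs)
  if (any(records$yield < 0)) {
    warning("negative plot yields truncated to 0 (", sum(records$yield < 0),
            " plot(s)); lower sd values or raise mu for exact recovery")
    records$yield <- pmax(records$yield, 0) # yields are physical quantities
  }
  class(records) <- c("met_trial", "data.frame")

  structure(list(records = records,
                 true_matrix = met_matrix(true_cells),
                 genotype_effects = G, environment_effects = E,
                 lambda = lambda, lambda_shares =
                   if (r > 0) lambda_shares else numeric(0),
                 genotype_vectors = uu, environment_vectors = vv,
                 stable_genotypes = stable_ids, mu = mu,
                 sd_noise = sd_noise, seed = seed),
            class = "met_simulation")
}

#' @export
print.met_simulation <- function(x, ...) {
  cat("Simulated MET:", nrow(x$true_matrix), "genotypes x",
      ncol(x$true_matrix), "environments,", nrow(x$records), "plots\n")
  cat("Interaction rank:", length(x$lambda),
      "| noise SD:", x$sd_noise, "t/ha\n")
  if (length(x$stable_genotypes))
    cat("Planted-stable:", paste(x$stable_genotypes, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a joint-regression (Finlay-Wilkinson) MET
#'
#' Generates X_ij = mean_i + b_i (E_j - Ebar) + noise with planted
#' per-genotype slopes. Slopes are rescaled to mean 1 (the slope on the
#' environmental index averages to 1 by construction, so only mean-1 slope
#' sets are realizable); at `sd_noise = 0`, [joint_regression()] recovers
#' every slope exactly.
#'
#' @param planted_slopes numeric vector of target slopes, one per genotype
#'   (mean rescaled to 1).
#' @param n_env number of environments.
#' @param mu grand mean, t/ha.
#' @param sd_gen SD of genotype mean deviations.
#' @param env_effects optional environment effects (centered); drawn
#'   Gaussian with SD `sd_env` otherwise.
#' @param sd_env SD of drawn environment effects.
#' @param sd_noise plot-error SD.
#' @param seed integer seed.
#' @return list of class `met_simulation_fw` with `records` (`met_trial`,
#'   all lines), `true_slopes` (the rescaled slopes), `genotype_means`,
#'   `environment_effects`.
#' @export
simulate_fw <- function(planted_slopes, n_env = 6, mu = 7, sd_gen = 1,
                        env_effects = NULL, sd_env = 1.5, sd_noise = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- length(planted_slopes)
  stopifnot(g >= 2, n_env >= 3)
  b <- planted_slopes / mean(planted_slopes)
  if (!is.null(env_effects)) {
    stopifnot(length(env_effects) == n_env)
    E <- env_effects - mean(env_effects)
  } else {
    E <- stats::rnorm(n_env, 0, sd_env); E <- E - mean(E)
  }
  if (all(E == 0)) stop("degenerate environment spread", call. = FALSE)
  G <- stats::rnorm(g, 0, sd_gen); G <- G - mean(G)
  gl <- paste0("G", seq_len(g)); el <- paste0("E", seq_len(n_env))
  names(G) <- gl; names(E) <- el; names(b) <- gl
  cells <- mu + outer(G, rep(1, n_env)) + outer(b, E)
  dimnames(cells) <- list(gl, el)
  obs <- cells + if (sd_noise > 0)
    matrix(stats::rnorm(g * n_env, 0, sd_noise), g, n_env) else 0
  records <- data.frame(
    environment = rep(el, each = g),
    genotype = rep(gl, times = n_env),
    block = "B1", role = "line",
    yield = as.vector(obs),
    stringsAsFactors = FALSE)
  if (any(records$yield < 0)) {
    warning("negative plot yields truncated to 0 (", sum(records$yield < 0),
            " plot(s))")
    records$yield <- pmax(records$yield, 0)
  }
  class(records) <- c("met_trial", "data.frame")
  structure(list(records = records, true_slopes = b,
                 genotype_means = mu + G, environment_effects = E,
                 sd_noise = sd_noise, seed = seed),
            class = "met_simulation_fw")
}
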