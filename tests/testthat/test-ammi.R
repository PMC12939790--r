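test_that("interaction SVD matches the eigen oracle and reconstructs Z", {
  m <- random_met_matrix(8, 4, seed = 19)
  fit <- ammi_decompose(m)
  z <- interaction_residuals(m)
  oc <- oracle_svd(z)
  kfull <- min(nrow(m) - 1, ncol(m) - 1)

  expect_equal(fit$singular_values, oc$d[1:kfull], tolerance = 1e-8)
  expect_equal(sum(fit$singular_values^2), sum(z^2), tolerance = 1e-10)
  # scores match the oracle up to the per-component sign convention
  for (k in 1:kfull) {
    gs <- fit$genotype_scores[, k] / sqrt(fit$singular_values[k])
    sgn <- sign(sum(gs * oc$u[, k]))
    expect_equal(unname(gs), sgn * oc$u[, k], tolerance = 1e-8)
  }
  # full-rank reconstruction reproduces Z
  recon <- fit$genotype_scores %*% t(fit$environment_scores)
  expect_equal(unname(recon), unname(z), tolerance = 1e-10)
  expect_equal(max(abs(fit$residual)), 0, tolerance = 1e-10)

  # truncated fit leaves the tail in the residual
  fit1 <- ammi_decompose(m, k_max = 1)
  expect_equal(sum(fit1$residual^2),
               sum(fit$singular_values[-1]^2), tolerance = 1e-8)
  expect_error(ammi_decompose(m, k_max = 10), "k_max")
})

test_that("score columns are centered and the sign convention is deterministic", {
  m <- random_met_matrix(7, 5, seed = 23)
  fit <- ammi_decompose(m)
  expect_equal(max(abs(colSums(fit$genotype_scores))), 0, tolerance = 1e-10)
  expect_equal(max(abs(colSums(fit$environment_scores))), 0,
               tolerance = 1e-10)
  for (k in seq_along(fit$singular_values)) {
    j <- which.max(abs(fit$environment_scores[, k]))
    expect_gt(fit$environment_scores[j, k], 0)
  }
  expect_equal(sum(fit$explained), 1, tolerance = 1e-10)

  # a rank-1 interaction is fully explained by the first component
  u <- c(1, -1, 0, 0); v <- c(1, 0, -1)
  base <- outer(c(5, 6, 7, 8), rep(1, 3)) + outer(rep(1, 4), c(0, 1, 2))
  m1 <- met_matrix(base + outer(u - mean(u), v - mean(v)))
  f1 <- ammi_decompose(m1)
  expect_equal(f1$explained[1], 1, tolerance = 1e-10)
})

test_that("combined ANOVA reproduces brute-force sums of squares and dfs", {
  sim <- simulate_met(g_lines = 9, n_env = 4, n_checks = 3,
                      reps_per_check = 3, sd_noise = 0.5, seed = 29)
  fit <- ammi(sim$records)
  an <- fit$anova
  m <- unclass(as_met_matrix(sim$records, keep_checks = FALSE))
  dec <- oracle_two_way_ss(m)
  g <- nrow(m); n <- ncol(m)

  row <- function(s) an[an$Source == s, ]
  expect_equal(row("Environment")$SS, dec$env, tolerance = 1e-8)
  expect_equal(row("Genotype")$SS, dec$gen, tolerance = 1e-8)
  expect_equal(row("Env:Gen")$SS, dec$ge, tolerance = 1e-8)
  expect_equal(row("Environment")$Df, n - 1)
  expect_equal(row("Genotype")$Df, g - 1)
  expect_equal(row("Env:Gen")$Df, (g - 1) * (n - 1))
  # Gollob df: g + n - 1 - 2k
  for (k in seq_along(fit$singular_values))
    expect_equal(row(paste0("PC", k))$Df, g + n - 1 - 2 * k)
  # component SS partition the interaction SS
  pcs <- an[grepl("^PC", an$Source), ]
  expect_equal(sum(pcs$SS), dec$ge, tolerance = 1e-8)
  expect_equal(pcs$Accumulated[nrow(pcs)], 100, tolerance = 1e-8)

  # F denominators: Env over Rep(Env) MS, everything else over residual MS
  ms_rep <- row("Replication(Env)")$MS
  ms_res <- row("Residuals")$MS
  expect_equal(row("Environment")$F, row("Environment")$MS / ms_rep,
               tolerance = 1e-10)
  expect_equal(row("Genotype")$F, row("Genotype")$MS / ms_res,
               tolerance = 1e-10)
  expect_equal(pcs$F, pcs$MS / ms_res, tolerance = 1e-10)
  expect_equal(attr(an, "cv_percent"), 100 * sqrt(ms_res) / dec$grand,
               tolerance = 1e-10)

  # replication stratum df derives from the block labels
  expect_equal(row("Replication(Env)")$Df, 4 * (3 - 1))
})

test_that("a zero-noise additive trial has zero interaction everywhere", {
  sim <- simulate_met(g_lines = 8, n_env = 4, interaction_rank = 0,
                      sd_noise = 0, seed = 31)
  # a perfect (zero-residual) check fit triggers the base-R unreliable-F
  # warning; the SS content is what matters here
  fit <- suppressWarnings(ammi(sim$records))
  expect_equal(fit$ss_ge, 0, tolerance = 1e-18)
  expect_equal(unname(fit$singular_values), rep(0, 3), tolerance = 1e-9)
  an <- fit$anova
  expect_equal(an[an$Source == "Env:Gen", "SS"], 0, tolerance = 1e-18)
  expect_equal(sum(an[grepl("^PC", an$Source), "SS"]), 0, tolerance = 1e-18)
})

test_that("IPCA distance identifies planted-stable genotypes", {
  sim <- simulate_met(g_lines = 10, n_env = 5, sd_noise = 0,
                      planted_stable = 1, seed = 37)
  fit <- ammi(as_met_matrix(sim$records, keep_checks = FALSE))
  d <- ipca_distance(fit, k = 2)
  expect_equal(unname(d["G1"]), 0, tolerance = 1e-10)
  expect_equal(names(which.min(d)), "G1")
  expect_error(ipca_distance(fit, k = 10), "exceeds")

  # cross-module consistency: W2 equals the squared row norm of the
  # full-rank multiplicative reconstruction of the interaction
  m <- as_met_matrix(sim$records, keep_checks = FALSE)
  z_recon <- fit$genotype_scores %*% t(fit$environment_scores)
  expect_equal(unname(rowSums(z_recon^2)), unname(wricke_ecovalence(m)),
               tolerance = 1e-8)
})

test_that("biplot coordinates carry means and centered scores", {
  sim <- simulate_met(g_lines = 8, n_env = 4, sd_noise = 0.3, seed = 41)
  fit <- ammi(sim$records)
  co <- ammi_biplot_coords(fit)
  expect_equal(sum(co$genotype$IPCA1), 0, tolerance = 1e-10)
  expect_equal(sum(co$genotype$IPCA2), 0, tolerance = 1e-10)
  expect_equal(co$genotype$mean,
               unname(fit$grand_mean + fit$genotype_effects))
  expect_equal(mean(co$genotype$mean), fit$grand_mean, tolerance = 1e-10)
})

test_that("an ANOVA without checks needs an external error MS", {
  m <- random_met_matrix(6, 4, seed = 43)
  fit <- ammi(m)
  expect_null(fit$anova)
  fit2 <- ammi(m, error_ms = 0.5, error_df = 12)
  expect_equal(fit2$anova[fit2$anova$Source == "Genotype", "F"],
               fit2$anova[fit2$anova$Source == "Genotype", "MS"] / 0.5,
               tolerance = 1e-10)
  recs_nocheck <- simulate_met(g_lines = 6, n_env = 4, n_checks = 0,
                               sd_noise = 0.2, seed = 47)$records
  expect_error(combined_anova(recs_nocheck), "no replicated check")
})
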