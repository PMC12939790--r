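test_that("environmental variance and CV match oracles and scale rules", {
  expect_equal(environmental_variance(c(3, 3, 3, 3)), 0)
  expect_equal(coefficient_of_variation(c(3, 3, 3, 3)), 0)
  expect_error(environmental_variance(5), ">= 2")
  expect_error(coefficient_of_variation(c(-1, -3)), "mean")

  set.seed(101)
  for (i in 1:5) {
    row <- rnorm(4, 7, 1.5)
    expect_equal(environmental_variance(row), oracle_two_pass_variance(row),
                 tolerance = 1e-12)
    expect_equal(coefficient_of_variation(row),
                 100 * sqrt(oracle_two_pass_variance(row)) / mean(row),
                 tolerance = 1e-12)
    # CV is invariant to positive rescaling
    expect_equal(coefficient_of_variation(3.7 * row),
                 coefficient_of_variation(row), tolerance = 1e-10)
  }
})

test_that("ecovalence is the per-genotype interaction SS", {
  m <- random_met_matrix(5, 4, seed = 7)
  w <- wricke_ecovalence(m)
  for (i in 1:5)
    expect_equal(unname(w[i]), oracle_wricke(unclass(m), i),
                 tolerance = 1e-12)
  expect_equal(sum(w), oracle_two_way_ss(unclass(m))$ge, tolerance = 1e-10)

  # a genotype tracking the environment means has zero ecovalence
  base <- unclass(random_met_matrix(4, 4, seed = 8))
  tracker <- colMeans(base) + 2
  m2 <- met_matrix(rbind(base, tracker))
  expect_equal(unname(wricke_ecovalence(m2)[5]), 0, tolerance = 1e-18)
  expect_error(wricke_ecovalence(m2, "nope"), "unknown genotype")
})

test_that("both Shukla estimators match their direct formulas", {
  m <- random_met_matrix(6, 4, seed = 13)
  w <- wricke_ecovalence(m)
  sp <- shukla_variance(m, mode = "scaled_ecovalence")
  sc <- shukla_variance(m, mode = "classical")
  n <- ncol(m)
  expect_equal(unname(sp), unname(w) / (n - 1), tolerance = 1e-12)
  for (i in 1:6)
    expect_equal(unname(sc[i]), oracle_shukla_classical(unclass(m), i),
                 tolerance = 1e-10)
  expect_error(shukla_variance(met_matrix(matrix(rnorm(8), 2, 4)),
                               mode = "classical"), ">= 3 genotypes")

  # purely additive matrix: zero interaction everywhere, both modes zero
  add <- outer(c(5, 6, 7, 8), rep(1, 4)) + outer(rep(1, 4), c(0, 1, 2, 3))
  expect_equal(unname(shukla_variance(met_matrix(add), mode = "scaled_ecovalence")),
               rep(0, 4), tolerance = 1e-18)
  expect_equal(unname(shukla_variance(met_matrix(add), mode = "classical")),
               rep(0, 4), tolerance = 1e-18)
})

test_that("joint regression matches the normal-equations oracle", {
  # tracking genotype: perfect unit-slope fit
  ei <- c(5, 6, 8, 9)
  fit <- joint_regression(ei + 2, ei)
  expect_equal(fit$b, 1)
  expect_equal(fit$s2d, 0, tolerance = 1e-24)
  expect_equal(fit$r2, 1)
  expect_equal(fit$fitted, ei + 2)

  set.seed(5)
  for (i in 1:5) {
    row <- rnorm(6, 7, 1)
    ei <- rnorm(6, 7, 1.5)
    fit <- joint_regression(row, ei)
    oc <- oracle_lstsq(row, ei)
    expect_equal(fit$b, oc$b, tolerance = 1e-10)
    expect_equal(fit$s2d, oc$s2d, tolerance = 1e-10)
    expect_equal(fit$r2, oc$r2, tolerance = 1e-10)
    expect_equal(fit$fitted, oc$fitted, tolerance = 1e-10)
  }

  expect_error(joint_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_error(joint_regression(c(1, 2, 3), c(4, 4, 4)), "constant")
  expect_warning(fitc <- joint_regression(c(2, 2, 2, 2), c(1, 2, 3, 4)),
                 "R2 undefined")
  expect_true(is.na(fitc$r2))
})

test_that("stability() table is internally consistent", {
  sim <- simulate_met(g_lines = 12, n_env = 5, sd_noise = 0.5, seed = 21)
  fit <- stability(sim$records)
  ind <- fit$indices
  n <- ncol(fit$matrix)

  expect_equal(ind$sd^2, ind$s2, tolerance = 1e-10)
  expect_equal(ind$cv, 100 * ind$sd / ind$mean, tolerance = 1e-10)
  # mean slope is exactly 1 because the regressor is the column-mean profile
  expect_equal(mean(ind$b), 1, tolerance = 1e-10)
  # R2 = 1 - (n-2) s2d / ((n-1) s2)
  expect_equal(ind$r2, 1 - (n - 2) * ind$s2d / ((n - 1) * ind$s2),
               tolerance = 1e-8)
  expect_equal(ind$sigma2_scaled, ind$w2 / (n - 1), tolerance = 1e-12)
})

test_that("all indices are invariant to permuting environments", {
  m <- random_met_matrix(8, 5, seed = 31)
  fit <- stability(m)
  perm <- c(3, 5, 1, 2, 4)
  mp <- met_matrix(unclass(m)[, perm])
  fitp <- stability(mp)
  expect_equal(fitp$indices, fit$indices, tolerance = 1e-10)
})

test_that("a planted additive genotype attains the minimum W2 and S2d", {
  sim <- simulate_met(g_lines = 10, n_env = 4, sd_noise = 0,
                      planted_stable = 1, seed = 9)
  fit <- stability(as_met_matrix(sim$records, keep_checks = FALSE))
  i <- match("G1", fit$indices$genotype)
  expect_equal(fit$indices$w2[i], min(fit$indices$w2), tolerance = 1e-12)
  expect_equal(fit$indices$s2d[i], min(fit$indices$s2d), tolerance = 1e-12)
  expect_lt(fit$indices$w2[i], 1e-18)
})

test_that("a single genotype is a degenerate but legal table", {
  fit <- stability(matrix(c(5, 6, 7, 8), 1, 4,
                          dimnames = list("G1", paste0("E", 1:4))))
  expect_equal(nrow(fit$indices), 1L)
  expect_equal(fit$indices$w2, 0, tolerance = 1e-24)
  expect_equal(fit$indices$b, 1)
  expect_equal(fit$sid$rsid, 1)
})
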