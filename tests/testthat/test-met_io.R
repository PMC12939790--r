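test_that("long CSV parsing returns one record per row and validates", {
  f <- write_toy_long_csv(tempfile(fileext = ".csv"))
  trial <- read_met_long(f)
  expect_s3_class(trial, "met_trial")
  expect_equal(nrow(trial), 4L)
  expect_setequal(trial$genotype, c("A", "B"))

  fdup <- write_toy_long_csv(tempfile(fileext = ".csv"), dup = TRUE)
  expect_error(read_met_long(fdup), "duplicated")

  # missing column named in the error
  df <- read.csv(f)
  df$yield <- NULL
  f2 <- tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(read_met_long(f2), "yield")

  # non-numeric yield reported with row position
  df <- read.csv(f)
  df$yield <- as.character(df$yield)
  df$yield[3] <- "oops"
  write.csv(df, f2, row.names = FALSE)
  expect_error(read_met_long(f2), "row.*3")
})

test_that("packaged mock trial has the documented augmented layout", {
  f <- system.file("extdata", "mock_met.csv", package = "metstab")
  trial <- read_met_long(f)
  expect_equal(nrow(trial), 30 * 4 + 4 * 4 * 4) # lines + checks x reps x envs
  expect_equal(length(unique(trial$environment)), 4L)
  expect_equal(sum(trial$role == "check"), 64L)
  m <- as_met_matrix(trial)
  expect_equal(dim(m), c(34L, 4L))
})

test_that("matrix assembly averages replicates and matches double-loop margins", {
  set.seed(42)
  # checks with 4 replicates per env -> cell = replicate mean
  recs <- met_trial(
    environment = rep(c("E1", "E2"), each = 4),
    genotype = "CHK1", block = rep(paste0("B", 1:4), 2),
    role = "check", yield = c(1, 2, 3, 4, 5, 6, 7, 8))
  recs2 <- rbind(recs, met_trial(rep(c("E1", "E2"), 2),
                                 rep(c("L1", "L2"), each = 2),
                                 "B1", "line", c(2, 3, 4, 5)))
  m <- as_met_matrix(recs2)
  expect_equal(unname(m["CHK1", c("E1", "E2")]), c(2.5, 6.5))

  # complete 3x3 line table reproduces its values and grand mean
  vals <- matrix(1:9, 3, 3)
  recs3 <- met_trial(rep(paste0("E", 1:3), each = 3),
                     rep(paste0("G", 1:3), 3), "B1", "line", as.vector(vals))
  m3 <- as_met_matrix(recs3)
  expect_equal(unname(unclass(m3)[cbind(paste0("G", 1:3), "E2")]),
               c(4, 5, 6))
  expect_equal(grand_mean(m3), mean(1:9))

  # random 10x4 record set: margins equal brute-force means
  g <- 10; n <- 4
  y <- rnorm(g * n, 7, 1)
  recs4 <- met_trial(rep(paste0("E", 1:n), each = g),
                     rep(paste0("G", 1:g), n), "B1", "line", y)
  m4 <- as_met_matrix(recs4)
  dec <- oracle_two_way_ss(unclass(m4))
  expect_equal(unname(genotype_means(m4)), dec$rmean, tolerance = 1e-12)
  expect_equal(unname(environmental_index(m4)), dec$cmean, tolerance = 1e-12)
  expect_equal(grand_mean(m4), dec$grand, tolerance = 1e-12)

  # permutation invariance in record order
  perm <- sample(nrow(recs4))
  m4p <- as_met_matrix(recs4[perm, ])
  expect_equal(unclass(m4)[rownames(m4), colnames(m4)],
               unclass(m4p)[rownames(m4), colnames(m4)])
})

test_that("margins are consistent and environmental index behaves", {
  m <- random_met_matrix(5, 4, seed = 11)
  expect_equal(mean(genotype_means(m)), grand_mean(m), tolerance = 1e-10)
  expect_equal(mean(environmental_index(m)), grand_mean(m),
               tolerance = 1e-10)

  # identical rows: index equals the common row
  row <- c(4, 6, 8, 5)
  mi <- met_matrix(matrix(rep(row, each = 3), 3, 4))
  expect_equal(unname(environmental_index(mi)), row)
})

test_that("missing cells follow the declared policy", {
  recs <- met_trial(rep(c("E1", "E2"), each = 2),
                    c("G1", "G2", "G1", "G2"), "B1", "line", c(5, 6, 7, 8))
  recs_missing <- recs[-4, ]
  expect_error(as_met_matrix(recs_missing), "empty cell.*G2.*E2")
  m <- as_met_matrix(recs_missing, missing_policy = "impute_env_mean")
  expect_equal(unname(unclass(m)["G2", "E2"]), 7) # env mean of observed G1
  expect_true(attr(m, "imputed")["G2", "E2"])
})

test_that("check adjustment subtracts the block check deviation", {
  recs <- met_trial(
    environment = rep("E1", 6),
    genotype = c("CHK1", "CHK1", "CHK2", "CHK2", "L1", "L2"),
    block = c("B1", "B2", "B1", "B2", "B1", "B2"),
    role = c(rep("check", 4), "line", "line"),
    yield = c(6, 4, 8, 6, 7, 7))
  recs2 <- rbind(recs, transform(recs, environment = "E2"))
  # env check mean = 6; block B1 check mean = 7 (dev +1), B2 = 5 (dev -1)
  m <- as_met_matrix(recs2, check_adjustment = TRUE)
  expect_equal(unname(unclass(m)["L1", "E1"]), 7 - 1)
  expect_equal(unname(unclass(m)["L2", "E1"]), 7 + 1)
})

test_that("wide matrix CSV round-trips bit-identically at written precision", {
  m <- random_met_matrix(6, 4, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_met_wide(m, f, digits = 6)
  m2 <- read_met_wide(f)
  expect_equal(unclass(m2)[, ], signif(unclass(m)[, ], 6),
               ignore_attr = TRUE)
  expect_identical(rownames(m2), rownames(m))
  # a second round trip is exact
  f2 <- tempfile(fileext = ".csv")
  write_met_wide(m2, f2, digits = 6)
  expect_identical(readLines(f), readLines(f2))
})

test_that("invalid containers are rejected", {
  expect_error(met_matrix(matrix(1:2, 1, 2)), "at least 2")
  expect_error(met_matrix(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
  expect_error(met_trial("E1", "G1", "B1", "line", -1), "negative")
  expect_error(met_trial("E1", "G1", "B1", "plot", 1), "role")
})
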