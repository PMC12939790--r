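#' Univariate stability indices
#'
#' The per-genotype indices computed from a genotype's yield profile across
#' environments. All use t/ha yields; "stable" means a small value except for
#' the regression slope b (stable ~ 1) and R-squared (large = well explained
#' by the environmental index).
#'
#' @param row numeric vector: one genotype's yields across the n
#'   environments.
#' @name univariate-indices
NULL

#' @describeIn univariate-indices environmental variance S2: the sample
#'   variance (n-1 divisor) of the genotype across environments.
#' @export
environmental_variance <- function(row) {
  row <- as.numeric(row)
  if (length(row) < 2L)
    stop("environmental variance needs >= 2 environments", call. = FALSE)
  sum((row - mean(row))^2) / (length(row) - 1L)
}

#' @describeIn univariate-indices coefficient of variation CV = 100 * S / mean
#'   (%), requires a positive mean.
#' @export
coefficient_of_variation <- function(row) {
  row <- as.numeric(row)
  m <- mean(row)
  if (!is.finite(m) || m <= 0)
    stop("CV undefined: genotype mean must be > 0, got ", m, call. = FALSE)
  100 * sqrt(environmental_variance(row)) / m
}

#' Wricke's ecovalence
#'
#' W2_i = sum_j (X_ij - Xbar_i - Xbar_j + Xbar)^2, genotype i's contribution
#' to the interaction sum of squares; summing over genotypes gives SS_GE
#' exactly. Lower = more stable.
#'
#' @param x a [met_matrix] (or plain matrix).
#' @param genotype optional label or index vector to subset; default all.
#' @return named non-negative vector.
#' @export
wricke_ecovalence <- function(x, genotype = NULL) {
  z <- if (inherits(x, "met_matrix")) interaction_residuals(x) else
    double_center(as.matrix(x))
  w <- rowSums(z^2)
  if (is.null(genotype)) return(w)
  if (is.character(genotype) && !all(genotype %in% names(w)))
    stop("unknown genotype(s): ",
         paste(setdiff(genotype, names(w)), collapse = ", "), call. = FALSE)
  w[genotype]
}

double_center <- function(m) {
  sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
}

#' Shukla's stability variance
#'
#' Two estimators are offered. `"scaled_ecovalence"` divides the ecovalence by
#' (n - 1), a simple per-environment scaling of the interaction residual sum
#' of squares. `"classical"` is Shukla's (1972) unbiased variance-component
#' estimator, sigma2_i = (g (g-1) W2_i - sum_m W2_m) / ((g-1) (g-2) (n-1)),
#' which can be negative for very stable genotypes and needs g >= 3.
#'
#' @inheritParams wricke_ecovalence
#' @param mode `"scaled_ecovalence"` (default) or `"classical"`.
#' @return named vector; non-negative for `scaled_ecovalence`.
#' @export
shukla_variance <- function(x, genotype = NULL,
                            mode = c("scaled_ecovalence", "classical")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "met_matrix")) unclass(x) else as.matrix(x)
  n <- ncol(m)
  g <- nrow(m)
  w <- wricke_ecovalence(x)
  s <- if (mode == "scaled_ecovalence") {
    w / (n - 1L)
  } else {
    if (g < 3L)
      stop("classical Shukla estimator needs >= 3 genotypes", call. = FALSE)
    (g * (g - 1L) * w - sum(w)) / ((g - 1L) * (g - 2L) * (n - 1L))
  }
  if (is.null(genotype)) s else s[genotype]
}

#' Finlay-Wilkinson joint regression of a genotype on the environmental index
#'
#' Least-squares regression of one genotype's yields on the environmental
#' index E_j (environment means). Returns the slope b, the Eberhart-Russell
#' deviation mean square S2d (residual SS / (n - 2)) and R-squared. The line
#' passes through (Ebar, Xbar_i), so fitted = Xbar_i + b (E_j - Ebar).
#'
#' @param row numeric length-n yield profile.
#' @param env_index numeric length-n environmental index (not constant).
#' @return list with `b`, `s2d`, `r2`, `fitted` (class
#'   `joint_regression`).
#' @export
joint_regression <- function(row, env_index) {
  row <- as.numeric(row); env_index <- as.numeric(env_index)
  n <- length(row)
  stopifnot(length(env_index) == n)
  if (n < 3L)
    stop("joint regression needs >= 3 environments (S2d divisor n - 2)",
         call. = FALSE)
  e <- env_index - mean(env_index)
  see <- sum(e^2)
  if (see == 0)
    stop("environmental index is constant: slope undefined", call. = FALSE)
  xc <- row - mean(row)
  b <- sum(xc * e) / see
  fitted <- mean(row) + b * e
  ss_res <- sum((row - fitted)^2)
  ss_tot <- sum(xc^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else {
    warning("constant yield profile: R2 undefined, reported NA")
    NA_real_
  }
  structure(list(b = b, s2d = ss_res / (n - 2L), r2 = r2, fitted = fitted),
            class = "joint_regression")
}

#' Fit the univariate stability table and SID aggregate for a trial
#'
#' The main univariate entry point: computes, for every genotype, the mean
#' yield and the eight stability indices (environmental variance S2, CV,
#' standard deviation, Wricke's ecovalence W2, Shukla's stability variance
#' in both modes, regression slope b, deviation from regression S2d, and
#' R-squared), then aggregates the seven stability indices into the SID
#' score -- the harmonic mean of the genotype's per-index ranks after
#' orienting each index by the sign of its correlation with mean yield --
#' and its rank RSID, with the four-quadrant yield-vs-rank classification.
#'
#' @param x a [met_matrix], a plain genotype x environment matrix, or a
#'   `met_trial` record frame (converted via [as_met_matrix()]).
#' @param shukla_mode which Shukla estimator feeds the SID ranking:
#'   `"scaled_ecovalence"` (default) or `"classical"`; both are reported.
#' @param sid_include_yield also feed a yield rank (rank 1 = highest mean
#'   yield) into the SID harmonic mean; default `FALSE`.
#' @param b_rank how the slope feeds the ranking: `"correlation"` (default:
#'   oriented by its empirical yield correlation like every other index) or
#'   `"closeness_to_one"` (rank 1 = slope nearest 1, the average-adaptability
#'   convention of joint-regression practice).
#' @param ... passed to [as_met_matrix()] when `x` is a record frame.
#'
#' @return object of class `met_stability` with components
#'   \describe{
#'     \item{indices}{data frame: genotype, mean, s2, cv, sd, w2,
#'       sigma2_scaled, sigma2_classical, b, s2d, r2.}
#'     \item{sid}{data frame: genotype, per-index ranks, sid, rsid,
#'       mean_rank, quadrant.}
#'     \item{orientation}{per-index orientation (as_is/inverted) and its
#'       yield correlation.}
#'     \item{matrix}{the fitted [met_matrix].}
#'   }
#'   with `print`, `summary`, `coef` and `plot` methods.
#'
#' @examples
#' sim <- simulate_met(g_lines = 12, n_env = 4, seed = 1)
#' fit <- stability(sim$records)
#' head(coef(fit))
#' summary(fit)
#' @export
stability <- function(x, shukla_mode = c("scaled_ecovalence", "classical"),
                      sid_include_yield = FALSE,
                      b_rank = c("correlation", "closeness_to_one"), ...) {
  shukla_mode <- match.arg(shukla_mode)
  b_rank <- match.arg(b_rank)
  if (inherits(x, "met_trial") ||
      (is.data.frame(x) && all(c("genotype", "environment", "yield") %in%
                               names(x))))
    x <- as_met_matrix(x, ...)
  if (!inherits(x, "met_matrix")) {
    xm <- as.matrix(x)
    storage.mode(xm) <- "double"
    if (is.null(rownames(xm))) rownames(xm) <- paste0("G", seq_len(nrow(xm)))
    # a single genotype is a legal (degenerate) stability table
    x <- if (nrow(xm) >= 2L) met_matrix(xm) else xm
  }
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  g <- nrow(m); n <- ncol(m)
  ei <- colMeans(m)

  w2 <- wricke_ecovalence(x)
  sig_p <- shukla_variance(x, mode = "scaled_ecovalence")
  sig_c <- if (g >= 3L) shukla_variance(x, mode = "classical") else
    rep(NA_real_, g)
  s2 <- apply(m, 1L, environmental_variance)
  means <- rowMeans(m)
  cv <- ifelse(means > 0, 100 * sqrt(s2) / means, NA_real_)
  if (anyNA(cv)) warning("CV undefined for genotype(s) with mean <= 0")

  fits <- apply(m, 1L, function(r)
    withCallingHandlers(joint_regression(r, ei),
                        warning = function(w) invokeRestart("muffleWarning")))
  b <- vapply(fits, `[[`, numeric(1), "b")
  s2d <- vapply(fits, `[[`, numeric(1), "s2d")
  r2 <- vapply(fits, `[[`, numeric(1), "r2")

  indices <- data.frame(
    genotype = rownames(m), mean = means, s2 = s2, cv = cv, sd = sqrt(s2),
    w2 = w2, sigma2_scaled = sig_p, sigma2_classical = sig_c,
    b = b, s2d = s2d, r2 = r2,
    row.names = NULL, stringsAsFactors = FALSE
  )

  sigma2_for_rank <- if (shukla_mode == "scaled_ecovalence") sig_p else sig_c
  b_for_rank <- if (b_rank == "closeness_to_one") abs(b - 1) else b
  index_cols <- cbind(s2 = s2, cv = cv, w2 = w2, sigma2 = sigma2_for_rank,
                      b = b_for_rank, s2d = s2d, r2 = r2)

  if (g >= 3L) {
    orientation <- orient_indices(index_cols, means)
    if (b_rank == "closeness_to_one") { # |b-1|: smaller is always better
      orientation$orientation[orientation$index == "b"] <- "inverted"
      orientation$index[orientation$index == "b"] <- "abs(b-1)"
    }
    ranks <- vapply(seq_len(ncol(index_cols)), function(j)
      rank_by_index(index_cols[, j], orientation$orientation[j]),
      numeric(g))
  } else {
    orientation <- data.frame(index = colnames(index_cols), r_yield = NA_real_,
                              orientation = "as_is",
                              stringsAsFactors = FALSE)
    ranks <- vapply(seq_len(ncol(index_cols)), function(j)
      rank_by_index(index_cols[, j], "as_is"),
      if (g == 1L) numeric(1) else numeric(g))
    ranks <- matrix(ranks, nrow = g)
  }
  colnames(ranks) <- colnames(index_cols)
  if (sid_include_yield) # rank 1 = highest mean yield, by definition
    ranks <- cbind(ranks, yield = rank(-means, ties.method = "average"))

  agg <- sid(ranks, yields = means, ranked = TRUE)
  agg$table <- cbind(data.frame(genotype = rownames(m),
                                stringsAsFactors = FALSE),
                     agg$table)
  rownames(agg$table) <- NULL

  structure(list(indices = indices, sid = agg$table,
                 orientation = orientation, matrix = x,
                 shukla_mode = shukla_mode, b_rank = b_rank,
                 sid_include_yield = sid_include_yield),
            class = "met_stability")
}

#' @export
print.met_stability <- function(x, digits = 4, ...) {
  cat("Univariate stability analysis:", nrow(x$indices), "genotypes x",
      ncol(x$matrix), "environments\n")
  cat("Shukla mode for ranking:", x$shukla_mode, "\n")
  best <- x$sid$genotype[x$sid$rsid == min(x$sid$rsid)]
  cat("Best RSID genotype(s):", paste(best, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.met_stability <- function(object, digits = 4, ...) {
  ord <- order(object$sid$rsid)
  out <- merge(object$indices[, c("genotype", "mean", "w2", "b", "s2d")],
               object$sid[, c("genotype", "sid", "rsid", "mean_rank",
                              "quadrant")],
               by = "genotype", sort = FALSE)[ord, ]
  rownames(out) <- NULL
  cat("Stability summary (ordered by RSID; quadrant A = above-mean yield,",
      "better-than-mean rank)\n")
  print(utils::head(cbind(out["genotype"],
                          round(out[, sapply(out, is.numeric)], digits),
                          out["quadrant"]), 12L))
  cat("\nIndex orientation (inverted = negative yield correlation):\n")
  print(object$orientation)
  invisible(out)
}

#' @export
coef.met_stability <- function(object, ...) {
  m <- as.matrix(object$indices[, -1])
  rownames(m) <- object$indices$genotype
  m
}

#' Yield-vs-rank quadrant plot
#'
#' Scatter of genotype mean yield against the aggregated stability rank,
#' split into four quadrants by the grand mean yield and the mean rank;
#' quadrant A (high yield, better-than-average rank) holds the genotypes
#' worth advancing.
#'
#' @param x a `met_stability` fit.
#' @param rank_axis `"rsid"` (default) or `"mean_rank"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.met_stability <- function(x, rank_axis = c("rsid", "mean_rank"), ...) {
  rank_axis <- match.arg(rank_axis)
  yld <- x$indices$mean
  rnk <- x$sid[[rank_axis]]
  graphics::plot(yld, rnk, xlab = "mean yield (t/ha)",
                 ylab = paste("aggregate stability rank (", rank_axis, ")"),
                 ...)
  graphics::abline(v = mean(yld), h = mean(rnk), lty = 2)
  graphics::text(yld, rnk, x$indices$genotype, pos = 3, cex = 0.6)
  invisible(x)
}
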