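#' Genotype-by-environment mean-yield matrix
#'
#' `met_matrix()` constructs the central data container of the package: a
#' complete genotype x environment matrix of mean yields (t/ha) together with
#' its margins -- genotype means, environment means (the environmental index)
#' and the grand mean. All stability statistics operate on this object.
#'
#' @param x numeric matrix, genotypes as rows, environments as columns.
#'   Dimnames are used as genotype/environment labels; unnamed dimensions get
#'   `G1..Gg` / `E1..En` labels in input order.
#' @param unit yield unit recorded as metadata (never converted), default
#'   `"t/ha"`.
#'
#' @return an object of class `met_matrix`: the numeric matrix with
#'   attributes `genotype_means`, `environment_means`, `grand_mean`, `unit`
#'   and (if cells were imputed) `imputed`, a logical matrix.
#'
#' @details A valid matrix has at least 2 genotypes and 2 environments and no
#'   missing cells; margins are always recomputed from the cell values, so
#'   they agree with arithmetic means to machine precision.
#'
#' @seealso [as_met_matrix()] to build one from plot records,
#'   [read_met_wide()] to read one from CSV, [environmental_index()].
#' @export
met_matrix <- function(x, unit = "t/ha") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("met_matrix needs at least 2 genotypes and 2 environments, got ",
         nrow(x), " x ", ncol(x), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop("met_matrix has ", nrow(bad), " missing/non-finite cell(s), e.g. (",
         paste(bad[1, ], collapse = ", "), "); use missing_policy = ",
         "\"impute_env_mean\" in as_met_matrix() or supply complete data",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("E", seq_len(ncol(x)))
  structure(
    x,
    genotype_means = rowMeans(x),
    environment_means = colMeans(x),
    grand_mean = mean(x),
    unit = unit,
    class = c("met_matrix", "matrix", "array")
  )
}

#' @export
print.met_matrix <- function(x, digits = 4, ...) {
  cat("Genotype x environment mean-yield matrix (", attr(x, "unit"), ")\n",
      sep = "")
  cat("  ", nrow(x), " genotypes x ", ncol(x), " environments, grand mean ",
      format(attr(x, "grand_mean"), digits = digits), "\n\n", sep = "")
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (nrow(m) > 10L) {
    print(round(m[1:10, , drop = FALSE], digits))
    cat("  ... ", nrow(m) - 10L, " more genotypes\n", sep = "")
  } else {
    print(round(m, digits))
  }
  invisible(x)
}

#' Environmental index
#'
#' The environmental index E_j is the mean yield of all genotypes in
#' environment j; it is the regressor of Finlay-Wilkinson joint regression.
#' Its mean equals the grand mean for a complete matrix.
#'
#' @param x a [met_matrix].
#' @return named numeric vector of length n (environments).
#' @export
environmental_index <- function(x) {
  stopifnot(inherits(x, "met_matrix"))
  attr(x, "environment_means")
}

#' @rdname met_matrix
#' @export
grand_mean <- function(x) {
  stopifnot(inherits(x, "met_matrix"))
  attr(x, "grand_mean")
}

#' @rdname met_matrix
#' @export
genotype_means <- function(x) {
  stopifnot(inherits(x, "met_matrix"))
  attr(x, "genotype_means")
}

#' Double-centered interaction residual
#'
#' Z_ij = X_ij - Xbar_i - Xbar_j + Xbar: the genotype-by-environment
#' interaction matrix after removing additive main effects. Its total sum of
#' squares is SS_GE; its per-genotype row sums of squares are Wricke's
#' ecovalences.
#'
#' @param x a [met_matrix].
#' @return plain numeric matrix of the same dimension.
#' @export
interaction_residuals <- function(x) {
  stopifnot(inherits(x, "met_matrix"))
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
}
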