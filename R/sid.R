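#' Orient stability indices by their correlation with yield
#'
#' Before ranking, each index is oriented so that rank 1 goes to the
#' genotypes the index associates with high yield: an index whose Pearson
#' correlation with mean yield is negative has its values inverted
#' (reciprocals) before ranking. Since the greatest oriented value ranks
#' first (see [rank_by_index()]), inversion means the SMALLEST raw value of
#' a negatively yield-correlated stability index -- e.g. the minimum
#' ecovalence -- receives rank 1.
#'
#' @param values matrix or data frame, one column per index, one row per
#'   genotype.
#' @param yields per-genotype mean yields (same row order).
#' @return data frame with columns `index`, `r_yield` (Pearson correlation
#'   with yield) and `orientation` (`"as_is"` or `"inverted"`).
#' @export
orient_indices <- function(values, yields) {
  values <- as.matrix(values)
  if (nrow(values) < 3L)
    stop("orientation needs >= 3 genotypes", call. = FALSE)
  stopifnot(length(yields) == nrow(values))
  r <- vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    ok <- is.finite(v) & is.finite(yields)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(yields[ok]) == 0) {
      warning("index '", colnames(values)[j],
              "' has no usable variance; oriented as_is")
      return(NA_real_)
    }
    stats::cor(v[ok], yields[ok])
  }, numeric(1))
  data.frame(index = colnames(values), r_yield = r,
             orientation = ifelse(!is.na(r) & r < 0, "inverted", "as_is"),
             stringsAsFactors = FALSE)
}

#' Rank genotypes by one (oriented) index
#'
#' The greater the oriented value, the lower (better) the rank: rank 1 goes
#' to the greatest value of an `as_is` index and -- via reciprocal
#' inversion -- to the smallest value of an `inverted` one. Inversion uses
#' reciprocals when all values are non-negative (rank of 1/x, a zero value
#' ranking first); for columns spanning zero, where 1/x is not monotone,
#' ascending ranks are used directly, which agree with the reciprocal ranks
#' on any positive column. Ties get average (fractional) ranks; missing
#' values keep `NA` ranks.
#'
#' @param values per-genotype index values.
#' @param orientation `"as_is"` or `"inverted"`.
#' @return numeric ranks.
#' @export
rank_by_index <- function(values, orientation = c("as_is", "inverted")) {
  orientation <- match.arg(orientation)
  v <- as.numeric(values)
  ok <- is.finite(v)
  key <- if (orientation == "inverted") {
    if (all(v[ok] >= 0)) -1 / v else v # greatest reciprocal ranks first
  } else {
    -v # greatest value ranks first
  }
  r <- rep(NA_real_, length(v))
  ok <- ok & !is.na(key)
  r[ok] <- rank(key[ok], ties.method = "average")
  r
}

#' SID: harmonic-mean rank aggregation of stability indices
#'
#' Aggregates a genotype's per-index stability ranks into a single score,
#' the harmonic mean of its ranks (SID); the genotypes are then re-ranked by
#' SID to give the final RSID. The harmonic mean rewards genotypes that are
#' top-ranked by at least some indices: it is always <= the arithmetic mean
#' rank, with equality only when all ranks agree.
#'
#' @param x either a matrix/data frame of raw index values (one column per
#'   index; requires `yields` for orientation) or a matrix of precomputed
#'   ranks (set `ranked = TRUE`).
#' @param yields per-genotype mean yields; used to orient the indices and to
#'   classify quadrants. Optional when `ranked = TRUE` (quadrants are then
#'   `NA` if absent).
#' @param ranked logical: `x` already holds ranks.
#' @return list with
#'   \describe{
#'     \item{table}{data frame: `rank_<index>` columns, `sid`, `rsid`,
#'       `mean_rank`, `quadrant`, `boundary` flag.}
#'     \item{orientation}{the [orient_indices()] frame (or `NULL`).}
#'   }
#' @examples
#' sid(cbind(a = c(2, 1, 3), b = c(4, 1, 3), c = c(4, 1, 3)),
#'     ranked = TRUE)$table
#' @export
sid <- function(x, yields = NULL, ranked = FALSE) {
  x <- as.matrix(x)
  orientation <- NULL
  if (ranked) {
    ranks <- x
    if (any(ranks <= 0, na.rm = TRUE))
      stop("ranks must be >= 1", call. = FALSE)
  } else {
    if (is.null(yields))
      stop("yields required to orient raw index values", call. = FALSE)
    orientation <- orient_indices(x, yields)
    ranks <- vapply(seq_len(ncol(x)), function(j)
      rank_by_index(x[, j], orientation$orientation[j]),
      numeric(nrow(x)))
    colnames(ranks) <- colnames(x)
  }
  if (is.null(colnames(ranks)))
    colnames(ranks) <- paste0("idx", seq_len(ncol(ranks)))

  k <- rowSums(is.finite(ranks))
  if (any(k == 0))
    stop("genotype(s) with no finite rank: ",
         paste(which(k == 0), collapse = ", "), call. = FALSE)
  sid_val <- k / rowSums(1 / ranks, na.rm = TRUE)
  mean_rank <- rowMeans(ranks, na.rm = TRUE)
  rsid <- rank(sid_val, ties.method = "average")

  tab <- data.frame(ranks, check.names = FALSE)
  names(tab) <- paste0("rank_", names(tab))
  tab$sid <- sid_val
  tab$rsid <- rsid
  tab$mean_rank <- mean_rank
  if (!is.null(yields)) {
    q <- quadrant_classify(yields, rsid)
    tab$quadrant <- q$quadrant
    tab$boundary <- q$boundary
  } else {
    tab$quadrant <- NA_character_
    tab$boundary <- NA
  }
  list(table = tab, orientation = orientation)
}

#' Four-quadrant classification of the yield-vs-rank plot
#'
#' Splits genotypes by the mean yield and the mean aggregate rank:
#' quadrant A = above-mean yield with better (smaller) than mean rank -- the
#' selection target; proceeding counter-clockwise, B = above-mean yield but
#' poor rank, C = below-mean yield and poor rank, D = below-mean yield but
#' good rank. Genotypes exactly on a boundary go to the favorable side
#' (high-yield / good-rank) and are flagged.
#'
#' @param yields per-genotype mean yields.
#' @param ranks per-genotype aggregate ranks (RSID or mean rank).
#' @return list of `quadrant` (factor A/B/C/D) and `boundary` (logical).
#' @export
quadrant_classify <- function(yields, ranks) {
  stopifnot(length(yields) == length(ranks))
  ym <- mean(yields); rm_ <- mean(ranks)
  high_yield <- yields >= ym
  good_rank <- ranks <= rm_
  q <- ifelse(high_yield & good_rank, "A",
       ifelse(high_yield & !good_rank, "B",
       ifelse(!high_yield & !good_rank, "C", "D")))
  list(quadrant = factor(q, levels = c("A", "B", "C", "D")),
       boundary = yields == ym | ranks == rm_)
}
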