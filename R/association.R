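#' Pearson correlation matrix among stability indices and yield
#'
#' Pairwise Pearson correlations over genotypes, with two-sided p-values
#' from the t transform t = r sqrt((m - 2) / (1 - r^2)) on m complete
#' pairs. Used to screen which indices agree with yield and with each
#' other. Holm-adjusted p-values are included alongside the raw ones.
#'
#' @param columns data frame or matrix of named per-genotype value vectors
#'   (typically `coef()` of a [stability()] fit, or a subset of its
#'   columns).
#' @return object of class `index_correlation`: list with `r`, `p`,
#'   `p_holm` (symmetric matrices) and `n_used` (complete pair counts).
#'   Zero-variance columns yield `NA` correlations for their pairs.
#'
#' @examples
#' fit <- stability(simulate_met(g_lines = 20, n_env = 5, seed = 2)$records)
#' pearson_matrix(fit$indices[, c("mean", "s2", "cv", "w2", "b", "s2d")])
#' @export
pearson_matrix <- function(columns) {
  m <- as.matrix(columns)
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("need >= 3 genotypes", call. = FALSE)
  p <- ncol(m)
  labs <- colnames(m)
  r <- pv <- nu <- matrix(NA_real_, p, p, dimnames = list(labs, labs))
  for (i in seq_len(p)) for (j in i:p) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    nij <- sum(ok)
    nu[i, j] <- nu[j, i] <- nij
    if (nij < 3L) next
    xi <- m[ok, i]; yj <- m[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
    rij <- sum((xi - mean(xi)) * (yj - mean(yj))) /
      (sqrt(sum((xi - mean(xi))^2)) * sqrt(sum((yj - mean(yj))^2)))
    r[i, j] <- r[j, i] <- rij
    pv[i, j] <- pv[j, i] <- if (i == j) 0 else {
      tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
      2 * stats::pt(abs(tt), nij - 2, lower.tail = FALSE)
    }
  }
  diag(r) <- ifelse(is.na(diag(r)), NA, 1)
  up <- upper.tri(pv)
  ph <- pv
  ph[up] <- stats::p.adjust(pv[up], method = "holm")
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  structure(list(r = r, p = pv, p_holm = ph, n_used = nu),
            class = "index_correlation")
}

#' @export
print.index_correlation <- function(x, digits = 2, ...) {
  cat("Pearson correlations (", nrow(x$r), " variables); * p<0.05, ",
      "** p<0.01, *** p<0.001 (unadjusted)\n", sep = "")
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        signif_code(ifelse(x$p == 0, NA, x$p))),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[x$p == 0 & !is.na(x$p)] <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Hierarchical clustering of a MET matrix axis
#'
#' Agglomerative clustering of the genotypes or the environments of the
#' yield matrix (raw t/ha values by default, matching a heatmap of
#' untransformed yields; optional z-scoring of the opposite axis).
#'
#' @param x a [met_matrix] or plain matrix.
#' @param axis `"environments"` (default) or `"genotypes"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @param distance distance measure passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param k optional number of flat clusters to cut.
#' @param standardize z-score the profiles across the clustered items
#'   before computing distances (default `FALSE`).
#' @return object of class `met_cluster`: the `hclust` tree plus `order`
#'   (leaf labels in dendrogram order), `flat` (named cluster labels when
#'   `k` given), `axis`, `linkage`, `distance`.
#' @export
met_cluster <- function(x, axis = c("environments", "genotypes"),
                        linkage = "ward.D2", distance = "euclidean",
                        k = NULL, standardize = FALSE) {
  axis <- match.arg(axis)
  m <- if (inherits(x, "met_matrix")) unclass(x) else as.matrix(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  items <- if (axis == "environments") t(m) else m
  if (nrow(items) < 2L)
    stop("need >= 2 items on the '", axis, "' axis", call. = FALSE)
  if (standardize) items <- scale(items)
  d <- stats::dist(items, method = distance)
  hc <- stats::hclust(d, method = linkage)
  # canonical leaf order (weighted by item means): invariant to input order
  dend <- stats::reorder(stats::as.dendrogram(hc), wts = rowMeans(items),
                         agglo.FUN = mean)
  flat <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, order = labels(dend), flat = flat,
                 axis = axis, linkage = linkage, distance = distance),
            class = "met_cluster")
}

#' @export
print.met_cluster <- function(x, ...) {
  cat("Hierarchical clustering of ", x$axis, " (", x$distance, " distance, ",
      x$linkage, " linkage)\n", sep = "")
  cat("Leaf order:", paste(x$order, collapse = ", "), "\n")
  if (!is.null(x$flat)) {
    cat("Flat clusters:\n")
    print(split(names(x$flat), x$flat))
  }
  invisible(x)
}

#' @export
plot.met_cluster <- function(x, ...) {
  plot(x$hclust, xlab = x$axis, sub = paste(x$distance, x$linkage), ...)
  invisible(x)
}

#' Two-way heatmap layout
#'
#' Permutes the yield matrix to the dendrogram leaf orders of a genotype
#' and an environment clustering and returns the ordered values together
#' with the merge trees, ready for plotting (no value transformation
#' unless the clusterings were standardized).
#'
#' @param x a [met_matrix] or plain matrix.
#' @param row_cluster a [met_cluster()] on `"genotypes"` (computed with
#'   defaults if missing).
#' @param col_cluster a [met_cluster()] on `"environments"` (computed with
#'   defaults if missing).
#' @return list with `values` (reordered matrix), `row_order`,
#'   `col_order`, and the two cluster objects.
#' @export
heatmap_layout <- function(x, row_cluster = NULL, col_cluster = NULL) {
  m <- if (inherits(x, "met_matrix")) unclass(x) else as.matrix(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (is.null(row_cluster)) row_cluster <- met_cluster(m, "genotypes")
  if (is.null(col_cluster)) col_cluster <- met_cluster(m, "environments")
  stopifnot(row_cluster$axis == "genotypes",
            col_cluster$axis == "environments")
  ro <- row_cluster$order
  co <- col_cluster$order
  list(values = m[ro, co, drop = FALSE], row_order = ro, col_order = co,
       row_cluster = row_cluster, col_cluster = col_cluster)
}
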