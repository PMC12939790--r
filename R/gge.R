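#' GGE: genotype plus genotype-by-environment analysis
#'
#' Singular value decomposition of the environment-centered yield matrix
#' C_ij = X_ij - Xbar_j, which retains the genotype main effect together
#' with the interaction (the two sources relevant to cultivar choice) and
#' removes the environment main effect. The first components are the axes
#' of the GGE biplot and of which-won-where sectoring.
#'
#' @param x a [met_matrix], plain matrix, or `met_trial` record frame
#'   (converted with `keep_checks = FALSE`... see `...`).
#' @param scaling `"none"` (default: centering only, the standard
#'   "centering = 2, scaling = 0" convention) or `"sd"` to divide each
#'   centered environment by its standard deviation.
#' @param ... passed to [as_met_matrix()] for record input.
#'
#' @return object of class `gge`: `singular_values`, symmetrically scaled
#'   `genotype_scores` / `environment_scores` (sign fixed as in [ammi()]),
#'   `explained`, `residual` (always the full-rank zero residual is omitted;
#'   the centered matrix is kept as `centered`), `ss_total`.
#'
#' @examples
#' sim <- simulate_met(g_lines = 12, n_env = 4, seed = 3)
#' fit <- gge(sim$records)
#' sum(fit$explained[1:2])
#' @export
gge <- function(x, scaling = c("none", "sd"), ...) {
  scaling <- match.arg(scaling)
  if (inherits(x, "met_trial") ||
      (is.data.frame(x) && all(c("genotype", "environment", "yield") %in%
                               names(x))))
    x <- as_met_matrix(x, ...)
  if (!inherits(x, "met_matrix")) x <- met_matrix(as.matrix(x))
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  cmat <- sweep(m, 2L, colMeans(m))
  if (scaling == "sd") {
    s <- apply(cmat, 2L, stats::sd)
    if (any(s == 0))
      stop("environment(s) with zero variance cannot be sd-scaled",
           call. = FALSE)
    cmat <- sweep(cmat, 2L, s, `/`)
  }
  kfull <- min(nrow(m) - 1L, ncol(m))
  sv <- svd(cmat)
  keep <- seq_len(kfull)
  lambda <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  for (k in keep) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  gs <- sweep(u, 2L, sqrt(lambda), `*`)
  es <- sweep(v, 2L, sqrt(lambda), `*`)
  dimnames(gs) <- list(rownames(m), paste0("PC", keep))
  dimnames(es) <- list(colnames(m), paste0("PC", keep))
  ss <- sum(cmat^2)
  structure(list(singular_values = lambda,
                 genotype_scores = gs, environment_scores = es,
                 explained = if (ss > 0) lambda^2 / ss else rep(0, kfull),
                 centered = cmat, ss_total = ss, scaling = scaling,
                 matrix = x),
            class = "gge")
}

#' @export
print.gge <- function(x, digits = 4, ...) {
  cat("GGE analysis:", nrow(x$genotype_scores), "genotypes x",
      nrow(x$environment_scores), "environments (scaling:", x$scaling, ")\n")
  cat("PC1 + PC2 explain",
      round(100 * sum(x$explained[seq_len(min(2, length(x$explained)))]), 1),
      "% of G + GxE variability\n")
  invisible(x)
}

#' Which-won-where sectoring of the GGE biplot
#'
#' Draws the convex hull of the genotype PC1-PC2 score cloud and the rays
#' from the origin perpendicular to each hull edge. The rays split the
#' plane into as many angular sectors as the hull has vertices; each sector
#' contains exactly one hull vertex, the genotype with the highest
#' projected performance for every environment direction inside that
#' sector ("the winner"). Environments are assigned to sectors by their
#' angular position; an environment exactly on a ray goes to the
#' counter-clockwise sector.
#'
#' @param fit a [gge()] fit.
#' @return object of class `gge_sectors`:
#'   \describe{
#'     \item{hull}{hull vertex labels, counter-clockwise.}
#'     \item{sector_count}{number of sectors (= hull vertices).}
#'     \item{rays}{data frame of boundary ray angles (radians, in
#'       (-pi, pi]) with the edge each is perpendicular to.}
#'     \item{sectors}{data frame: sector id, winner genotype, angular
#'       interval, environments inside, `empty` flag.}
#'     \item{environment_sector}{named sector id per environment.}
#'   }
#' @export
which_won_where <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  pts <- fit$genotype_scores[, 1:2, drop = FALSE]
  env <- fit$environment_scores[, 1:2, drop = FALSE]
  hull_idx <- grDevices::chull(pts) # clockwise
  if (length(hull_idx) < 3L) {
    warning("genotype scores are collinear: falling back to a 2-sector split")
    return(degenerate_sectors(pts, env, hull_idx))
  }
  hull_idx <- rev(hull_idx) # counter-clockwise
  h <- pts[hull_idx, , drop = FALSE]
  nh <- nrow(h)
  nxt <- c(2:nh, 1L)
  # outward normal of each CCW edge (v_i -> v_{i+1}): rotate edge by -90 deg
  edge <- h[nxt, , drop = FALSE] - h
  normal_angle <- atan2(-edge[, 1L], edge[, 2L])
  # vertex i's sector lies between the normals of its two adjacent edges:
  # incoming edge (i-1 -> i) and outgoing edge (i -> i+1)
  prev <- c(nh, seq_len(nh - 1L))
  lo <- normal_angle[prev]
  hi <- normal_angle
  winners <- rownames(h)

  env_angle <- atan2(env[, 2L], env[, 1L])
  in_arc <- function(a, lo, hi) {
    # CCW arc from lo to hi, half-open [lo, hi): an environment exactly on
    # a boundary ray belongs to the counter-clockwise sector
    w <- (a - lo) %% (2 * pi)
    span <- (hi - lo) %% (2 * pi)
    w >= 0 & w < span
  }
  env_sector <- vapply(env_angle, function(a) {
    which(in_arc(a, lo, hi))[1]
  }, numeric(1))
  names(env_sector) <- rownames(env)

  sectors <- data.frame(
    sector = seq_len(nh),
    winner = winners,
    from_angle = lo, to_angle = hi,
    environments = vapply(seq_len(nh), function(s)
      paste(rownames(env)[env_sector == s], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  sectors$empty <- sectors$environments == ""

  structure(list(hull = winners, sector_count = nh,
                 rays = data.frame(angle = normal_angle,
                                   edge_from = winners,
                                   edge_to = winners[nxt],
                                   stringsAsFactors = FALSE),
                 sectors = sectors,
                 environment_sector = env_sector),
            class = "gge_sectors")
}

degenerate_sectors <- function(pts, env, hull_idx) {
  dirv <- pts[hull_idx[1L], ] - pts[hull_idx[length(hull_idx)], ]
  if (all(dirv == 0)) dirv <- c(1, 0)
  dirv <- dirv / sqrt(sum(dirv^2))
  proj_g <- drop(pts %*% dirv)
  proj_e <- drop(env %*% dirv)
  winners <- c(rownames(pts)[which.max(proj_g)],
               rownames(pts)[which.min(proj_g)])
  env_sector <- ifelse(proj_e >= 0, 1L, 2L)
  names(env_sector) <- rownames(env)
  sectors <- data.frame(
    sector = 1:2, winner = winners,
    from_angle = NA_real_, to_angle = NA_real_,
    environments = vapply(1:2, function(s)
      paste(rownames(env)[env_sector == s], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  sectors$empty <- sectors$environments == ""
  structure(list(hull = rownames(pts)[hull_idx], sector_count = 2L,
                 rays = data.frame(angle = numeric(0),
                                   edge_from = character(0),
                                   edge_to = character(0)),
                 sectors = sectors, environment_sector = env_sector),
            class = "gge_sectors")
}

#' @export
print.gge_sectors <- function(x, ...) {
  cat("Which-won-where partition:", x$sector_count, "sectors, hull:",
      paste(x$hull, collapse = ", "), "\n")
  print(x$sectors[, c("sector", "winner", "environments", "empty")],
        row.names = FALSE)
  invisible(x)
}

#' Genotype-environment proximities in GGE biplot space
#'
#' Euclidean distances in the PC1-PC2 plane between every genotype and
#' environment marker, plus each marker's distance from the origin.
#' Genotypes with positive PC1 (above-average G + GxE performance across
#' the tested environments) and near-zero PC2 are flagged as broadly
#' favorable.
#'
#' @param fit a [gge()] fit with >= 2 components.
#' @return list with `dist` (g x n matrix), `genotype_origin`,
#'   `environment_origin` (named vectors) and `favorable` (genotype labels
#'   with PC1 > 0, ordered by |PC2|).
#' @export
environment_proximity <- function(fit) {
  stopifnot(inherits(fit, "gge"))
  if (ncol(fit$genotype_scores) < 2L)
    stop("need >= 2 components", call. = FALSE)
  gsc <- fit$genotype_scores[, 1:2, drop = FALSE]
  esc <- fit$environment_scores[, 1:2, drop = FALSE]
  d <- outer(seq_len(nrow(gsc)), seq_len(nrow(esc)),
             Vectorize(function(i, j) sqrt(sum((gsc[i, ] - esc[j, ])^2))))
  dimnames(d) <- list(rownames(gsc), rownames(esc))
  pos <- gsc[, 1L] > 0
  fav <- rownames(gsc)[pos][order(abs(gsc[pos, 2L]))]
  list(dist = d,
       genotype_origin = sqrt(rowSums(gsc^2)),
       environment_origin = sqrt(rowSums(esc^2)),
       favorable = fav)
}

#' GGE biplot with which-won-where overlay
#'
#' @param x a [gge()] fit.
#' @param sectors logical; draw the hull and sector rays.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gge <- function(x, sectors = TRUE, ...) {
  gsc <- x$genotype_scores[, 1:2, drop = FALSE]
  esc <- x$environment_scores[, 1:2, drop = FALSE]
  lim <- range(c(gsc, esc, 0))
  graphics::plot(gsc, xlim = lim, ylim = lim, xlab = "PC1", ylab = "PC2",
                 ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  graphics::arrows(0, 0, esc[, 1L], esc[, 2L], length = 0.08, col = 2)
  graphics::text(esc, rownames(esc), pos = 3, col = 2, cex = 0.7)
  if (sectors && nrow(gsc) >= 3L) {
    ww <- tryCatch(which_won_where(x), warning = function(w) NULL)
    if (!is.null(ww) && nrow(ww$rays)) {
      hpts <- gsc[ww$hull, , drop = FALSE]
      graphics::polygon(hpts, border = "grey50", lty = 2)
      r <- 2 * max(abs(lim))
      for (a in ww$rays$angle)
        graphics::segments(0, 0, r * cos(a), r * sin(a), col = "grey60")
    }
  }
  invisible(x)
}

#' @export
fitted.gge <- function(object, k = 2, ...) {
  object$genotype_scores[, seq_len(k), drop = FALSE] %*%
    t(object$environment_scores[, seq_len(k), drop = FALSE])
}

#' @export
residuals.gge <- function(object, k = 2, ...) {
  object$centered - fitted.gge(object, k = k)
}
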