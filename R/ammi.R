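#' AMMI: additive main effects and multiplicative interaction analysis
#'
#' Fits the AMMI model Y_ij = mu + G_i + E_j + sum_k lambda_k g_ik e_jk +
#' rho_ij to a multi-environment trial: a two-way additive decomposition of
#' the genotype x environment mean-yield matrix followed by a singular value
#' decomposition of the double-centered interaction residual. When plot-level
#' records with replicated checks are supplied, the combined analysis of
#' variance of the augmented design is computed as well: the replication
#' (within environment) stratum and the residual error are estimated from
#' the replicated check plots, environment / genotype / interaction sums of
#' squares from the unreplicated line cells.
#'
#' @param x a `met_trial` record frame (preferred: enables the combined
#'   ANOVA), or a [met_matrix] / plain matrix of cell means.
#' @param k_max number of multiplicative terms retained, default the full
#'   rank min(g - 1, n - 1).
#' @param error_ms optional externally supplied error mean square (with
#'   `error_df`) used for F tests when no replicated checks are available.
#' @param error_df degrees of freedom of `error_ms`.
#' @param ... passed to [as_met_matrix()] when `x` is a record frame
#'   (e.g. `check_adjustment`).
#'
#' @return object of class `ammi`:
#'   \describe{
#'     \item{grand_mean, genotype_effects, environment_effects}{the additive
#'       part; effects sum to zero.}
#'     \item{singular_values}{lambda_k, descending.}
#'     \item{genotype_scores, environment_scores}{symmetrically scaled
#'       scores (u sqrt(lambda), v sqrt(lambda)); each column sums to zero
#'       and the component sign is fixed so the largest-magnitude
#'       environment score is positive.}
#'     \item{explained}{lambda_k^2 / SS_GE.}
#'     \item{residual}{interaction left after `k_max` terms.}
#'     \item{anova}{the combined ANOVA table (or `NULL`).}
#'   }
#'
#' @examples
#' sim <- simulate_met(g_lines = 15, n_env = 4, seed = 7)
#' fit <- ammi(sim$records)
#' fit$explained
#' summary(fit)
#' @export
ammi <- function(x, k_max = NULL, error_ms = NULL, error_df = NULL, ...) {
  records <- NULL
  if (inherits(x, "met_trial") ||
      (is.data.frame(x) && all(c("genotype", "environment", "yield") %in%
                               names(x)))) {
    records <- validate_met_trial(as.data.frame(x))
    mat <- as_met_matrix(records, keep_checks = FALSE, ...)
  } else {
    mat <- if (inherits(x, "met_matrix")) x else met_matrix(as.matrix(x))
  }
  dec <- ammi_decompose(mat, k_max = k_max)
  an <- NULL
  if (!is.null(records) && any(records$role == "check")) {
    an <- combined_anova(records, decomposition = dec, ...)
  } else if (!is.null(error_ms)) {
    an <- anova_from_matrix(mat, dec, error_ms = error_ms,
                            error_df = error_df)
  }
  dec$anova <- an
  dec$matrix <- mat
  dec$call <- match.call()
  class(dec) <- "ammi"
  dec
}

#' Singular value decomposition of the double-centered interaction
#'
#' Core computation behind [ammi()], usable directly on a matrix of cell
#' means.
#'
#' @param x a [met_matrix] or plain matrix.
#' @param k_max components retained (default full rank min(g-1, n-1)).
#' @return list with the fields documented under [ammi()] (minus the ANOVA).
#' @export
ammi_decompose <- function(x, k_max = NULL) {
  if (!inherits(x, "met_matrix")) x <- met_matrix(as.matrix(x))
  m <- unclass(x)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  g <- nrow(m); n <- ncol(m)
  kfull <- min(g - 1L, n - 1L)
  if (is.null(k_max)) k_max <- kfull
  if (k_max < 1L || k_max > kfull)
    stop("k_max must be in 1..", kfull, call. = FALSE)

  z <- double_center(m)
  sv <- svd(z)
  keep <- seq_len(kfull)
  lambda <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest-|.| environment loading positive per component
  for (k in keep) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  gs <- sweep(u, 2L, sqrt(lambda), `*`)
  es <- sweep(v, 2L, sqrt(lambda), `*`)
  dimnames(gs) <- list(rownames(m), paste0("IPCA", keep))
  dimnames(es) <- list(colnames(m), paste0("IPCA", keep))
  ss_ge <- sum(z^2)
  recon <- gs[, seq_len(k_max), drop = FALSE] %*%
    t(es[, seq_len(k_max), drop = FALSE])

  list(grand_mean = mean(m),
       genotype_effects = rowMeans(m) - mean(m),
       environment_effects = colMeans(m) - mean(m),
       singular_values = lambda,
       genotype_scores = gs,
       environment_scores = es,
       explained = if (ss_ge > 0) lambda^2 / ss_ge else rep(0, kfull),
       k_max = k_max,
       residual = z - recon,
       ss_ge = ss_ge)
}

#' Combined analysis of variance for an augmented MET
#'
#' Environment, genotype and interaction sums of squares come from the
#' unreplicated line cells; the replication-within-environment stratum and
#' the residual error come from the replicated check plots (model:
#' environment + blocks within environment + check genotype + check x
#' environment). F ratios: environment over the replication MS; genotype,
#' interaction and each multiplicative component over the check residual
#' MS. Component degrees of freedom follow Gollob: g + n - 1 - 2k.
#'
#' @param records `met_trial` frame containing both lines and replicated
#'   checks.
#' @param decomposition optional precomputed [ammi_decompose()] result for
#'   the line matrix (recomputed otherwise).
#' @param ... passed to [as_met_matrix()].
#' @return data frame of class `ammi_anova` with columns Source, Df, SS, MS,
#'   F, p, signif, Accumulated; attribute `cv_percent` carries the trial
#'   coefficient of variation 100 sqrt(MS_error) / grand mean.
#' @export
combined_anova <- function(records, decomposition = NULL, ...) {
  records <- validate_met_trial(as.data.frame(records))
  checks <- records[records$role == "check", , drop = FALSE]
  if (!nrow(checks))
    stop("no replicated check records: the replication stratum and error ",
         "MS are not estimable; supply error_ms to ammi() instead",
         call. = FALSE)
  mat <- as_met_matrix(records, keep_checks = FALSE, ...)
  if (is.null(decomposition)) decomposition <- ammi_decompose(mat)

  m <- unclass(mat)
  g <- nrow(m); n <- ncol(m)
  gm <- mean(m)
  ss_env <- g * sum((colMeans(m) - gm)^2)
  ss_gen <- n * sum((rowMeans(m) - gm)^2)
  ss_ge <- decomposition$ss_ge

  # replication and error strata from the replicated checks
  checks$environment <- factor(checks$environment)
  checks$block <- factor(paste(checks$environment, checks$block, sep = ":"))
  checks$genotype <- factor(checks$genotype)
  fit <- stats::lm(yield ~ environment + environment:block + genotype +
                     environment:genotype, data = checks)
  at <- stats::anova(fit)
  rep_row <- match("environment:block", rownames(at))
  if (is.na(rep_row) || at$Df[rep_row] < 1L)
    stop("check blocks do not replicate within environments: ",
         "replication stratum not estimable", call. = FALSE)
  ss_rep <- at$`Sum Sq`[rep_row]; df_rep <- at$Df[rep_row]
  res_row <- match("Residuals", rownames(at))
  ss_res <- at$`Sum Sq`[res_row]; df_res <- at$Df[res_row]
  if (df_res < 1L)
    stop("check plots leave no residual degrees of freedom", call. = FALSE)
  ms_rep <- ss_rep / df_rep
  ms_res <- ss_res / df_res

  kfull <- length(decomposition$singular_values)
  df_pc <- g + n - 1L - 2L * seq_len(kfull) # Gollob
  ss_pc <- decomposition$singular_values^2

  src <- c("Environment", "Replication(Env)", "Genotype", "Env:Gen",
           paste0("PC", seq_len(kfull)), "Sum", "Residuals")
  df <- c(n - 1L, df_rep, g - 1L, (g - 1L) * (n - 1L), df_pc,
          (g - 1L) * (n - 1L), df_res)
  ss <- c(ss_env, ss_rep, ss_gen, ss_ge, ss_pc, ss_ge, ss_res)
  ms <- ss / df
  fval <- c(ms[1] / ms_rep, ms_rep / ms_res, ms[3] / ms_res, ms[4] / ms_res,
            ms_pc_f <- (ss_pc / df_pc) / ms_res, NA, NA)
  fden_df <- c(df_rep, df_res, df_res, df_res, rep(df_res, kfull), NA, NA)
  p <- stats::pf(fval, df, fden_df, lower.tail = FALSE)
  acc <- c(rep(NA, 4L),
           if (ss_ge > 0) 100 * cumsum(ss_pc) / ss_ge else rep(NA, kfull),
           100, NA)

  out <- data.frame(Source = src, Df = df, SS = ss, MS = ms, F = fval,
                    p = p, signif = signif_code(p), Accumulated = acc,
                    stringsAsFactors = FALSE)
  attr(out, "cv_percent") <- 100 * sqrt(ms_res) / gm
  class(out) <- c("ammi_anova", "data.frame")
  out
}

anova_from_matrix <- function(mat, decomposition, error_ms, error_df = NULL) {
  m <- unclass(mat)
  g <- nrow(m); n <- ncol(m); gm <- mean(m)
  kfull <- length(decomposition$singular_values)
  df_pc <- g + n - 1L - 2L * seq_len(kfull)
  ss_pc <- decomposition$singular_values^2
  ss_ge <- decomposition$ss_ge
  src <- c("Environment", "Genotype", "Env:Gen", paste0("PC", seq_len(kfull)))
  df <- c(n - 1L, g - 1L, (g - 1L) * (n - 1L), df_pc)
  ss <- c(g * sum((colMeans(m) - gm)^2), n * sum((rowMeans(m) - gm)^2),
          ss_ge, ss_pc)
  ms <- ss / df
  fval <- ms / error_ms
  p <- if (!is.null(error_df))
    stats::pf(fval, df, error_df, lower.tail = FALSE) else rep(NA_real_, length(df))
  acc <- c(NA, NA, NA,
           if (ss_ge > 0) 100 * cumsum(ss_pc) / ss_ge else rep(NA, kfull))
  out <- data.frame(Source = src, Df = df, SS = ss, MS = ms, F = fval, p = p,
                    signif = signif_code(p), Accumulated = acc,
                    stringsAsFactors = FALSE)
  attr(out, "cv_percent") <- 100 * sqrt(error_ms) / gm
  class(out) <- c("ammi_anova", "data.frame")
  out
}

signif_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.ammi_anova <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "cv_percent")))
    cat("Coefficient of Variation (%):",
        format(attr(x, "cv_percent"), digits = digits + 2), "\n")
  invisible(x)
}

#' Distance from the biplot origin in IPCA space
#'
#' The Euclidean norm of each genotype's first `k` scaled interaction
#' scores; small distances mean small interaction, i.e. AMMI-stable
#' genotypes. Ascending order is the AMMI stability order.
#'
#' @param fit an `ammi` fit (or [ammi_decompose()] result).
#' @param k components used, default 2.
#' @return named non-negative vector.
#' @export
ipca_distance <- function(fit, k = 2) {
  ks <- min(k, ncol(fit$genotype_scores))
  if (k > ncol(fit$genotype_scores))
    stop("k = ", k, " exceeds the ", ncol(fit$genotype_scores),
         " stored components", call. = FALSE)
  sqrt(rowSums(fit$genotype_scores[, seq_len(ks), drop = FALSE]^2))
}

#' Biplot coordinates of an AMMI fit
#'
#' @param fit an `ammi` fit with >= 2 components.
#' @return list of two data frames (`genotype`, `environment`) with columns
#'   `label`, `mean`, `IPCA1`, `IPCA2`.
#' @export
ammi_biplot_coords <- function(fit) {
  if (ncol(fit$genotype_scores) < 2L)
    stop("need >= 2 stored components for biplot coordinates", call. = FALSE)
  list(
    genotype = data.frame(
      label = rownames(fit$genotype_scores),
      mean = fit$grand_mean + fit$genotype_effects,
      IPCA1 = fit$genotype_scores[, 1L], IPCA2 = fit$genotype_scores[, 2L],
      row.names = NULL, stringsAsFactors = FALSE),
    environment = data.frame(
      label = rownames(fit$environment_scores),
      mean = fit$grand_mean + fit$environment_effects,
      IPCA1 = fit$environment_scores[, 1L],
      IPCA2 = fit$environment_scores[, 2L],
      row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' @export
print.ammi <- function(x, digits = 4, ...) {
  cat("AMMI analysis:", nrow(x$genotype_scores), "genotypes x",
      nrow(x$environment_scores), "environments\n")
  cat("Interaction SS:", format(x$ss_ge, digits = digits),
      "| explained by components:",
      paste0(round(100 * x$explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ammi <- function(object, digits = 4, k = 2, ...) {
  print(object, digits = digits)
  if (!is.null(object$anova)) {
    cat("\nCombined analysis of variance:\n")
    print(object$anova, digits = digits)
  }
  d <- sort(ipca_distance(object, min(k, ncol(object$genotype_scores))))
  cat("\nMost stable genotypes (smallest IPCA distance):\n")
  print(round(utils::head(d, 5L), digits))
  invisible(object)
}

#' AMMI biplots
#'
#' `type = "mean"` plots mean yield against IPCA1; `type = "ipca"` plots
#' IPCA1 against IPCA2. Genotypes as points, environments as labelled
#' arrows from the origin.
#'
#' @param x an `ammi` fit.
#' @param type `"mean"` or `"ipca"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ammi <- function(x, type = c("ipca", "mean"), ...) {
  type <- match.arg(type)
  co <- ammi_biplot_coords(x)
  if (type == "mean") {
    xs <- c(co$genotype$mean, co$environment$mean)
    ys <- c(co$genotype$IPCA1, co$environment$IPCA1)
    graphics::plot(co$genotype$mean, co$genotype$IPCA1,
                   xlim = range(xs), ylim = range(ys),
                   xlab = "mean yield (t/ha)", ylab = "IPCA1", ...)
    graphics::abline(h = 0, v = x$grand_mean, lty = 2)
    graphics::points(co$environment$mean, co$environment$IPCA1, pch = 17,
                     col = 2)
    graphics::text(co$environment$mean, co$environment$IPCA1,
                   co$environment$label, pos = 3, col = 2, cex = 0.7)
  } else {
    xs <- c(co$genotype$IPCA1, co$environment$IPCA1)
    ys <- c(co$genotype$IPCA2, co$environment$IPCA2)
    graphics::plot(co$genotype$IPCA1, co$genotype$IPCA2,
                   xlim = range(xs), ylim = range(ys),
                   xlab = "IPCA1", ylab = "IPCA2", ...)
    graphics::abline(h = 0, v = 0, lty = 2)
    graphics::arrows(0, 0, co$environment$IPCA1, co$environment$IPCA2,
                     length = 0.08, col = 2)
    graphics::text(co$environment$IPCA1, co$environment$IPCA2,
                   co$environment$label, pos = 3, col = 2, cex = 0.7)
  }
  invisible(x)
}

#' @export
fitted.ammi <- function(object, k = object$k_max, ...) {
  add <- object$grand_mean + outer(object$genotype_effects,
                                   rep(1, length(object$environment_effects))) +
    outer(rep(1, length(object$genotype_effects)),
          object$environment_effects)
  mult <- object$genotype_scores[, seq_len(k), drop = FALSE] %*%
    t(object$environment_scores[, seq_len(k), drop = FALSE])
  add + mult
}

#' @export
residuals.ammi <- function(object, ...) object$residual
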