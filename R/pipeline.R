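#' Run the full stability pipeline and write its outputs
#'
#' Executes the requested analysis steps in dependency order on a long- or
#' wide-format trial file (or an in-memory `met_trial` / [met_matrix]),
#' writing each module's tabular outputs plus a JSON run manifest to
#' `output_dir`. This is the programmatic core of the `met-stab` command
#' line script shipped under `inst/scripts/`.
#'
#' @param input path to a CSV (long plot records or wide matrix, see
#'   `format`), or a `met_trial` data frame, or a [met_matrix].
#' @param output_dir directory for outputs (created if needed).
#' @param steps subset of `c("univariate", "sid", "ammi", "gge", "corr",
#'   "cluster")`; the matrix conversion always runs first, `sid` implies
#'   `univariate`.
#' @param format `"long"` (default) or `"wide"` for file input.
#' @param shukla_mode,sid_include_yield,check_adjustment,missing_policy
#'   analysis options, see [stability()] and [as_met_matrix()].
#' @param linkage,distance clustering options, see [met_cluster()].
#' @param env_clusters flat environment clusters to cut (default 3).
#' @param seed integer seed set before any stochastic step.
#' @param digits significant digits in written tables (default 6).
#' @param verbose logical; log step progress to stderr.
#'
#' @return (invisibly) the manifest list; its `status` element is `"ok"`
#'   only if every requested step succeeded. The manifest is also written
#'   to `manifest.json` even when a step fails.
#' @export
run_pipeline <- function(input, output_dir,
                         steps = c("univariate", "sid", "ammi", "gge",
                                   "corr", "cluster"),
                         format = c("long", "wide"),
                         shukla_mode = c("scaled_ecovalence", "classical"),
                         sid_include_yield = FALSE,
                         check_adjustment = FALSE,
                         missing_policy = c("error", "impute_env_mean"),
                         linkage = "ward.D2", distance = "euclidean",
                         env_clusters = 3, seed = 1, digits = 6,
                         verbose = FALSE) {
  steps <- match.arg(steps, several.ok = TRUE)
  format <- match.arg(format)
  shukla_mode <- match.arg(shukla_mode)
  missing_policy <- match.arg(missing_policy)
  if ("sid" %in% steps) steps <- union(steps, "univariate")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  log_ <- function(...) if (verbose) message("[met-stab] ", ...)

  manifest <- list(
    tool = paste("metstab", as.character(utils::packageVersion("metstab"))),
    config = list(steps = steps, format = format, shukla_mode = shukla_mode,
                  sid_include_yield = sid_include_yield,
                  check_adjustment = check_adjustment,
                  missing_policy = missing_policy, linkage = linkage,
                  distance = distance, env_clusters = env_clusters,
                  seed = seed, digits = digits),
    input = if (is.character(input))
      list(path = input, md5 = unname(tools::md5sum(input))) else
      list(path = "<in-memory>", md5 = NA),
    steps = list(), outputs = character(0), warnings = character(0),
    status = "ok")
  outp <- function(name) file.path(output_dir, name)
  emit <- function(name) manifest$outputs <<- c(manifest$outputs, name)
  wr_csv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
    utils::write.csv(df, outp(name), row.names = FALSE)
    emit(name)
  }
  wr_json <- function(x, name) {
    jsonlite::write_json(x, outp(name), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    emit(name)
  }
  run_step <- function(name, fun) {
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$steps[[name]] <<- list(status = "error",
                                        message = conditionMessage(e))
        manifest$status <<- "error"
        log_(name, " FAILED: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      manifest$steps[[name]] <- list(status = "ok")
      log_(name, " ok")
    }
    res
  }

  # --- convert ---------------------------------------------------------
  records <- NULL
  mat <- run_step("convert", function() {
    if (inherits(input, "met_matrix")) return(input)
    if (is.data.frame(input)) {
      records <<- validate_met_trial(as.data.frame(input))
    } else if (format == "wide") {
      return(read_met_wide(input))
    } else {
      records <<- read_met_long(input)
    }
    as_met_matrix(records, check_adjustment = check_adjustment,
                  missing_policy = missing_policy)
  })
  if (is.null(mat)) {
    manifest$steps <- c(manifest$steps,
                        stats::setNames(lapply(steps, function(s)
                          list(status = "skipped")), steps))
    wr_json(manifest, "manifest.json")
    return(invisible(manifest))
  }
  write_met_wide(mat, outp("met_matrix.csv"), digits = digits)
  emit("met_matrix.csv")

  fit <- NULL
  if ("univariate" %in% steps) {
    fit <- run_step("univariate", function()
      stability(mat, shukla_mode = shukla_mode,
                sid_include_yield = sid_include_yield))
    if (!is.null(fit)) {
      ind <- fit$indices
      names(ind) <- c("genotype", "mean", "S2", "CV", "SD", "W2",
                      "sigma2_scaled", "sigma2_classical", "b", "S2d", "R2")
      wr_csv(ind, "univariate_indices.csv")
    }
  }
  if ("sid" %in% steps) {
    if (is.null(fit)) {
      manifest$steps[["sid"]] <- list(status = "skipped")
      manifest$status <- "error"
    } else {
      run_step("sid", function() {
        wr_csv(cbind(fit$sid,
                     orientation = paste(fit$orientation$index,
                                         fit$orientation$orientation,
                                         sep = "=", collapse = ";")),
               "sid_ranks.csv")
        wr_json(list(yield = fit$indices$mean, rsid = fit$sid$rsid,
                     mean_rank = fit$sid$mean_rank,
                     genotype = fit$sid$genotype,
                     boundaries = list(yield = mean(fit$indices$mean),
                                       rank = mean(fit$sid$rsid))),
                "rank_plot.json")
        TRUE
      })
    }
  }
  if ("ammi" %in% steps) {
    afit <- run_step("ammi", function()
      if (!is.null(records) && any(records$role == "check"))
        ammi(records, check_adjustment = check_adjustment,
             missing_policy = missing_policy) else ammi(mat))
    if (!is.null(afit)) {
      if (!is.null(afit$anova)) {
        an <- as.data.frame(afit$anova)
        an$CV_percent <- c(attr(afit$anova, "cv_percent"),
                           rep(NA, nrow(an) - 1L))
        wr_csv(an, "ammi_anova.csv")
      }
      wr_csv(data.frame(item = c(rownames(afit$genotype_scores),
                                 rownames(afit$environment_scores)),
                        kind = rep(c("genotype", "environment"),
                                   c(nrow(afit$genotype_scores),
                                     nrow(afit$environment_scores))),
                        rbind(afit$genotype_scores,
                              afit$environment_scores),
                        check.names = FALSE),
             "ammi_scores.csv")
      wr_json(ammi_biplot_coords(afit), "ammi_biplot.json")
    }
  }
  if ("gge" %in% steps) {
    gfit <- run_step("gge", function() gge(mat))
    if (!is.null(gfit)) {
      wr_csv(data.frame(item = c(rownames(gfit$genotype_scores),
                                 rownames(gfit$environment_scores)),
                        kind = rep(c("genotype", "environment"),
                                   c(nrow(gfit$genotype_scores),
                                     nrow(gfit$environment_scores))),
                        rbind(gfit$genotype_scores,
                              gfit$environment_scores),
                        check.names = FALSE),
             "gge_scores.csv")
      wr_csv(data.frame(component = seq_along(gfit$explained),
                        proportion = gfit$explained,
                        cumulative = cumsum(gfit$explained)),
             "gge_explained.csv")
      ww <- tryCatch(which_won_where(gfit), warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0("gge: ", conditionMessage(w)))
        suppressWarnings(which_won_where(gfit))
      })
      wr_json(list(hull = ww$hull, sector_count = ww$sector_count,
                   rays = ww$rays, sectors = ww$sectors,
                   environment_sector = as.list(ww$environment_sector)),
              "gge_sectors.json")
    }
  }
  if ("corr" %in% steps) {
    run_step("corr", function() {
      sfit <- if (!is.null(fit)) fit else
        stability(mat, shukla_mode = shukla_mode)
      cols <- sfit$indices[, c("mean", "s2", "cv", "w2", "sigma2_scaled",
                               "b", "s2d", "r2")]
      names(cols)[1] <- "yield"
      cm <- pearson_matrix(cols)
      wr_csv(data.frame(index = rownames(cm$r), cm$r, check.names = FALSE),
             "correlation_matrix.csv")
      wr_csv(data.frame(index = rownames(cm$p), cm$p, check.names = FALSE),
             "correlation_pvalues.csv")
      TRUE
    })
  }
  if ("cluster" %in% steps) {
    run_step("cluster", function() {
      ce <- met_cluster(mat, "environments", linkage = linkage,
                        distance = distance,
                        k = min(env_clusters, ncol(mat) - 1L))
      cg <- met_cluster(mat, "genotypes", linkage = linkage,
                        distance = distance)
      wr_json(dendrogram_json(ce$hclust), "cluster_environments.json")
      wr_json(dendrogram_json(cg$hclust), "cluster_genotypes.json")
      lay <- heatmap_layout(mat, cg, ce)
      wr_json(list(row_order = lay$row_order, col_order = lay$col_order,
                   values = apply(lay$values, 1L, as.numeric,
                                  simplify = FALSE)),
              "heatmap_layout.json")
      TRUE
    })
  }

  wr_json(manifest, "manifest.json")
  log_("done: ", manifest$status)
  invisible(manifest)
}

#' Nested-list (newick-like) serialization of an hclust tree
#'
#' @param hc an `hclust` object.
#' @return nested list of `list(height, children)` / `list(label)` nodes.
#' @export
dendrogram_json <- function(hc) {
  node <- function(i) {
    if (i < 0) return(list(label = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(node(hc$merge[i, 1L]), node(hc$merge[i, 2L])))
  }
  node(nrow(hc$merge))
}
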