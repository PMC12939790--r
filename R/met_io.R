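#' Read a long-format trial table
#'
#' Reads plot-level yield records of an augmented multi-environment trial:
#' one row per plot with environment, genotype, block, role (check or
#' unreplicated line) and grain yield. Unreplicated lines must appear at most
#' once per (genotype, environment); replicated checks may appear in several
#' blocks.
#'
#' @param path CSV file (RFC-4180, UTF-8). The header must name the five
#'   fields, case-insensitively; alternative column names can be supplied via
#'   `col_map`.
#' @param col_map named character vector mapping the canonical names
#'   `environment`, `genotype`, `block`, `role`, `yield` to the file's column
#'   names.
#' @param sep field separator, default `","`.
#'
#' @return a `met_trial` data frame with columns `environment`, `genotype`,
#'   `block`, `role` (factor with levels check/line) and `yield` (numeric,
#'   non-negative). Row order and label order are preserved from the file.
#'
#' @examples
#' f <- system.file("extdata", "mock_met.csv", package = "metstab")
#' trial <- read_met_long(f)
#' table(trial$role)
#' @export
read_met_long <- function(path,
                          col_map = c(environment = "environment",
                                      genotype = "genotype",
                                      block = "block",
                                      role = "role",
                                      yield = "yield"),
                          sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  canon <- c("environment", "genotype", "block", "role", "yield")
  map <- c(col_map)[canon]
  names(map) <- canon
  map[is.na(map)] <- canon[is.na(map)]
  missing_cols <- canon[!(tolower(map) %in% names(df))]
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(
    environment = as.character(df[[tolower(map[["environment"]])]]),
    genotype = as.character(df[[tolower(map[["genotype"]])]]),
    block = as.character(df[[tolower(map[["block"]])]]),
    role = tolower(as.character(df[[tolower(map[["role"]])]])),
    yield = suppressWarnings(as.numeric(df[[tolower(map[["yield"]])]])),
    stringsAsFactors = FALSE
  )
  validate_met_trial(out, source = path)
}

#' Assemble a trial-record data frame from vectors
#'
#' Programmatic counterpart of [read_met_long()]; applies the same
#' validation.
#'
#' @param environment,genotype,block,role,yield vectors of equal length; see
#'   [read_met_long()] for their meaning.
#' @return a validated `met_trial` data frame.
#' @export
met_trial <- function(environment, genotype, block, role, yield) {
  validate_met_trial(data.frame(
    environment = as.character(environment),
    genotype = as.character(genotype),
    block = as.character(block),
    role = tolower(as.character(role)),
    yield = as.numeric(yield),
    stringsAsFactors = FALSE
  ))
}

validate_met_trial <- function(out, source = "input") {
  bad_num <- which(is.na(out$yield))
  if (length(bad_num))
    stop("non-numeric or missing yield in ", source, " at row(s): ",
         paste(utils::head(bad_num, 5L), collapse = ", "),
         if (length(bad_num) > 5L) " ...", call. = FALSE)
  if (any(out$yield < 0))
    stop("negative yield(s) at row(s): ",
         paste(utils::head(which(out$yield < 0), 5L), collapse = ", "),
         call. = FALSE)
  if (!all(out$role %in% c("check", "line")))
    stop("role must be 'check' or 'line'; found: ",
         paste(unique(setdiff(out$role, c("check", "line"))), collapse = ", "),
         call. = FALSE)
  lines <- out[out$role == "line", ]
  key <- paste(lines$genotype, lines$environment, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicated (line, environment) record(s): ",
         paste(gsub("\r", " in ", utils::head(dup, 5L)), collapse = "; "),
         call. = FALSE)
  }
  class(out) <- c("met_trial", "data.frame")
  out
}

#' Build the genotype x environment matrix from trial records
#'
#' Cell values are the arithmetic means of all plots of a genotype in an
#' environment (so replicated checks are averaged over their blocks, lines
#' contribute their single plot). Optionally the unreplicated line values are
#' first block-adjusted using the replicated checks, the standard
#' augmented-design correction: adjusted value = value - (block check mean -
#' environment check mean).
#'
#' @param records a `met_trial` data frame from [read_met_long()] or
#'   [met_trial()].
#' @param check_adjustment logical; block-adjust line plots using check
#'   deviations (default `FALSE`, raw cell values).
#' @param missing_policy `"error"` (default) fails listing empty cells;
#'   `"impute_env_mean"` fills each empty cell with its environment mean over
#'   the observed genotypes and flags it in the `imputed` attribute.
#' @param keep_checks logical; include check genotypes as matrix rows
#'   (default `TRUE`).
#'
#' @return a [met_matrix]; genotype and environment order follow first
#'   appearance in `records`.
#' @export
as_met_matrix <- function(records, check_adjustment = FALSE,
                          missing_policy = c("error", "impute_env_mean"),
                          keep_checks = TRUE) {
  stopifnot(inherits(records, "data.frame"))
  missing_policy <- match.arg(missing_policy)
  records <- validate_met_trial(as.data.frame(records))

  if (check_adjustment) {
    checks <- records[records$role == "check", ]
    if (!nrow(checks))
      stop("check_adjustment = TRUE but no check records present",
           call. = FALSE)
    env_check_mean <- tapply(checks$yield, checks$environment, mean)
    blk_key <- paste(checks$environment, checks$block, sep = "\r")
    blk_check_mean <- tapply(checks$yield, blk_key, mean)
    is_line <- records$role == "line"
    rkey <- paste(records$environment, records$block, sep = "\r")
    adj <- blk_check_mean[rkey] - env_check_mean[records$environment]
    adj[is.na(adj)] <- 0 # line block without checks: no information, leave raw
    records$yield[is_line] <- records$yield[is_line] - adj[is_line]
  }

  keep <- if (keep_checks) rep(TRUE, nrow(records)) else records$role == "line"
  rec <- records[keep, , drop = FALSE]
  gl <- unique(rec$genotype)
  el <- unique(rec$environment)
  m <- matrix(NA_real_, length(gl), length(el), dimnames = list(gl, el))
  cell_key <- paste(rec$genotype, rec$environment, sep = "\r")
  means <- tapply(rec$yield, cell_key, mean)
  ij <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
  m[cbind(match(ij[, 1], gl), match(ij[, 2], el))] <- as.numeric(means)

  imputed <- is.na(m)
  if (any(imputed)) {
    if (missing_policy == "error") {
      empty <- which(imputed, arr.ind = TRUE)
      stop("empty cell(s): ",
           paste(utils::head(paste0("(", gl[empty[, 1]], ", ",
                                    el[empty[, 2]], ")"), 10L),
                 collapse = ", "),
           if (nrow(empty) > 10L) " ...",
           "; set missing_policy = \"impute_env_mean\" to impute",
           call. = FALSE)
    }
    env_mean <- colMeans(m, na.rm = TRUE)
    for (j in seq_along(el)) m[imputed[, j], j] <- env_mean[j]
  }
  out <- met_matrix(m)
  if (any(imputed)) attr(out, "imputed") <- imputed
  out
}

#' Read / write a wide genotype x environment matrix
#'
#' The wide CSV layout has genotype labels in column 1 and environment labels
#' in the header; cells are mean yields.
#'
#' @param path CSV file.
#' @return [read_met_wide()] returns a [met_matrix].
#' @export
read_met_wide <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("wide matrix needs a genotype column plus >= 2 environments",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  met_matrix(m)
}

#' @rdname read_met_wide
#' @param x a [met_matrix].
#' @param digits significant digits written (default 6).
#' @return [write_met_wide()] invisibly returns `path`.
#' @export
write_met_wide <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "met_matrix"))
  df <- data.frame(genotype = rownames(x),
                   signif(unclass(x)[, , drop = FALSE], digits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
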