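# Cohort file I/O and the end-to-end pipeline driver.
#
# File dialect: comma-separated, header row, UTF-8, "." decimal, empty
# string = missing.  Logical columns are written as TRUE/FALSE text.

#' Read a cohort from delimited text
#'
#' @param path CSV file (comma separator, header, empty string = missing).
#' @param column_map optional named character vector renaming site-specific
#'   headers to canonical names, as `c(canonical = "site_header", ...)`.
#' @return a data frame; columns that parse fully as numbers or TRUE/FALSE
#'   become numeric/logical.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src))
      stop("column_map references absent column(s): ",
           paste(missing_src, collapse = ", "))
    for (canonical in names(column_map))
      names(df)[names(df) == column_map[[canonical]]] <- canonical
  }
  df
}

#' Write a cohort as delimited text
#'
#' @param cohort a data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline over two or more sites
#'
#' Executes, per site: phenotyping (optional, for raw cohorts),
#' condition co-occurrence counts, and a penalized scan for every requested
#' (direction, rho) combination; then randomization significance for each
#' scan (when `K > 0`) and cross-site transfer of every discovered
#' description to every other site.  All randomness flows from named
#' sub-streams of `seed`, so a rerun with the same config is identical.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `sites` (named list of data frames or CSV paths), `phenotype`
#'   (logical, default `TRUE`), `creatinine_unit`, `outcome` (default
#'   `"mm"`), `features` (default: scan-feature columns), `n_bins`, `rho`
#'   (vector of penalties), `directions` (default `c("high", "low")`),
#'   `restarts`, `K` (replicas; 0 skips testing), `seed`, `out_dir`
#'   (optional: write result files there).
#' @return an object of class `mdscan_bundle`: `cohorts`, `cooccurrence`,
#'   `scans`, `tests`, `transfers`, `results` (discovery table),
#'   `transfer_results` (transfer table), `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(phenotype = TRUE, creatinine_unit = "mg/dL", outcome = "mm",
         features = NULL, n_bins = 10, rho = 1.5,
         directions = c("high", "low"), restarts = 10, K = 0, seed = 1,
         out_dir = NULL),
    config)
  if (is.null(cfg$sites) || length(cfg$sites) < 1L)
    stop("config$sites must name at least one cohort")
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  cohorts <- lapply(names(cfg$sites), function(s) {
    x <- cfg$sites[[s]]
    if (is.character(x)) x <- read_cohort(x)
    if (cfg$phenotype) {
      ph <- phenotype_cohort(x, creatinine_unit = cfg$creatinine_unit)
      note("site ", s, ": retained ", nrow(ph), "/", attr(ph, "n_raw"),
           " rows (", sprintf("%.1f%%", 100 * attr(ph, "retention")),
           "), mu = ", sprintf("%.4f", attr(ph, "mu")))
      ph
    } else x
  })
  names(cohorts) <- names(cfg$sites)

  cooc <- lapply(cohorts, function(ch)
    if (all(c("ht", "dm", "ckd", "cvd") %in% names(ch)))
      cooccurrence_counts(ch) else NULL)

  features <- cfg$features %||% intersect(names(default_feature_specs()),
                                          names(cohorts[[1L]]))
  if (length(features) == 0L) stop("no scan features available")
  fml <- stats::reformulate(features, cfg$outcome)

  scans <- list(); tests <- list(); transfers <- list()
  for (s in names(cohorts)) for (dir in cfg$directions) for (rho in cfg$rho) {
    key <- paste(s, dir, rho, sep = "/")
    fit <- mdscan(fml, cohorts[[s]], rho = rho, direction = dir,
                  n_bins = cfg$n_bins, restarts = cfg$restarts,
                  seed = substream_seed(cfg$seed, paste0("scan:", key)))
    scans[[key]] <- fit
    note("scan ", key, ": ", format(fit$description),
         sprintf(" (F_pen = %.3f, NL = %d)", fit$F_pen, fit$NL))
    if (cfg$K > 0)
      tests[[key]] <- mdscan_significance(fit, K = cfg$K,
        seed = substream_seed(cfg$seed, paste0("test:", key)))
    for (t in setdiff(names(cohorts), s))
      transfers[[paste(key, t, sep = "->")]] <-
        mdscan_transfer(fit, cohorts[[t]], source_site = s, target_site = t)
  }

  results <- do.call(rbind, lapply(names(scans), function(key) {
    f <- scans[[key]]; st <- f$stats
    data.frame(site = strsplit(key, "/")[[1L]][1L], direction = f$direction,
               rho = f$rho, NL = f$NL, description = format(f$description),
               F = f$F, F_pen = f$F_pen,
               OR = st$or, P_S = st$p_s, P_MM_S = st$p_mm_given_s,
               P_S_MM = st$p_s_given_mm,
               p_value = if (!is.null(tests[[key]])) tests[[key]]$p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  transfer_results <- if (length(transfers)) do.call(rbind, lapply(
    names(transfers), function(key) {
      tr <- transfers[[key]]; st <- tr$stats
      data.frame(transfer = key, NL = count_literals(tr$description),
                 description = format(tr$description), OR = tr$or,
                 ci_low = tr$ci_low, ci_high = tr$ci_high,
                 P_S = st$p_s, P_MM_S = st$p_mm_given_s,
                 P_S_MM = st$p_s_given_mm, robust = tr$robust,
                 stringsAsFactors = FALSE)
    }))
  bundle <- structure(list(cohorts = cohorts, cooccurrence = cooc,
                           scans = scans, tests = tests,
                           transfers = transfers, results = results,
                           transfer_results = transfer_results,
                           config = cfg, log = log),
                      class = "mdscan_bundle")
  if (!is.null(cfg$out_dir)) write_results(bundle, cfg$out_dir)
  bundle
}

#' @export
print.mdscan_bundle <- function(x, ...) {
  cat("mdscan pipeline bundle:", length(x$cohorts), "site(s),",
      length(x$scans), "scan(s),", length(x$transfers), "transfer(s)\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Emits the discovery table (`results.csv`), the transfer table
#' (`transfer_results.csv`), per-site co-occurrence counts
#' (`cooccurrence.json`), per-scan JSON descriptions, and the run log.
#'
#' @param bundle an `mdscan_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mdscan_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$results, file.path(dir, "results.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(bundle$transfer_results))
    utils::write.csv(bundle$transfer_results,
                     file.path(dir, "transfer_results.csv"),
                     row.names = FALSE, na = "")
  writeLines(jsonlite::toJSON(bundle$cooccurrence, auto_unbox = TRUE),
             file.path(dir, "cooccurrence.json"))
  for (key in names(bundle$scans))
    scan_result_json(bundle$scans[[key]],
                     file.path(dir, paste0("scan_", gsub("[^A-Za-z0-9._-]", "_",
                                                         key), ".json")))
  writeLines(c(paste("seed:", bundle$config$seed), bundle$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
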