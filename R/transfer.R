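# Cross-cohort transferability: re-apply a discovered description verbatim
# at another site and test whether its odds ratio's 95% CI excludes 1.

#' Woolf confidence interval for an odds ratio
#'
#' The log-odds-ratio normal interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  If any cell is zero
#' the Haldane-Anscombe correction (0.5 added to every cell) is applied and
#' flagged.
#'
#' @param stats a [subset_stats()] object, or a numeric vector of the four
#'   cells `c(a, b, c, d)`.
#' @param level confidence level (default 0.95).
#' @return a list with `or`, `ci_low`, `ci_high`, `level`, `haldane`.
#' @examples
#' or_ci(c(33, 86, 139, 1519))   # OR ~ 4.19, CI ~ (2.71, 6.49)
#' @export
or_ci <- function(stats, level = 0.95) {
  if (inherits(stats, "subset_stats")) cells <- c(stats$a, stats$b, stats$c, stats$d)
  else cells <- as.numeric(stats)
  stopifnot(length(cells) == 4L, all(cells >= 0))
  haldane <- min(cells) == 0
  if (haldane) cells <- cells + 0.5
  if (min(cells) == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                level = level, haldane = haldane))
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       level = level, haldane = haldane)
}

#' Transfer a discovered subset description to a target cohort
#'
#' Applies the source-site description literal by literal on the raw
#' measurement scale to the target cohort (no re-binning), computes the 2x2
#' statistics there, and judges robustness: the transfer is robust when the
#' odds ratio's confidence interval excludes 1.0.
#'
#' @param object an `mdscan` fit (the source-site result) or an
#'   [mds_description()].
#' @param target the target cohort (phenotyped, with the outcome column).
#' @param level confidence level for the Woolf interval.
#' @param outcome outcome column name (taken from the fit if available).
#' @param source_site,target_site optional labels recorded in the result.
#' @return an object of class `mdscan_transfer`: `description`, `stats`
#'   (a [subset_stats()] on the target), `or`, `ci_low`, `ci_high`,
#'   `robust`, site labels.
#' @export
mdscan_transfer <- function(object, target, level = 0.95, outcome = NULL,
                            source_site = NULL, target_site = NULL) {
  if (inherits(object, "mdscan")) {
    description <- object$description
    outcome <- outcome %||% object$outcome
  } else {
    description <- object
    outcome <- outcome %||% "mm"
  }
  stopifnot(inherits(description, "mds_description"))
  for (l in description$literals)
    if (!l$feature %in% names(target))
      stop("target cohort lacks feature '", l$feature, "'")
  st <- subset_stats(target, description, outcome = outcome)
  ci <- or_ci(st, level = level)
  robust <- !is.na(ci$ci_low) && (ci$ci_low > 1 || ci$ci_high < 1)
  if (!is.null(target) && !is.null(target$site) && is.null(target_site))
    target_site <- as.character(target$site[1L])
  structure(list(description = description, stats = st, or = ci$or,
                 ci_low = ci$ci_low, ci_high = ci$ci_high, level = level,
                 haldane = ci$haldane, robust = robust,
                 source_site = source_site, target_site = target_site),
            class = "mdscan_transfer")
}

#' @export
print.mdscan_transfer <- function(x, digits = 3, ...) {
  cat("Transfer of: ", format(x$description), "\n", sep = "")
  if (!is.null(x$source_site) || !is.null(x$target_site))
    cat("  ", x$source_site %||% "?", " -> ", x$target_site %||% "?", "\n", sep = "")
  cat(sprintf("  OR = %s, %d%% CI (%s, %s)%s\n",
              format(x$or, digits = digits + 1), round(100 * x$level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits),
              if (x$haldane) " [Haldane-corrected]" else ""))
  cat("  robust (CI excludes 1):", x$robust, "\n")
  invisible(x)
}
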