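#' Descriptive statistics of a subset description on a cohort
#'
#' Builds the 2x2 table of subset membership against the binary outcome and
#' reports the statistics used for discovered sub-populations:
#' the odds ratio `OR = (a*d)/(b*c)` (odds of the outcome inside the subset
#' over odds outside), the relative subset size `P(S)`, the outcome rate
#' within the subset `P(MM|S)`, and the share of all cases the subset
#' contains `P(S|MM)`.
#'
#' With an empty subset or empty complement the OR is undefined and reported
#' as `NA` alongside the cell counts.  If any single cell is zero the OR is
#' computed with the Haldane-Anscombe correction (0.5 added to every cell)
#' and flagged via the `haldane` field.
#'
#' @param data a data frame.
#' @param description an [mds_description()] (or an `mdscan` fit, whose
#'   description is used).
#' @param outcome name of the binary outcome column (default `"mm"`).
#' @return an object of class `subset_stats` with fields `n`, cells `a`
#'   (cases in S), `b` (non-cases in S), `c` (cases outside), `d` (non-cases
#'   outside), `or`, `p_s`, `p_mm_given_s`, `p_s_given_mm`, `haldane`.
#' @export
subset_stats <- function(data, description, outcome = "mm") {
  if (inherits(description, "mdscan")) description <- description$description
  stopifnot(inherits(description, "mds_description"))
  y <- as_binary_outcome(data[[outcome]], outcome)
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]; y <- y[keep]
  s <- subset_mask(data, description)
  cells_to_stats(a = sum(s & y), b = sum(s & !y),
                 c = sum(!s & y), d = sum(!s & !y))
}

cells_to_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  haldane <- FALSE
  or <- NA_real_
  if ((a + b) > 0 && (c + d) > 0) {
    if (min(a, b, c, d) == 0) {
      haldane <- TRUE
      or <- ((a + .5) * (d + .5)) / ((b + .5) * (c + .5))
    } else or <- (a * d) / (b * c)
  }
  structure(list(n = n, a = a, b = b, c = c, d = d, or = or,
                 p_s = (a + b) / n,
                 p_mm_given_s = if (a + b > 0) a / (a + b) else NA_real_,
                 p_s_given_mm = if (a + c > 0) a / (a + c) else NA_real_,
                 haldane = haldane),
            class = "subset_stats")
}

#' @export
print.subset_stats <- function(x, digits = 3, ...) {
  cat(sprintf("2x2 cells (a,b,c,d) = (%d, %d, %d, %d), n = %d\n",
              x$a, x$b, x$c, x$d, x$n))
  cat(sprintf("  OR = %s%s   P(S) = %.*f   P(MM|S) = %.*f   P(S|MM) = %.*f\n",
              if (is.na(x$or)) "undefined" else format(x$or, digits = digits + 1),
              if (x$haldane) " (Haldane-corrected)" else "",
              digits, x$p_s, digits, x$p_mm_given_s, digits, x$p_s_given_mm))
  invisible(x)
}

#' Reconstruct subset statistics from reported fractions
#'
#' Inverts the rounding of a published results row: from the cohort size,
#' the population outcome rate `mu`, the subset size fraction `P(S)` and the
#' within-subset outcome rate `P(MM|S)`, the integer 2x2 cells are recovered
#' by nearest-integer rounding of the expected cells, after which the OR and
#' `P(S|MM)` follow.  This is how printed odds ratios can be verified from
#' printed three-decimal fractions.
#'
#' @param n cohort size.
#' @param mu population outcome rate.
#' @param p_s subset size as a fraction of the cohort.
#' @param p_mm_given_s outcome rate within the subset.
#' @return a `subset_stats` object.
#' @examples
#' # published worked example: OR ~ 3.57 for a 2-literal high-risk subset
#' stats_from_fractions(1377, 0.164, 0.164, 0.345)$or
#' @export
stats_from_fractions <- function(n, mu, p_s, p_mm_given_s) {
  check_prob(mu, "mu"); check_prob(p_s, "p_s"); check_prob(p_mm_given_s, "p_mm_given_s")
  a <- round(p_mm_given_s * p_s * n)
  s_size <- round(p_s * n)
  mm_tot <- round(mu * n)
  b <- s_size - a
  c <- mm_tot - a
  d <- n - s_size - c
  if (min(a, b, c, d) < 0)
    stop_validation("inconsistent fractions: reconstructed cell is negative")
  cells_to_stats(a, b, c, d)
}

#' Venn region summaries for a set of subset descriptions
#'
#' Partitions the cohort into the cells of the membership indicator of up to
#' four descriptions (every non-empty combination of inside/outside), and
#' reports for each region its size, outcome fraction and, optionally, the
#' fraction of a reference level of a categorical feature (e.g. the share of
#' women).  The row with all-`FALSE` membership is the outside-all region.
#'
#' @param data a data frame.
#' @param descriptions a list of [mds_description()] (or `mdscan` fits).
#' @param outcome binary outcome column name.
#' @param female_feature,female_level optionally, a categorical column and
#'   level whose within-region fraction is reported (default `sex`/`Female`
#'   when present).
#' @return a data.frame with one row per non-empty region: logical membership
#'   columns, `count`, `outcome_frac`, and `level_frac` if requested.  Region
#'   counts always sum to `nrow(data)`.
#' @export
venn_regions <- function(data, descriptions, outcome = "mm",
                         female_feature = if ("sex" %in% names(data)) "sex",
                         female_level = "Female") {
  descriptions <- lapply(descriptions, function(d)
    if (inherits(d, "mdscan")) d$description else d)
  stopifnot(length(descriptions) >= 1L, length(descriptions) <= 4L)
  y <- as_binary_outcome(data[[outcome]], outcome)
  memb <- vapply(descriptions, function(d) subset_mask(data, d),
                 logical(nrow(data)))
  nm <- names(descriptions) %||% paste0("S", seq_along(descriptions))
  if (is.null(names(descriptions))) colnames(memb) <- nm else colnames(memb) <- nm
  key <- apply(memb, 1L, paste, collapse = "")
  out <- do.call(rbind, lapply(unique(key), function(kk) {
    rows <- key == kk
    rec <- as.data.frame(as.list(memb[which(rows)[1L], ]))
    rec$count <- sum(rows)
    rec$outcome_frac <- mean(y[rows], na.rm = TRUE)
    if (!is.null(female_feature))
      rec$level_frac <- mean(as.character(data[[female_feature]][rows]) ==
                               female_level, na.rm = TRUE)
    rec
  }))
  out[order(-out$count), , drop = FALSE]
}
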