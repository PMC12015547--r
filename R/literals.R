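#' Construct a single literal of a subset description
#'
#' A literal is an atomic constraint on one feature: a one-sided raw-scale
#' threshold (`">="` or `"<="`) or membership in a set of categorical levels
#' (`"in"`).  Subset descriptions are conjunctions of literals.
#'
#' @param feature column name the literal constrains.
#' @param relation one of `">="`, `"<="`, `"in"`.
#' @param value numeric threshold for threshold literals, or a non-empty
#'   character vector of levels for `"in"` literals.
#' @return an object of class `mds_literal`.
#' @examples
#' mds_literal("age", ">=", 53)
#' mds_literal("sex", "in", "Female")
#' @export
mds_literal <- function(feature, relation = c(">=", "<=", "in"), value) {
  relation <- match.arg(relation)
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature))
  if (relation == "in") {
    value <- as.character(value)
    if (length(value) == 0L) stop_validation("'in' literal needs at least one level")
  } else {
    if (!is.numeric(value) || length(value) != 1L || is.na(value))
      stop_validation("threshold literal needs a single numeric value")
  }
  structure(list(feature = feature, relation = relation, value = value),
            class = "mds_literal")
}

#' @export
format.mds_literal <- function(x, ...) {
  if (x$relation == "in") {
    lv <- if (length(x$value) == 1L) x$value else
      paste0("{", paste(x$value, collapse = ", "), "}")
    paste(x$feature, "is", lv)
  } else {
    paste(x$feature, x$relation, format(x$value, digits = 6, trim = TRUE))
  }
}

#' @export
print.mds_literal <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Construct a subset description (a conjunction of literals)
#'
#' The empty description denotes the whole population.  At most one literal
#' per (feature, relation side) is allowed; a `">="` and a `"<="` literal on
#' the same ordered feature form a two-sided interval and count as 2 literals.
#'
#' @param ... `mds_literal` objects (or a single list of them).
#' @return an object of class `mds_description`.
#' @examples
#' mds_description(mds_literal("age", ">=", 53),
#'                 mds_literal("waist_circumference", ">=", 950))
#' @export
mds_description <- function(...) {
  lits <- list(...)
  if (length(lits) == 1L && is.list(lits[[1L]]) && !inherits(lits[[1L]], "mds_literal"))
    lits <- lits[[1L]]
  for (l in lits)
    if (!inherits(l, "mds_literal")) stop_validation("all arguments must be mds_literal")
  key <- vapply(lits, function(l)
    paste(l$feature, if (l$relation == "in") "in" else l$relation), "")
  if (anyDuplicated(key))
    stop_validation("at most one literal per (feature, relation side)")
  structure(list(literals = lits), class = "mds_description")
}

#' Count the literals in a subset description
#'
#' One-sided threshold literals and categorical level-set literals each count
#' 1; a two-sided interval on one ordered feature counts 2 (it is stored as
#' two one-sided literals).  The empty description counts 0.
#'
#' @param description an `mds_description`.
#' @return integer literal count (the complexity `NL` penalized by `rho`).
#' @export
count_literals <- function(description) {
  stopifnot(inherits(description, "mds_description"))
  length(description$literals)
}

#' @export
format.mds_description <- function(x, ...) {
  if (length(x$literals) == 0L) return("<whole population>")
  paste(vapply(x$literals, format, ""), collapse = " & ")
}

#' @export
print.mds_description <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.mds_description <- function(x, ...) format(x)

#' Evaluate a subset description on a cohort, row by row
#'
#' Literals are evaluated on the raw measurement scale, so a description
#' discovered on one cohort can be re-applied verbatim to another without
#' re-binning.  A literal is a positive assertion: rows missing any restricted
#' feature are excluded from the subset.
#'
#' @param data a data frame containing the features the description references.
#' @param description an `mds_description` (the empty description selects all rows).
#' @return a logical vector with one element per row, no `NA`s.
#' @export
subset_mask <- function(data, description) {
  stopifnot(is.data.frame(data), inherits(description, "mds_description"))
  mask <- rep(TRUE, nrow(data))
  for (l in description$literals) {
    if (!l$feature %in% names(data))
      stop("feature '", l$feature, "' not present in the data")
    x <- data[[l$feature]]
    m <- switch(l$relation,
                ">=" = x >= l$value,
                "<=" = x <= l$value,
                "in" = as.character(x) %in% l$value)
    m[is.na(m)] <- FALSE
    mask <- mask & m
  }
  mask
}
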