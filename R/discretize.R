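#' Build a feature codebook for scanning
#'
#' Continuous (and ordinal) features are cut into at most `n_bins` left-closed
#' right-open quantile bins; categorical features pass through as their level
#' sets.  Bin edges are recorded on the raw measurement scale so that any
#' one-sided run of bins renders as a raw-scale threshold literal
#' (e.g. `waist_circumference >= 950`), and each edge also stores its
#' predecessor (the largest observed value strictly below it) so that `"<="`
#' literals select exactly the rows of the corresponding bin prefix even in
#' the presence of ties.
#'
#' Edges are order statistics (`x_(floor(j*n/k)+1)`), which makes bin
#' populations differ by at most one when values are distinct; duplicate edges
#' from heavily tied data are collapsed, so a feature with `d < n_bins`
#' distinct values gets at most `d` bins.  A constant feature yields a single
#' bin (and a warning): it can never be restricted.
#'
#' @param data a data frame (typically a phenotyped cohort).
#' @param features character vector of columns to include; defaults to every
#'   column except identifiers, outcome and condition flags.
#' @param n_bins maximum number of bins per ordered feature (>= 2); default 10.
#' @return an object of class `mds_codebook`: per feature a list with `kind`
#'   (`"ordered"` or `"categorical"`), and `edges`/`edge_prev` or `levels`.
#'   Every level set implicitly carries a "missing" pseudo-level (encoded 0).
#' @export
build_codebook <- function(data, features = NULL,
                           n_bins = 10) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (n_bins < 2) stop_validation("n_bins must be >= 2")
  default_drop <- c("id", "site", "mm", "ht", "dm", "ckd", "cvd")
  if (is.null(features)) features <- setdiff(names(data), default_drop)
  miss <- setdiff(features, names(data))
  if (length(miss)) stop("features not in data: ", paste(miss, collapse = ", "))
  book <- lapply(features, function(f) {
    x <- data[[f]]
    if (is.numeric(x)) {
      v <- sort(x[!is.na(x)])
      n <- length(v)
      if (n == 0L) stop("feature '", f, "' is entirely missing")
      idx <- floor(seq_len(n_bins - 1L) * n / n_bins) + 1L
      edges <- unique(v[idx])
      edges <- edges[edges > v[1L]]          # an edge at the minimum binds nothing
      if (length(edges) == 0L)
        warning("feature '", f, "' is constant (or nearly so): single bin")
      edge_prev <- vapply(edges, function(e) max(v[v < e]), 0)
      list(kind = "ordered", edges = edges, edge_prev = edge_prev)
    } else {
      lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x[!is.na(x)])))
      if (length(lv) == 0L) stop("feature '", f, "' is entirely missing")
      list(kind = "categorical", levels = lv)
    }
  })
  names(book) <- features
  structure(book, class = "mds_codebook")
}

#' @export
print.mds_codebook <- function(x, ...) {
  cat("Feature codebook:", length(x), "features\n")
  for (f in names(x)) {
    e <- x[[f]]
    if (e$kind == "ordered")
      cat(sprintf("  %s: %d bins (edges %s)\n", f, length(e$edges) + 1L,
                  paste(format(e$edges, digits = 4, trim = TRUE), collapse = ", ")))
    else
      cat(sprintf("  %s: levels %s\n", f, paste(e$levels, collapse = ", ")))
  }
  invisible(x)
}

#' Encode a cohort against a codebook
#'
#' Maps every cell to its level index (1-based; ordered bins are left-closed
#' right-open on the raw scale).  Missing cells map to the pseudo-level 0.
#' Values outside the codebook's range clamp to the extreme bin; categorical
#' levels unseen at codebook-build time map to the missing pseudo-level and
#' are counted in the `clamped`/`unseen` attributes.
#'
#' @param data a data frame with the codebook's features.
#' @param codebook an `mds_codebook` built on a compatible schema.
#' @return a list of class `mds_encoded`: `levels` (integer matrix, n x p,
#'   0 = missing), `k` (levels per feature), `kind`, `features`.
#' @export
encode_cohort <- function(data, codebook) {
  stopifnot(is.data.frame(data), inherits(codebook, "mds_codebook"))
  feats <- names(codebook)
  miss <- setdiff(feats, names(data))
  if (length(miss)) stop("data lacks codebook features: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  lev <- matrix(0L, n, length(feats), dimnames = list(NULL, feats))
  k <- integer(length(feats)); names(k) <- feats
  unseen <- 0L
  for (j in seq_along(feats)) {
    f <- feats[j]; e <- codebook[[f]]; x <- data[[f]]
    if (e$kind == "ordered") {
      k[j] <- length(e$edges) + 1L
      v <- findInterval(x, e$edges) + 1L      # left-closed on edges
      v[is.na(x)] <- 0L
      lev[, j] <- v
    } else {
      k[j] <- length(e$levels)
      v <- match(as.character(x), e$levels)
      unseen <- unseen + sum(!is.na(x) & is.na(v))
      v[is.na(v)] <- 0L
      lev[, j] <- v
    }
  }
  structure(list(levels = lev, k = k,
                 kind = vapply(codebook, `[[`, "", "kind"),
                 features = feats, unseen = unseen),
            class = "mds_encoded")
}

# Render the restriction of one feature (an internal search state) as
# raw-scale literals.  state: ordered -> c(lo, hi) bin bounds; categorical ->
# integer vector of included level indices; NULL -> unrestricted.
render_restriction <- function(feature, entry, state) {
  if (is.null(state)) return(list())
  lits <- list()
  if (entry$kind == "ordered") {
    lo <- state[1L]; hi <- state[2L]; kk <- length(entry$edges) + 1L
    if (lo > 1L) lits <- c(lits, list(mds_literal(feature, ">=", entry$edges[lo - 1L])))
    if (hi < kk) lits <- c(lits, list(mds_literal(feature, "<=", entry$edge_prev[hi])))
  } else {
    lits <- list(mds_literal(feature, "in", entry$levels[sort(state)]))
  }
  lits
}

# Full state -> mds_description (raw-scale literals, codebook order).
render_state <- function(state, codebook) {
  lits <- list()
  for (f in names(codebook))
    lits <- c(lits, render_restriction(f, codebook[[f]], state[[f]]))
  mds_description(lits)
}

# Encoded-level membership mask for a state (0 = missing is excluded by any
# restriction on that feature).
state_mask <- function(enc, state) {
  mask <- rep(TRUE, nrow(enc$levels))
  for (f in names(state)) {
    s <- state[[f]]
    if (is.null(s)) next
    v <- enc$levels[, f]
    if (enc$kind[[f]] == "ordered") {
      kk <- enc$k[[f]]
      if (s[1L] == 1L && s[2L] == kk) next
      mask <- mask & v >= s[1L] & v <= s[2L] & v > 0L
    } else {
      mask <- mask & v %in% s
    }
  }
  mask
}

state_nl <- function(enc, state) {
  nl <- 0L
  for (f in names(state)) {
    s <- state[[f]]
    if (is.null(s)) next
    if (enc$kind[[f]] == "ordered")
      nl <- nl + (s[1L] > 1L) + (s[2L] < enc$k[[f]])
    else
      nl <- nl + 1L
  }
  nl
}

#' Serialize / deserialize a codebook as JSON
#'
#' The JSON form lets a codebook built at one site be re-applied verbatim at
#' another.
#' @param codebook an `mds_codebook`.
#' @param path file to write (`codebook_to_json`) or read.
#' @return `codebook_to_json` invisibly returns the JSON string;
#'   `codebook_from_json` returns an `mds_codebook`.
#' @export
codebook_to_json <- function(codebook, path = NULL) {
  # 17 significant digits: doubles survive the text round trip bit-exactly
  js <- jsonlite::toJSON(unclass(codebook), auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname codebook_to_json
#' @export
codebook_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  book <- lapply(raw, function(e) {
    if (identical(e$kind, "ordered"))
      list(kind = "ordered", edges = as.numeric(e$edges),
           edge_prev = as.numeric(e$edge_prev))
    else list(kind = "categorical", levels = as.character(e$levels))
  })
  structure(book, class = "mds_codebook")
}
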