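#' Automatic stratification: penalized multidimensional subset scan
#'
#' Finds the conjunctive sub-population description `S*` maximizing the
#' penalized binomial likelihood-ratio score
#' `F_pen(S) = F(S) - rho * NL(S)` over all descriptions built from one-sided
#' raw-scale thresholds on ordered features and level sets on categorical
#' features.  `F(S)` compares the observed outcome count in `S` with its
#' expectation under the cohort-wide outcome rate (`B(S) = mu * |S|`, with
#' `mu` the observed mean of the outcome in `data`), and `NL(S)` is the number
#' of literals in the description.
#'
#' The maximization is an iterative ascent: starting from the whole
#' population (and, for later restarts, from random single-literal
#' descriptions), features are swept in seeded random order and each feature's
#' restriction is re-optimized exactly, conditioned on the others, among its
#' linearly many one-sided candidates (the ALTSS property guarantees the
#' optimal level subset of a categorical feature is a prefix of its levels
#' sorted by observed/expected ratio).  Sweeps repeat until a full pass gains
#' no more than `tol`; the best result over restarts is returned.  The
#' direction gate restricts the search to subsets with `C >= B` (`"high"`) or
#' `C <= B` (`"low"`): the score itself is a symmetric divergence, so
#' low-risk subsets are found by the same maximization with the gate
#' reversed, not by minimizing `F`.
#'
#' @param formula outcome ~ features, e.g. `mm ~ age + sex + bmi` or
#'   `mm ~ .`.  The outcome must be binary (logical or 0/1) with mean strictly
#'   inside (0, 1); features are used untransformed.
#' @param data a data frame (typically a phenotyped cohort).
#' @param rho non-negative complexity penalty per literal.  Larger values
#'   yield shorter descriptions; `rho = 0` is the unpenalized scan.
#' @param direction `"high"` for anomalously high outcome rates, `"low"` for
#'   anomalously low.
#' @param n_bins maximum quantile bins per ordered feature (default 10).
#' @param restarts number of ascent restarts (>= 1).  Restart 1 is the
#'   deterministic greedy ascent from the whole population; the rest start
#'   from seeded random single-literal descriptions.
#' @param seed master seed for restart randomization.
#' @param codebook optionally a pre-built [build_codebook()] object (e.g. to
#'   reuse one site's binning elsewhere); built from `data` if `NULL`.
#' @param forced an `mds_description` of literals held fixed throughout the
#'   search (e.g. constrain `sex is Female`); they are excluded from
#'   optimization but still counted in `NL`.  Thresholds must be codebook
#'   edges.
#' @param allow_intervals also consider two-sided intervals on ordered
#'   features (counted as 2 literals).  Off by default: one-sided thresholds
#'   are the canonical description language.
#' @param tol absolute convergence tolerance on `F_pen` (default 1e-9).
#' @return an object of class `mdscan`: the best `description`
#'   (an [mds_description()]), `F`, `F_pen`, `NL`, counts `C`, `B`, `N`,
#'   cohort size `n`, outcome mean `mu`, descriptive `stats`
#'   (a [subset_stats()] object), the `codebook`, and the configuration.
#' @examples
#' set.seed(1)
#' d <- data.frame(age = runif(400, 40, 60),
#'                 sex = sample(c("Female", "Male"), 400, TRUE))
#' risk <- ifelse(d$age >= 55 & d$sex == "Female", 0.6, 0.1)
#' d$mm <- rbinom(400, 1, risk) == 1
#' fit <- mdscan(mm ~ age + sex, d, rho = 1, restarts = 5, seed = 1)
#' print(fit)
#' @seealso [mdscan_significance()], [mdscan_transfer()], [exhaustive_mdscan()]
#' @export
mdscan <- function(formula, data, rho = 1, direction = c("high", "low"),
                   n_bins = 10, restarts = 50, seed = 1, codebook = NULL,
                   forced = NULL, allow_intervals = FALSE, tol = 1e-9) {
  direction <- match.arg(direction)
  if (rho < 0) stop_validation("rho must be non-negative")
  if (restarts < 1) stop_validation("restarts must be >= 1")
  vars <- resolve_formula(formula, data)
  y <- as_binary_outcome(data[[vars$outcome]], vars$outcome)
  keep <- !is.na(y)
  mdata <- data[keep, c(vars$outcome, vars$features), drop = FALSE]
  y <- y[keep]
  mu <- mean(y)
  if (mu <= 0 || mu >= 1)
    stop("outcome '", vars$outcome, "' is degenerate (mean ", mu,
         "); the scan needs both outcomes present")
  if (is.null(codebook))
    codebook <- build_codebook(mdata, features = vars$features, n_bins = n_bins)
  enc <- encode_cohort(mdata, codebook)
  forced_state <- if (!is.null(forced)) description_to_state(forced, codebook, enc)
  res <- scan_engine(enc, y, mu, rho, direction, restarts = restarts,
                     seed = seed, tol = tol, forced = forced_state,
                     allow_intervals = allow_intervals)
  description <- render_state(res$state, codebook)
  stats <- subset_stats(mdata, description, outcome = vars$outcome)
  structure(list(description = description, F = res$F, F_pen = res$F_pen,
                 NL = res$NL, C = res$C, B = res$B, N = res$N,
                 n = nrow(mdata), mu = mu, direction = direction, rho = rho,
                 stats = stats, codebook = codebook,
                 outcome = vars$outcome, features = vars$features,
                 config = list(n_bins = n_bins, restarts = restarts,
                               seed = seed, tol = tol,
                               allow_intervals = allow_intervals,
                               forced = forced),
                 data = mdata, call = match.call()),
            class = "mdscan")
}

#' Exhaustive scan over the full description space (brute-force oracle)
#'
#' Enumerates every conjunctive description (all per-feature one-sided bin
#' runs and categorical level subsets, including "unrestricted") and returns
#' the global maximizer of the penalized score among direction-eligible
#' candidates.  Only feasible on small instances; refuses candidate spaces
#' above `max_space` with a size estimate.  Intended as the ground truth the
#' iterative scan is validated against.
#'
#' @inheritParams mdscan
#' @param max_space refuse enumeration above this many candidate descriptions.
#' @return an object of class `mdscan` (with `restarts = NA`).
#' @export
exhaustive_mdscan <- function(formula, data, rho = 1,
                              direction = c("high", "low"), n_bins = 10,
                              codebook = NULL, allow_intervals = FALSE,
                              max_space = 1e6) {
  direction <- match.arg(direction)
  vars <- resolve_formula(formula, data)
  y <- as_binary_outcome(data[[vars$outcome]], vars$outcome)
  keep <- !is.na(y)
  mdata <- data[keep, c(vars$outcome, vars$features), drop = FALSE]
  y <- y[keep]
  mu <- mean(y)
  if (is.null(codebook))
    codebook <- build_codebook(mdata, features = vars$features, n_bins = n_bins)
  enc <- encode_cohort(mdata, codebook)
  res <- exhaustive_engine(enc, y, mu, rho, direction,
                           allow_intervals = allow_intervals,
                           max_space = max_space)
  description <- render_state(res$state, codebook)
  stats <- subset_stats(mdata, description, outcome = vars$outcome)
  structure(list(description = description, F = res$F, F_pen = res$F_pen,
                 NL = res$NL, C = res$C, B = res$B, N = res$N,
                 n = nrow(mdata), mu = mu, direction = direction, rho = rho,
                 stats = stats, codebook = codebook,
                 outcome = vars$outcome, features = vars$features,
                 config = list(n_bins = n_bins, restarts = NA_integer_,
                               seed = NA_integer_, tol = 0,
                               allow_intervals = allow_intervals,
                               forced = NULL),
                 data = mdata, call = match.call()),
            class = "mdscan")
}

resolve_formula <- function(formula, data) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  tt <- stats::terms(formula, data = data)
  if (attr(tt, "response") != 1L) stop("formula needs an outcome on the left")
  outcome <- as.character(attr(tt, "variables"))[2L]
  features <- attr(tt, "term.labels")
  if (!outcome %in% names(data)) stop("outcome '", outcome, "' not in data")
  miss <- setdiff(features, names(data))
  if (length(miss))
    stop("features not in data: ", paste(miss, collapse = ", "))
  if (length(features) == 0L) stop("no features on the right-hand side")
  list(outcome = outcome, features = features)
}

as_binary_outcome <- function(y, name) {
  if (is.logical(y)) return(y)
  if (is.numeric(y) && all(y %in% c(0, 1, NA))) return(y == 1)
  stop("outcome '", name, "' must be logical or 0/1")
}

# Translate an mds_description into an engine state.  Thresholds must match
# codebook edges (">=") or edge predecessors ("<=").
description_to_state <- function(description, codebook, enc) {
  state <- empty_state(enc)
  for (l in description$literals) {
    f <- l$feature
    if (!f %in% names(codebook)) stop("forced feature '", f, "' not in codebook")
    e <- codebook[[f]]
    cur <- state[[f]]
    if (l$relation == "in") {
      idx <- match(l$value, e$levels)
      if (anyNA(idx)) stop("unknown level in forced literal on '", f, "'")
      state[[f]] <- sort(idx)
    } else {
      kk <- length(e$edges) + 1L
      if (is.null(cur)) cur <- c(1L, kk)
      if (l$relation == ">=") {
        j <- match(l$value, e$edges)
        if (is.na(j)) stop("forced threshold on '", f, "' is not a codebook edge")
        cur[1L] <- j + 1L
      } else {
        j <- match(l$value, e$edge_prev)
        if (is.na(j)) j <- match(l$value, e$edges)  # tolerate edge-valued "<="
        if (is.na(j)) stop("forced threshold on '", f, "' is not a codebook edge")
        cur[2L] <- j
      }
      state[[f]] <- cur
    }
  }
  state[!vapply(state, is.null, TRUE)]
}

#' @export
print.mdscan <- function(x, digits = 3, ...) {
  cat("Penalized subset scan (", x$direction, "-risk direction)\n", sep = "")
  cat("  n = ", x$n, ", outcome mean mu = ", format(x$mu, digits = digits),
      ", rho = ", x$rho, "\n", sep = "")
  cat("  S*: ", format(x$description), "\n", sep = "")
  cat(sprintf("  F = %.*f   F_pen = %.*f   NL = %d\n",
              digits, x$F, digits, x$F_pen, x$NL))
  cat(sprintf("  |S| = %d   C = %d observed vs B = %.*f expected cases\n",
              as.integer(x$N), as.integer(x$C), digits, x$B))
  invisible(x)
}

#' @export
summary.mdscan <- function(object, ...) {
  structure(list(fit = object, stats = object$stats), class = "summary.mdscan")
}

#' @export
print.summary.mdscan <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nDescriptive statistics of S*:\n")
  print(x$stats, digits = digits)
  invisible(x)
}

#' @export
coef.mdscan <- function(object, ...) {
  lits <- object$description$literals
  data.frame(feature = vapply(lits, `[[`, "", "feature"),
             relation = vapply(lits, `[[`, "", "relation"),
             value = vapply(lits, function(l)
               if (l$relation == "in") paste(l$value, collapse = "|")
               else format(l$value, digits = 8, trim = TRUE), ""),
             stringsAsFactors = FALSE)
}

#' Apply a fitted subset description to (new) data
#'
#' Evaluates the discovered description literal by literal on the raw
#' measurement scale — no re-binning — which is exactly the cross-cohort
#' transfer operation.
#'
#' @param object an `mdscan` fit.
#' @param newdata a data frame with the features the description references;
#'   defaults to the training cohort.
#' @param type `"membership"` for the logical row mask, `"stats"` for the
#'   [subset_stats()] of the description on `newdata`.
#' @param ... unused.
#' @export
predict.mdscan <- function(object, newdata = NULL,
                           type = c("membership", "stats"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (type == "membership") return(subset_mask(newdata, object$description))
  subset_stats(newdata, object$description, outcome = object$outcome)
}

#' Simulate replica outcomes under the scan's null hypothesis
#'
#' Draws `nsim` replica outcome vectors, each i.i.d. Bernoulli with the
#' cohort's observed outcome mean — the randomization null that every subset
#' has outcomes drawn from the population rate.
#'
#' @param object an `mdscan` fit.
#' @param nsim number of replicas.
#' @param seed master seed (replica `k` uses the sub-stream `"replica<k>"`).
#' @param ... unused.
#' @return a data frame of `nsim` logical columns, `sim_1 ... sim_nsim`.
#' @export
simulate.mdscan <- function(object, nsim = 1, seed = 1, ...) {
  out <- lapply(seq_len(nsim), function(k) {
    set.seed(substream_seed(seed, paste0("replica", k)))
    stats::rbinom(object$n, 1, object$mu) == 1
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Plot observed versus expected outcome counts for a scan result
#'
#' Barplot of observed (`C`) and expected (`B`) multimorbidity counts inside
#' and outside the discovered subset.
#'
#' @param x an `mdscan` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mdscan <- function(x, ...) {
  m <- rbind(observed = c(x$C, sum(x$data[[x$outcome]], na.rm = TRUE) - x$C),
             expected = c(x$B, x$mu * (x$n - x$N)))
  colnames(m) <- c("inside S*", "outside S*")
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "outcome count",
                    main = paste0(x$direction, "-risk subset: ",
                                  format(x$description)), ...)
  invisible(x)
}

#' Serialize a scan result as JSON
#'
#' @param x an `mdscan` fit.
#' @param path optional file to write.
#' @return the JSON string, invisibly.
#' @export
scan_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mdscan"))
  lits <- lapply(x$description$literals, function(l)
    list(feature = l$feature, relation = l$relation, value = l$value))
  obj <- list(schema = "mdscan/scan-result/1",
              description = format(x$description), literals = lits,
              F = x$F, F_pen = x$F_pen, NL = x$NL,
              C = x$C, B = x$B, N = x$N, n = x$n, mu = x$mu,
              direction = x$direction, rho = x$rho, config = x$config)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
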