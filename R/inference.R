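# Randomization inference for a scan result: outcome-resampled replicas.

#' Build a replica cohort under the randomization null
#'
#' Features are copied unchanged; the outcome of every record is replaced by
#' an independent Bernoulli(`mu`) coin toss.  This embodies the null
#' hypothesis that every subset of the data has outcomes drawn from the
#' population mean.
#'
#' @param cohort a data frame.
#' @param mu outcome probability, strictly in (0, 1) — by convention the
#'   scanned cohort's observed outcome mean.
#' @param seed integer seed.
#' @param outcome outcome column name.
#' @return the replica data frame.
#' @export
make_replica <- function(cohort, mu, seed, outcome = "mm") {
  check_prob(mu, "mu")
  set.seed(seed)
  out <- cohort
  out[[outcome]] <- stats::rbinom(nrow(cohort), 1, mu) == 1
  out
}

#' Empirical p-value from replica scores
#'
#' `p = (r + 1) / (K + 1)` where `r` counts replicas whose score reaches the
#' real data's score.  The smallest attainable value is `1/(K+1)`.
#'
#' @param f_star score of the best subset on the real data.
#' @param replica_scores numeric vector of the K replica scores.
#' @return the empirical p-value.
#' @examples
#' empirical_p(21.9, rep(3, 100))   # 1/101
#' @export
empirical_p <- function(f_star, replica_scores) {
  if (length(replica_scores) < 1L) stop_validation("need at least one replica score")
  (sum(replica_scores >= f_star) + 1) / (length(replica_scores) + 1)
}

#' Randomization significance test for a scan result
#'
#' Generates `K` replica cohorts (outcomes resampled at the cohort's observed
#' rate), re-runs the full scan on each with the same configuration (fresh
#' seeds from the `"replica<k>"` sub-streams), and compares the raw scores:
#' the p-value is `(r + 1)/(K + 1)` with `r` the number of replicas whose
#' best score reaches the real data's best score.  Because each replica is
#' re-optimized, the selection effect of searching exponentially many
#' subsets is built into the null distribution.
#'
#' @param object an `mdscan` fit.
#' @param K number of replicas (default 100).
#' @param seed master seed for the replica sub-streams.
#' @return an object of class `mdscan_test`: `f_star`, `replica_scores`,
#'   `r`, `p`, `K`, `seed`.
#' @export
mdscan_significance <- function(object, K = 100, seed = 1) {
  stopifnot(inherits(object, "mdscan"), K >= 1)
  cfg <- object$config
  scores <- vapply(seq_len(K), function(k) {
    rep_seed <- substream_seed(seed, paste0("replica", k))
    repl <- make_replica(object$data, object$mu, rep_seed,
                         outcome = object$outcome)
    fit <- mdscan(stats::reformulate(object$features, object$outcome), repl,
                  rho = object$rho, direction = object$direction,
                  n_bins = cfg$n_bins, restarts = cfg$restarts,
                  seed = substream_seed(rep_seed, "scan"),
                  forced = cfg$forced, allow_intervals = cfg$allow_intervals,
                  tol = cfg$tol)
    fit$F
  }, 0)
  r <- sum(scores >= object$F)
  structure(list(f_star = object$F, replica_scores = scores, r = r,
                 p = (r + 1) / (K + 1), K = K, seed = seed),
            class = "mdscan_test")
}

#' @export
print.mdscan_test <- function(x, ...) {
  cat("Randomization test:", x$K, "replicas\n")
  cat(sprintf("  F* = %.4f; %d replica score(s) >= F*; empirical p = %.4f\n",
              x$f_star, x$r, x$p))
  invisible(x)
}

#' Plot the replica score distribution of a randomization test
#'
#' Histogram of the K replica scores with the real-data score marked.
#' @param x an `mdscan_test`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.mdscan_test <- function(x, ...) {
  graphics::hist(x$replica_scores, xlab = "replica score F(S_k)",
                 main = sprintf("empirical p = %.3f (K = %d)", x$p, x$K),
                 xlim = range(c(x$replica_scores, x$f_star)), ...)
  graphics::abline(v = x$f_star, lwd = 2)
  invisible(x)
}
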