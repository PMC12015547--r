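`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Named sub-streams keep the random draws of one component (e.g. the outcome
#' coin flips) stable when another component (e.g. an extra feature) is added.
#' The hash is plain integer arithmetic so it is identical across platforms.
#'
#' @param seed master seed, a non-negative integer below 2^31.
#' @param name character label of the sub-stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% m
  # 48271 is the classic Lehmer multiplier; products stay below 2^53
  as.integer(((h * 48271) %% m + seed) %% m)
}

# Three-valued (Kleene) OR over logical vectors: TRUE if any TRUE,
# NA if none TRUE but some NA, FALSE otherwise.  This is the missing-data
# semantics of every "or"-composed condition definition in the package:
# a condition is present if any criterion is met, absent only when every
# criterion is observed and unmet, and unknown otherwise.
or3 <- function(...) {
  args <- list(...)
  out <- Reduce(function(x, y) x | y, args)
  out
}

stop_validation <- function(...) {
  stop(structure(class = c("mds_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation(name, " must be a single number")
  if (open) {
    if (x <= 0 || x >= 1) stop_validation(name, " must lie strictly in (0, 1)")
  } else if (x < 0 || x > 1) stop_validation(name, " must lie in [0, 1]")
  x
}

# inverse-CDF truncated normal draw
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
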