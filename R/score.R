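#' Binomial likelihood-ratio scan statistic
#'
#' Divergence between the observed outcome count `C` in a subset of size `N`
#' and its expectation `B = mu * N` under the population outcome rate `mu`:
#'
#' \deqn{F = C \log(C/B) + (N - C) \log((N - C)/(N - B))}
#'
#' with natural logarithms and the convention `0 * log(0) = 0`.  This is `N`
#' times the Kullback-Leibler divergence between Bernoulli(C/N) and
#' Bernoulli(B/N), so `F >= 0` with equality iff `C = B`.  It is symmetric in
#' direction: both excesses (`C > B`) and deficits (`C < B`) score high, which
#' is why the high-/low-risk distinction is enforced by a direction gate in
#' the search rather than by the score.
#'
#' @param C observed outcome count in the subset (0 <= C <= N).
#' @param B expected count, `mu * N`; must satisfy 0 < B < N when N > 0.
#' @param N subset size.
#' @return the non-negative score; 0 for an empty subset.
#' @examples
#' score_binomial_lr(78, 37.06, 226)   # ~ 21.90
#' score_binomial_lr(50, 50, 500)      # 0: observed equals expected
#' @export
score_binomial_lr <- function(C, B, N) {
  stopifnot(length(C) == length(B), length(B) == length(N))
  if (any(C < 0 | C > N)) stop_validation("C must lie in [0, N]")
  pos <- N > 0
  if (any(B[pos] <= 0 | B[pos] >= N[pos]))
    stop_validation("B must lie strictly in (0, N) for non-empty subsets")
  t1 <- ifelse(C > 0, C * log(C / B), 0)
  t2 <- ifelse(N - C > 0, (N - C) * log((N - C) / (N - B)), 0)
  out <- t1 + t2
  out[!pos] <- 0
  # clamp tiny negative values from floating cancellation at C ~ B
  pmax(out, 0)
}

#' Complexity-penalized scan score
#'
#' Subtracts a per-literal penalty from the raw score: `F_pen = F - rho * NL`.
#' `rho` trades subset anomalousness against description length; `rho = 0`
#' recovers the unpenalized scan.
#'
#' @param F raw binomial likelihood-ratio score.
#' @param NL number of literals in the subset description.
#' @param rho non-negative penalty per literal.
#' @return the penalized score.
#' @export
penalized_score <- function(F, NL, rho) {
  if (any(rho < 0)) stop_validation("rho must be non-negative")
  if (any(NL < 0)) stop_validation("NL must be non-negative")
  F - rho * NL
}
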