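#' Population confusion rates for a discovery experiment
#'
#' Applies Bayes' rule to a discovery experiment characterised by the prior
#' truth fraction `gamma` (the proportion of tested hypotheses that are
#' true), the per-test false-positive rate `alpha` and false-negative rate
#' `beta`. The four cell rates are population fractions of all hypotheses
#' tested, so they sum to one:
#'
#' * true positives `gamma * (1 - beta)`
#' * false positives `alpha * (1 - gamma)`
#' * false negatives `gamma * beta`
#' * true negatives `(1 - alpha) * (1 - gamma)`
#'
#' The declared success rate is the positive margin, the true discovery rate
#' (TDR, the positive predictive value) is the share of declared positives
#' that are true, and the false discovery rate is its complement:
#' `FDR = alpha * (1 - gamma) / ((1 - beta) * gamma + alpha * (1 - gamma))`.
#'
#' @param gamma Prior truth fraction(s) in `[0, 1]`.
#' @param alpha Per-test false-positive rate(s).
#' @param beta Per-test false-negative rate(s); power is `1 - beta`.
#' @return A tibble with one row per parameter combination and columns
#'   `gamma`, `alpha`, `beta`, `tp`, `fp`, `fn`, `tn`, `declared_success`,
#'   `tdr`, `fdr`. Inputs are recycled to a common length.
#' @section Degenerate inputs: when the declared success rate is exactly zero
#'   (`alpha == 0` and `gamma * (1 - beta) == 0`) the discovery rates are
#'   0/0; an error of class `targetodds_undefined_rate` is raised rather
#'   than returning a sentinel.
#' @examples
#' confusion(gamma = 0.005, alpha = 0.05, beta = 0.2)$fdr # 0.926
#' @export
confusion <- function(gamma, alpha = 0.05, beta = 0.2) {
  check_probability(gamma, "gamma")
  check_probability(alpha, "alpha")
  check_probability(beta, "beta")
  n <- max(length(gamma), length(alpha), length(beta))
  gamma <- rep_len(gamma, n)
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)

  tp <- gamma * (1 - beta)
  fp <- alpha * (1 - gamma)
  fn <- gamma * beta
  tn <- (1 - alpha) * (1 - gamma)
  s <- tp + fp
  if (any(s == 0)) {
    abort_targetodds(
      "Declared success rate is 0 (alpha = 0 and no detectable truths): TDR and FDR are undefined.",
      "targetodds_undefined_rate")
  }
  tibble::tibble(
    gamma = gamma, alpha = alpha, beta = beta,
    tp = tp, fp = fp, fn = fn, tn = tn,
    declared_success = s,
    tdr = tp / s,
    fdr = fp / s
  )
}

#' False and true discovery rates
#'
#' Convenience scalars extracted from [confusion()].
#'
#' @inheritParams confusion
#' @return A numeric vector of rates.
#' @export
fdr_rate <- function(gamma, alpha = 0.05, beta = 0.2) {
  confusion(gamma, alpha, beta)$fdr
}

#' @rdname fdr_rate
#' @export
tdr_rate <- function(gamma, alpha = 0.05, beta = 0.2) {
  confusion(gamma, alpha, beta)$tdr
}
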