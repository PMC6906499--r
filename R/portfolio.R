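#' Parallel programmes needed for at least one success
#'
#' With independent development programmes each succeeding with probability
#' `p_s`, the number of parallel programmes needed for at least one success
#' with the stated confidence solves `1 - (1 - p_s)^N >= confidence`. The
#' default returns the smallest integer satisfying the inequality. With a
#' target-level success rate of 0.02, 114 programmes are needed for a 90%
#' chance of at least one success.
#'
#' @param p_s Per-programme success probability, in `(0, 1)`.
#' @param confidence Required probability of at least one success.
#' @param rounding `"ceiling"` (default) returns the smallest integer that
#'   attains the confidence; `"nearest"` rounds the real-valued solution of
#'   `(1 - p_s)^N = 1 - confidence` to the nearest integer, the convention
#'   behind quoted counts where the confidence is attained only
#'   approximately (e.g. 34 programmes for an approximately even chance).
#' @return A positive integer.
#' @examples
#' n_programmes_needed(0.02, 0.9) # 114
#' @export
n_programmes_needed <- function(p_s, confidence = 0.9,
                                rounding = c("ceiling", "nearest")) {
  n_for_at_least_one(p_s, confidence, rounding = match.arg(rounding))
}

check_portfolio <- function(frame_size, n_causal, n_programmes) {
  frame_size <- check_count(frame_size, "frame_size")
  n_causal <- check_count(n_causal, "n_causal", positive = FALSE)
  n_programmes <- check_count(n_programmes, "n_programmes")
  if (n_causal > frame_size) {
    abort_targetodds("`n_causal` cannot exceed `frame_size`.",
                     "targetodds_invalid_argument")
  }
  if (n_programmes > frame_size) {
    abort_targetodds("`n_programmes` cannot exceed `frame_size`.",
                     "targetodds_invalid_argument")
  }
  list(frame_size = frame_size, n_causal = n_causal,
       n_programmes = n_programmes)
}

#' Distribution of causal targets captured by a programme portfolio
#'
#' `n_programmes` targets are drawn without replacement from a sampling
#' frame of `frame_size` candidate targets of which `n_causal` are causal
#' for the disease of interest (each drawn target seeds one independent
#' development programme). The number of causal targets in the portfolio is
#' hypergeometric. `causal_in_sample_pmf()` returns the full probability
#' mass function; `expected_causal_in_sample()` the finite-population mean
#' `N * C / frame` and standard deviation
#' `sqrt(N * C * (F - C) * (F - N) / (F^2 * (F - 1)))`.
#'
#' @param frame_size Number of candidate targets in the sampling frame
#'   (e.g. the 4,000-gene druggable genome, or a curated subset).
#' @param n_causal Number of causal targets in the frame.
#' @param n_programmes Number of targets drawn (parallel programmes).
#' @return `causal_in_sample_pmf()`: a tibble with columns `n_causal_drawn`
#'   and `prob` over the full support (out-of-support counts have
#'   probability 0). `expected_causal_in_sample()`: a one-row tibble with
#'   `mean` and `sd`.
#' @examples
#' causal_in_sample_pmf(4000, 20, 20)$prob[1] # P(no causal target) ~ 0.90
#' expected_causal_in_sample(4000, 20, 200)
#' @export
causal_in_sample_pmf <- function(frame_size, n_causal, n_programmes) {
  p <- check_portfolio(frame_size, n_causal, n_programmes)
  a <- 0:min(p$n_causal, p$n_programmes)
  new_pmf_tbl(tibble::tibble(
    n_causal_drawn = a,
    prob = stats::dhyper(a, p$n_causal, p$frame_size - p$n_causal,
                         p$n_programmes)
  ))
}

#' @rdname causal_in_sample_pmf
#' @export
expected_causal_in_sample <- function(frame_size, n_causal, n_programmes) {
  p <- check_portfolio(frame_size, n_causal, n_programmes)
  f <- p$frame_size
  mean <- p$n_programmes * p$n_causal / f
  var <- p$n_programmes * p$n_causal * (f - p$n_causal) *
    (f - p$n_programmes) / (f^2 * (f - 1))
  tibble::tibble(mean = mean, sd = sqrt(var))
}

#' Probability that a portfolio advances a truly causal target
#'
#' Models the selection step of orthodox preclinical development as
#' draw-test-advance: `n_programmes` targets are drawn without replacement
#' from the frame; each causal target tests positive with probability
#' `1 - beta` and each non-causal target with probability `alpha`; one
#' nominally positive target, chosen uniformly among the positives, advances
#' to clinical development. Development succeeds iff the advanced target is
#' truly causal (no positives means no programme advances). The probability
#' is computed by exact summation over the joint distribution of
#' (causal targets drawn, true positives, false positives).
#'
#' @inheritParams causal_in_sample_pmf
#' @param alpha,beta Per-target false-positive and false-negative rates of
#'   the preclinical test.
#' @return A probability.
#' @examples
#' development_success_prob(4000, 20, 50)
#' @export
development_success_prob <- function(frame_size, n_causal, n_programmes,
                                     alpha = 0.05, beta = 0.2) {
  p <- check_portfolio(frame_size, n_causal, n_programmes)
  check_probability(alpha, "alpha")
  check_probability(beta, "beta")
  total <- 0
  for (a in 0:min(p$n_causal, p$n_programmes)) {
    pa <- stats::dhyper(a, p$n_causal, p$frame_size - p$n_causal,
                        p$n_programmes)
    if (pa == 0) next
    pt <- stats::dbinom(0:a, a, 1 - beta)
    pf <- stats::dbinom(0:(p$n_programmes - a), p$n_programmes - a, alpha)
    for (t in seq_along(pt) - 1L) {
      if (t == 0) next # no true positives: the advanced target (if any) is false
      f <- seq_along(pf) - 1L
      total <- total + pa * pt[t + 1L] * sum(pf * t / (t + f))
    }
  }
  total
}

#' Expected true and false positives in a programme portfolio
#'
#' Expected counts of truly causal and non-causal targets testing positive
#' among `n_programmes` drawn targets: `E[TP] = (1 - beta) * N * C / F` and
#' `E[FP] = alpha * N * (1 - C / F)`. True positives outnumber false
#' positives only when the frame is small enough;
#' `equal_positives_frame()` returns the frame size at which the two are
#' equal, `C * (1 - beta + alpha) / alpha` (340 targets under the defaults,
#' consistent with needing a frame of fewer than ~400 candidates).
#'
#' @inheritParams development_success_prob
#' @return A one-row tibble with `expected_tp` and `expected_fp`.
#' @examples
#' expected_positive_mix(4000, 20, 200)
#' @export
expected_positive_mix <- function(frame_size, n_causal, n_programmes,
                                  alpha = 0.05, beta = 0.2) {
  p <- check_portfolio(frame_size, n_causal, n_programmes)
  check_probability(alpha, "alpha")
  check_probability(beta, "beta")
  pc <- p$n_causal / p$frame_size
  tibble::tibble(
    expected_tp = (1 - beta) * p$n_programmes * pc,
    expected_fp = alpha * p$n_programmes * (1 - pc)
  )
}

#' @rdname expected_positive_mix
#' @export
equal_positives_frame <- function(n_causal, alpha = 0.05, beta = 0.2) {
  n_causal <- check_count(n_causal, "n_causal")
  check_probability(alpha, "alpha", allow_zero = FALSE)
  check_probability(beta, "beta")
  n_causal * (1 - beta + alpha) / alpha
}
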