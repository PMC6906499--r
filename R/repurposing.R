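#' Number of diseases affected by perturbing one target
#'
#' Under independent causal assignment, the number of diseases influenced by
#' a given gene is binomial with size `n_diseases` and success probability
#' [p_causal()], giving mean `E_D = P_C * N_D` and standard deviation
#' `sqrt(P_C * (1 - P_C) * N_D)`. The central 95% interval is reported with
#' the normal approximation (`mean +/- 1.96 * sd`, rounded to whole
#' diseases: 36 to 64 under the defaults) alongside the exact binomial
#' quantile interval. When `tail_at` is given, the probability of affecting
#' that many or fewer diseases is reported from both the exact binomial and
#' the normal approximation (about 1 in 1000 at 28 under the defaults).
#'
#' @param space A [sample_space()].
#' @param tail_at Optional disease count for the lower-tail probability.
#' @return A one-row tibble with columns `e_d`, `s_d`, `lower_95`,
#'   `upper_95` (normal, integer-rounded), `lower_95_exact`,
#'   `upper_95_exact` (binomial quantiles), and, if `tail_at` is supplied,
#'   `tail_at`, `tail_prob_exact`, `tail_prob_normal`.
#' @examples
#' diseases_per_target(sample_space(), tail_at = 28)
#' @export
diseases_per_target <- function(space, tail_at = NULL) {
  check_space(space)
  p_c <- p_causal(space)
  n_d <- space$n_diseases
  e_d <- p_c * n_d
  s_d <- sqrt(p_c * (1 - p_c) * n_d)
  out <- tibble::tibble(
    e_d = e_d,
    s_d = s_d,
    lower_95 = round(e_d - 1.96 * s_d),
    upper_95 = round(e_d + 1.96 * s_d),
    lower_95_exact = stats::qbinom(0.025, n_d, p_c),
    upper_95_exact = stats::qbinom(0.975, n_d, p_c)
  )
  if (!is.null(tail_at)) {
    tail_at <- check_count(tail_at, "tail_at", positive = FALSE)
    out$tail_at <- tail_at
    out$tail_prob_exact <- stats::pbinom(tail_at, n_d, p_c)
    out$tail_prob_normal <- if (s_d > 0) {
      stats::pnorm(tail_at, mean = e_d, sd = s_d)
    } else {
      as.numeric(tail_at >= e_d)
    }
  }
  out
}

#' Probability that k diseases share no causal gene
#'
#' Each disease's causal set is an independent uniform draw of
#' `causal_per_disease` genes from the genome. The probability that `k`
#' diseases are pairwise disjoint in their causal genes is computed as the
#' chained hypergeometric product: disease `j + 1` must avoid the `j * C`
#' genes accumulated by the previous diseases, giving
#' `prod_j choose(N_G - j * C, C) / choose(N_G, C)` for `j = 1 .. k - 1`,
#' evaluated with log binomial coefficients. The chain conditions each new
#' disease on the accumulated genes being distinct (which holds exactly on
#' the no-overlap event being computed), matching the successive 0.605 and
#' 0.365 terms of the worked three-disease example.
#'
#' @param space A [sample_space()]; `causal_per_disease` must be a whole
#'   number here.
#' @param k Number of diseases considered (`k = 1` trivially gives 1).
#' @return A probability. If the diseases cannot fit disjointly in the
#'   genome (`k * C > N_G`), returns 0 by pigeonhole.
#' @examples
#' prob_no_shared_gene_chain(sample_space(), k = 3) # 0.221
#' @export
prob_no_shared_gene_chain <- function(space, k) {
  check_space(space)
  k <- check_count(k, "k")
  cbar <- space$causal_per_disease
  if (cbar != round(cbar)) {
    abort_targetodds(
      "`causal_per_disease` must be integer-valued for the shared-gene chain.",
      "targetodds_invalid_argument")
  }
  if (k == 1) return(1)
  j <- seq_len(k - 1)
  if (any(space$n_genes - j * cbar < cbar)) return(0)
  exp(sum(lchoose(space$n_genes - j * cbar, cbar) -
            lchoose(space$n_genes, cbar)))
}

#' Diseases to study to find one affected by a given target
#'
#' Each studied disease is causally affected by the target with probability
#' `p_affected` (the causal fraction, e.g. [p_causal()]); the smallest
#' number of diseases giving at least the stated confidence of one hit uses
#' the same at-least-one-success kernel as [n_programmes_needed()]. Under
#' the defaults (`p_affected = 0.005`), 460 diseases are needed for a 90%
#' chance.
#'
#' @param p_affected Probability that a random disease is affected by the
#'   target.
#' @param confidence Required probability of at least one affected disease.
#' @inheritParams n_programmes_needed
#' @return A positive integer.
#' @examples
#' diseases_needed(0.005, 0.9) # 460
#' @export
diseases_needed <- function(p_affected, confidence = 0.9,
                            rounding = c("ceiling", "nearest")) {
  n_for_at_least_one(p_affected, confidence, rounding = match.arg(rounding))
}
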