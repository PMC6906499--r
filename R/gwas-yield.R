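#' Rediscovery of licensed drug targets by a GWAS
#'
#' A genome-wide association study of a disease with `n` licensed drug
#' targets available for rediscovery detects each independently with power
#' `1 - beta`, so the number rediscovered is binomial.
#' `rediscovery_pmf()` gives the full mass function over `0..n`;
#' `prob_any_rediscovery()` gives `P(X > 0) = 1 - beta^n`;
#' `expected_rediscoveries()` the mean `n * (1 - beta)` and standard
#' deviation `sqrt(n * beta * (1 - beta))`. Per-locus power may vary: pass a
#' vector `beta` of per-locus false-negative rates to
#' `expected_rediscoveries()` and the Poisson-binomial mean
#' `sum(1 - beta)` and standard deviation `sqrt(sum(beta * (1 - beta)))`
#' are used (with `n` implied by the vector length).
#'
#' @param n Number of true targets available for rediscovery (non-negative
#'   integer).
#' @param beta Per-locus false-negative rate; a scalar for homogeneous
#'   power, or for `expected_rediscoveries()` a vector of per-locus values.
#' @return `rediscovery_pmf()`: a tibble with columns `x` (targets
#'   detected) and `prob`. `prob_any_rediscovery()`: a probability.
#'   `expected_rediscoveries()`: a one-row tibble with `mean` and `sd`.
#' @examples
#' rediscovery_pmf(3, 0.2) # 0.008, 0.096, 0.384, 0.512
#' expected_rediscoveries(3, 0.2) # mean 2.4, sd 0.69
#' @export
rediscovery_pmf <- function(n, beta = 0.2) {
  n <- check_count(n, "n", positive = FALSE)
  check_probability(beta, "beta")
  if (length(beta) != 1L) {
    abort_targetodds("`beta` must be a scalar for the pmf; use `expected_rediscoveries()` for per-locus powers.",
                     "targetodds_invalid_argument")
  }
  x <- 0:n
  new_pmf_tbl(tibble::tibble(x = x, prob = stats::dbinom(x, n, 1 - beta)))
}

#' @rdname rediscovery_pmf
#' @export
prob_any_rediscovery <- function(n, beta = 0.2) {
  n <- check_count(n, "n", positive = FALSE)
  check_probability(beta, "beta")
  1 - beta^n
}

#' @rdname rediscovery_pmf
#' @export
expected_rediscoveries <- function(n = NULL, beta = 0.2) {
  check_probability(beta, "beta")
  if (length(beta) > 1L) {
    if (!is.null(n) && n != length(beta)) {
      abort_targetodds("With per-locus `beta`, `n` must be absent or equal to `length(beta)`.",
                       "targetodds_invalid_argument")
    }
    return(tibble::tibble(mean = sum(1 - beta),
                          sd = sqrt(sum(beta * (1 - beta)))))
  }
  n <- check_count(n, "n", positive = FALSE)
  tibble::tibble(mean = n * (1 - beta), sd = sqrt(n * beta * (1 - beta)))
}

#' Expected rediscoveries across many disease GWAS
#'
#' With one GWAS in each of `n_gwas` diseases, an average of `mean_targets`
#' licensed targets per disease and homogeneous power `1 - beta`, the total
#' number of target-indication rediscoveries has mean
#' `E_T = n_gwas * (1 - beta) * mean_targets` and standard deviation
#' `sqrt(beta * (1 - beta) * mean_targets * n_gwas)`.
#'
#' @param n_gwas Number of diseases with a GWAS.
#' @param mean_targets Average number of licensed drug targets per disease
#'   (may be non-integer; it is an average).
#' @param beta Per-locus false-negative rate.
#' @return A one-row tibble with `e_t` and `sd_t`.
#' @examples
#' multi_disease_rediscoveries(200, 3, 0.2) # E_T = 480, SD = 9.8
#' @export
multi_disease_rediscoveries <- function(n_gwas, mean_targets, beta = 0.2) {
  n_gwas <- check_count(n_gwas, "n_gwas")
  if (!is.numeric(mean_targets) || length(mean_targets) != 1L ||
      is.na(mean_targets) || mean_targets < 0) {
    abort_targetodds("`mean_targets` must be a single non-negative number.",
                     "targetodds_invalid_argument")
  }
  check_probability(beta, "beta")
  tibble::tibble(
    e_t = n_gwas * (1 - beta) * mean_targets,
    sd_t = sqrt(beta * (1 - beta) * mean_targets * n_gwas)
  )
}

#' Back-calculate average GWAS power from observed rediscoveries
#'
#' Inverts the multi-disease rediscovery expectation: given
#' `observed` target-indication rediscoveries over `n_gwas` disease GWAS
#' with `mean_targets` rediscoverable targets per disease on average, the
#' implied average power is `observed / (mean_targets * n_gwas)`. The 74
#' rediscoveries over 315 GWAS'd disease terms imply power 0.23 if each
#' disease offered one rediscoverable target (and proportionally less if
#' more).
#'
#' @param observed Observed number of rediscoveries.
#' @param n_gwas Number of diseases with a GWAS.
#' @param mean_targets Average rediscoverable targets per disease.
#' @return The implied average power `1 - beta`.
#' @examples
#' backcalc_power(74, 315, 1)
#' @export
backcalc_power <- function(observed, n_gwas, mean_targets) {
  observed <- check_count(observed, "observed", positive = FALSE)
  n_gwas <- check_count(n_gwas, "n_gwas")
  if (!is.numeric(mean_targets) || length(mean_targets) != 1L ||
      is.na(mean_targets) || mean_targets <= 0) {
    abort_targetodds("`mean_targets` must be a single positive number.",
                     "targetodds_invalid_argument")
  }
  power <- observed / (mean_targets * n_gwas)
  if (power > 1) {
    abort_targetodds(
      "Inconsistent inputs: observed rediscoveries exceed the number available, implying power > 1.",
      "targetodds_infeasible")
  }
  power
}

#' Prospective yield of causal, druggable targets from one GWAS
#'
#' For a disease with `causal_per_disease` causal genes, the true number of
#' causal-and-druggable targets is `n_ct = C * n_druggable / n_genes` (20
#' under the defaults). A GWAS detecting each with power `1 - beta` yields a
#' binomial count with mean `n_ct * (1 - beta)` and standard deviation
#' `sqrt(n_ct * beta * (1 - beta))`: 16 (SD 1.8) of the 20 at 80% power.
#'
#' @param space A [sample_space()].
#' @param beta Per-locus false-negative rate.
#' @param below Optional count; the probability of discovering fewer than
#'   `below` targets is reported from the exact binomial (vanishingly small
#'   below 10 under the defaults).
#' @return An object of class `druggable_yield`; `glance()` gives the
#'   one-row summary (`n_ct`, `e_ct`, `sd_ct` and `p_below` if requested),
#'   `tidy()` the detection-count pmf.
#' @examples
#' glance(druggable_yield(sample_space(), beta = 0.2, below = 10))
#' @export
druggable_yield <- function(space, beta = 0.2, below = NULL) {
  check_space(space)
  check_probability(beta, "beta")
  n_ct <- space$causal_per_disease * space$n_druggable / space$n_genes
  if (n_ct != round(n_ct)) {
    abort_targetodds(
      "Expected causal-druggable count is not a whole number; the binomial yield pmf needs an integer target count.",
      "targetodds_invalid_argument")
  }
  n_ct <- as.integer(round(n_ct))
  out <- list(
    n_ct = n_ct,
    e_ct = n_ct * (1 - beta),
    sd_ct = sqrt(n_ct * beta * (1 - beta)),
    beta = beta,
    pmf = rediscovery_pmf(n_ct, beta)
  )
  if (!is.null(below)) {
    below <- check_count(below, "below", positive = FALSE)
    out$below <- below
    out$p_below <- stats::pbinom(below - 1, n_ct, 1 - beta)
  }
  structure(out, class = "druggable_yield")
}

#' @export
print.druggable_yield <- function(x, ...) {
  cat(sprintf(
    "GWAS yield of causal, druggable targets: %d available, expect %.3g (SD %.2g) at power %.3g\n",
    x$n_ct, x$e_ct, x$sd_ct, 1 - x$beta))
  if (!is.null(x$p_below)) {
    cat(sprintf("  P(fewer than %d discovered) = %.3g\n", x$below, x$p_below))
  }
  invisible(x)
}
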