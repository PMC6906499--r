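#' Two-stage drug development model: preclinical then clinical
#'
#' Drug development is reduced to two linked discovery experiments. Stage 1
#' (preclinical) tests target-disease hypotheses with prior truth fraction
#' `gamma_pc` and error rates `alpha_pc` / `beta_pc`. Every declared
#' preclinical success enters stage 2 (clinical), so the prior truth fraction
#' in clinical development equals the preclinical true discovery rate:
#' `gamma_c = TDR_pc`. The overall declared success rate is the product of
#' the per-stage declared success rates, `S_o = S_pc * S_c`.
#'
#' @param gamma_pc Prior truth fraction of hypotheses entering preclinical
#'   development.
#' @param alpha_pc,beta_pc Preclinical false-positive and false-negative
#'   rates. The orthodox benchmark is `alpha_pc = 0.05`; a genome-wide
#'   association study used as stage 1 operates at `alpha_pc = 5e-8`.
#' @param alpha_c,beta_c Clinical-stage error rates (defaults 0.05 and 0.2).
#' @return An object of class `two_stage` with elements `preclinical` and
#'   `clinical` (one-row [confusion()] tibbles), `gamma_pc`, `gamma_c`,
#'   `s_pc`, `s_c` and `s_o`. Use [generics::tidy()] for the stage table and
#'   [generics::glance()] for the one-row summary.
#' @examples
#' fit <- two_stage(gamma_pc = 0.001)
#' glance(fit)
#' @export
two_stage <- function(gamma_pc, alpha_pc = 0.05, beta_pc = 0.2,
                      alpha_c = 0.05, beta_c = 0.2) {
  pre <- confusion(gamma_pc, alpha_pc, beta_pc)
  gamma_c <- pre$tdr
  clin <- confusion(gamma_c, alpha_c, beta_c)
  structure(
    list(
      preclinical = pre,
      clinical = clin,
      gamma_pc = gamma_pc,
      gamma_c = gamma_c,
      s_pc = pre$declared_success,
      s_c = clin$declared_success,
      s_o = pre$declared_success * clin$declared_success
    ),
    class = "two_stage"
  )
}

#' @export
print.two_stage <- function(x, ...) {
  cat("Two-stage development model\n")
  cat(sprintf("  preclinical: gamma = %.4g, alpha = %.3g, power = %.3g -> S_pc = %.4g, TDR_pc = %.4g\n",
              x$gamma_pc, x$preclinical$alpha, 1 - x$preclinical$beta,
              x$s_pc, x$preclinical$tdr))
  cat(sprintf("  clinical:    gamma = %.4g, alpha = %.3g, power = %.3g -> S_c  = %.4g, TDR_c  = %.4g\n",
              x$gamma_c, x$clinical$alpha, 1 - x$clinical$beta,
              x$s_c, x$clinical$tdr))
  cat(sprintf("  overall declared success S_o = %.4g\n", x$s_o))
  invisible(x)
}

#' Clinical true discovery rate in closed form
#'
#' Expresses the clinical-stage true discovery rate as a function of both
#' stages' error rates and the preclinical prior truth fraction:
#' `1 / (1 + (alpha_c / (1 - beta_c)) * (alpha_pc / (1 - beta_pc)) *
#' ((1 - gamma_pc) / gamma_pc))`. This is the posterior odds of a randomly
#' chosen advanced drug being effective: prior odds times the Bayes factors
#' contributed by the preclinical and clinical discoveries. It equals the
#' clinical TDR obtained by composing two confusion tables in [two_stage()].
#'
#' @inheritParams two_stage
#' @return A probability.
#' @export
tdr_clinical <- function(gamma_pc, alpha_pc = 0.05, beta_pc = 0.2,
                         alpha_c = 0.05, beta_c = 0.2) {
  check_probability(gamma_pc, "gamma_pc")
  check_probability(alpha_pc, "alpha_pc")
  check_probability(beta_c, "beta_c", allow_one = FALSE)
  check_probability(beta_pc, "beta_pc", allow_one = FALSE)
  check_probability(alpha_c, "alpha_c")
  if (any(gamma_pc == 0)) {
    abort_targetodds("`gamma_pc` = 0: prior odds are zero and the TDR is undefined.",
                     "targetodds_undefined_rate")
  }
  1 / (1 + (alpha_c / (1 - beta_c)) * (alpha_pc / (1 - beta_pc)) *
         ((1 - gamma_pc) / gamma_pc))
}

#' Back-calculate the prior truth fraction from observed success rates
#'
#' Inverts the two-stage model: given observed preclinical (`s_pc`) and
#' clinical (`s_c`) declared success rates and assumed clinical error rates,
#' solves in closed form for the proportion of true target-disease
#' relationships entering each stage and for the implied preclinical
#' false-positive rate:
#'
#' * `gamma_c  = (s_c - alpha_c) / ((1 - beta_c) - alpha_c)`
#' * `gamma_pc = gamma_c * s_pc / (1 - beta_pc)`
#' * `alpha_pc = (s_pc - gamma_pc * (1 - beta_pc)) / (1 - gamma_pc)`
#' * `FDR_pc   = alpha_pc * (1 - gamma_pc) / s_pc`
#'
#' The solution is exact (the equations are linear in gamma), which also
#' makes the feasibility region explicit: an observed `s_c` at or below
#' `alpha_c` is fully explained by false positives, and clinical power must
#' exceed `alpha_c`. Infeasible inputs raise an error naming the violated
#' inequality instead of clipping.
#'
#' @param s_pc Observed preclinical declared success rate (reported ~0.4).
#' @param s_c Observed clinical declared success rate (reported ~0.1).
#' @param alpha_c,beta_c Assumed clinical-stage error rates.
#' @param beta_pc Assumed preclinical false-negative rate.
#' @return An object of class `back_calc` with fields `gamma_c`, `gamma_pc`,
#'   `alpha_pc`, `fdr_pc` and the inputs. `glance()` returns the one-row
#'   summary.
#' @examples
#' glance(back_calculate(s_pc = 0.4, s_c = 0.1))
#' @export
back_calculate <- function(s_pc, s_c, alpha_c = 0.05, beta_c = 0.2,
                           beta_pc = 0.2) {
  check_probability(s_pc, "s_pc", allow_zero = FALSE)
  check_probability(s_c, "s_c")
  check_probability(alpha_c, "alpha_c")
  check_probability(beta_c, "beta_c")
  check_probability(beta_pc, "beta_pc", allow_one = FALSE)
  if (1 - beta_c <= alpha_c) {
    abort_targetodds(
      "Infeasible scenario: clinical power (1 - beta_c) must exceed alpha_c.",
      "targetodds_infeasible")
  }
  if (s_c < alpha_c) {
    abort_targetodds(
      "Infeasible scenario: observed s_c < alpha_c implies a negative truth fraction.",
      "targetodds_infeasible")
  }
  gamma_c <- (s_c - alpha_c) / ((1 - beta_c) - alpha_c)
  gamma_pc <- gamma_c * s_pc / (1 - beta_pc)
  if (gamma_pc >= 1) {
    abort_targetodds(
      "Infeasible scenario: implied gamma_pc >= 1; observed rates are inconsistent with the assumed powers.",
      "targetodds_infeasible")
  }
  alpha_pc <- (s_pc - gamma_pc * (1 - beta_pc)) / (1 - gamma_pc)
  if (alpha_pc < 0 || alpha_pc > 1) {
    abort_targetodds(
      "Infeasible scenario: implied alpha_pc outside [0, 1].",
      "targetodds_infeasible")
  }
  structure(
    list(
      gamma_c = gamma_c, gamma_pc = gamma_pc,
      alpha_pc = alpha_pc,
      fdr_pc = alpha_pc * (1 - gamma_pc) / s_pc,
      s_pc = s_pc, s_c = s_c,
      alpha_c = alpha_c, beta_c = beta_c, beta_pc = beta_pc
    ),
    class = "back_calc"
  )
}

#' @export
print.back_calc <- function(x, ...) {
  cat("Back-calculated two-stage parameters\n")
  cat(sprintf("  observed S_pc = %.4g, S_c = %.4g (alpha_c = %.3g, power_c = %.3g, power_pc = %.3g)\n",
              x$s_pc, x$s_c, x$alpha_c, 1 - x$beta_c, 1 - x$beta_pc))
  cat(sprintf("  gamma_c = %.4g, gamma_pc = %.4g, alpha_pc = %.4g, FDR_pc = %.4g\n",
              x$gamma_c, x$gamma_pc, x$alpha_pc, x$fdr_pc))
  invisible(x)
}

#' Back-calculation sweep over assumed preclinical power
#'
#' Repeats [back_calculate()] for a grid of preclinical power values at
#' fixed observed success rates, tracing how the inferred prior truth
#' fraction and false-positive rate depend on the assumed power.
#'
#' @inheritParams back_calculate
#' @param power_pc Preclinical power values to sweep (default 0.2 to 0.8 in
#'   steps of 0.05).
#' @return A tibble with columns `power_pc`, `gamma_c`, `gamma_pc`,
#'   `alpha_pc`, `fdr_pc`.
#' @examples
#' back_calculate_sweep(s_pc = 0.4, s_c = 0.1)
#' @export
back_calculate_sweep <- function(s_pc, s_c, alpha_c = 0.05, beta_c = 0.2,
                                 power_pc = seq(0.2, 0.8, by = 0.05)) {
  purrr::map_dfr(power_pc, function(pw) {
    bc <- back_calculate(s_pc, s_c, alpha_c, beta_c, beta_pc = 1 - pw)
    tibble::tibble(power_pc = pw, gamma_c = bc$gamma_c,
                   gamma_pc = bc$gamma_pc, alpha_pc = bc$alpha_pc,
                   fdr_pc = bc$fdr_pc)
  })
}

#' Enrichment of the studied truth fraction over a random pick
#'
#' Ratio of a back-calculated prior truth fraction to the baseline truth
#' fraction of a random pick from the sample space.
#'
#' @param gamma_pc Back-calculated prior truth fraction(s).
#' @param baseline_gamma Baseline truth fraction, e.g. [p_causal()] of the
#'   druggable-genome-restricted space (0.005 under the defaults).
#' @return Fold enrichment (positive real).
#' @export
enrichment_factor <- function(gamma_pc, baseline_gamma) {
  check_probability(gamma_pc, "gamma_pc")
  check_probability(baseline_gamma, "baseline_gamma", allow_zero = FALSE)
  gamma_pc / baseline_gamma
}

#' Default development scenarios: orthodox vs genomic target identification
#'
#' Builds the canonical 12-scenario grid: three values of the average number
#' of causal genes per disease (10, 100, 1000), crossed with the sampling
#' frame (panel `"a"`: whole genome, so
#' `gamma_pc = (C / n_genes) * (n_druggable / n_genes)`; panel `"b"`:
#' druggable genome, so `gamma_pc = C / n_genes`) and with the stage-1
#' approach (`"orthodox"` preclinical testing at `alpha_pc = 0.05` vs
#' `"genomic"` association testing at `alpha_pc = 5e-8`). Clinical-stage
#' parameters are fixed at `alpha_c = 0.05`, `beta_c = 0.2`.
#'
#' @param space A [sample_space()] providing the genome dimensions.
#' @param causal_per_disease Values of the average causal gene count to sweep.
#' @return A tibble of labelled scenarios, one per row.
#' @export
development_scenarios <- function(space = sample_space(),
                                  causal_per_disease = c(10, 100, 1000)) {
  check_space(space)
  grid <- tidyr::expand_grid(
    panel = c("a", "b"),
    causal_per_disease = causal_per_disease,
    approach = c("orthodox", "genomic")
  )
  dplyr::mutate(
    grid,
    gamma_pc = ifelse(panel == "a",
                      (causal_per_disease / space$n_genes) *
                        (space$n_druggable / space$n_genes),
                      causal_per_disease / space$n_genes),
    alpha_pc = ifelse(approach == "orthodox", 0.05, 5e-8),
    beta_pc = 0.2,
    alpha_c = 0.05,
    beta_c = 0.2
  )
}

#' Run the two-stage model over a table of scenarios
#'
#' Data-frame-first sweep: each row must carry `gamma_pc`, `alpha_pc`,
#' `beta_pc`, `alpha_c`, `beta_c` (as produced by [development_scenarios()]);
#' any other columns are kept as labels. Adds the per-stage discovery rates
#' and declared success rates of [two_stage()]. A row whose parameters are
#' infeasible gets `NA` results and the error message in `error` instead of
#' failing the whole sweep.
#'
#' @param scenarios A data frame of scenarios; defaults to
#'   [development_scenarios()].
#' @return A tibble with the input columns plus `fdr_pc`, `s_pc`, `tdr_pc`
#'   (= `gamma_c`), `fdr_c`, `tdr_c`, `s_c`, `s_o` and `error`.
#' @examples
#' development_sweep()
#' @export
development_sweep <- function(scenarios = development_scenarios()) {
  if (!is.data.frame(scenarios)) {
    abort_targetodds("`scenarios` must be a data frame.",
                     "targetodds_invalid_argument")
  }
  needed <- c("gamma_pc", "alpha_pc", "beta_pc", "alpha_c", "beta_c")
  missing <- setdiff(needed, names(scenarios))
  if (length(missing)) {
    abort_targetodds(paste0("`scenarios` is missing columns: ",
                            paste(missing, collapse = ", ")),
                     "targetodds_invalid_argument")
  }
  results <- purrr::pmap_dfr(
    scenarios[needed],
    function(gamma_pc, alpha_pc, beta_pc, alpha_c, beta_c) {
      tryCatch({
        fit <- two_stage(gamma_pc, alpha_pc, beta_pc, alpha_c, beta_c)
        tibble::tibble(
          fdr_pc = fit$preclinical$fdr, s_pc = fit$s_pc,
          tdr_pc = fit$preclinical$tdr,
          fdr_c = fit$clinical$fdr, tdr_c = fit$clinical$tdr,
          s_c = fit$s_c, s_o = fit$s_o, error = NA_character_
        )
      }, targetodds_error = function(e) {
        tibble::tibble(fdr_pc = NA_real_, s_pc = NA_real_, tdr_pc = NA_real_,
                       fdr_c = NA_real_, tdr_c = NA_real_, s_c = NA_real_,
                       s_o = NA_real_, error = conditionMessage(e))
      })
    })
  dplyr::bind_cols(tibble::as_tibble(scenarios), results)
}
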