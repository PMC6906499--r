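#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-stage model fit
#'
#' @param x A [two_stage()] object.
#' @param ... Unused.
#' @return One row per stage with the confusion rates.
#' @method tidy two_stage
#' @export
tidy.two_stage <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(stage = c("preclinical", "clinical")),
    dplyr::bind_rows(x$preclinical, x$clinical)
  )
}

#' @rdname tidy.two_stage
#' @method glance two_stage
#' @export
glance.two_stage <- function(x, ...) {
  tibble::tibble(
    gamma_pc = x$gamma_pc,
    gamma_c = x$gamma_c,
    fdr_pc = x$preclinical$fdr,
    fdr_c = x$clinical$fdr,
    tdr_c = x$clinical$tdr,
    s_pc = x$s_pc,
    s_c = x$s_c,
    s_o = x$s_o
  )
}

#' Tidy a back-calculation result
#'
#' @param x A [back_calculate()] object.
#' @param ... Unused.
#' @return `tidy()`: a term/estimate tibble of the inferred quantities;
#'   `glance()`: a one-row tibble including the observed inputs.
#' @method tidy back_calc
#' @export
tidy.back_calc <- function(x, ...) {
  tibble::tibble(
    term = c("gamma_c", "gamma_pc", "alpha_pc", "fdr_pc"),
    estimate = c(x$gamma_c, x$gamma_pc, x$alpha_pc, x$fdr_pc)
  )
}

#' @rdname tidy.back_calc
#' @method glance back_calc
#' @export
glance.back_calc <- function(x, ...) {
  tibble::tibble(
    s_pc = x$s_pc, s_c = x$s_c,
    alpha_c = x$alpha_c, beta_c = x$beta_c, beta_pc = x$beta_pc,
    gamma_c = x$gamma_c, gamma_pc = x$gamma_pc,
    alpha_pc = x$alpha_pc, fdr_pc = x$fdr_pc
  )
}

#' Tidy a GWAS druggable-yield result
#'
#' @param x A [druggable_yield()] object.
#' @param ... Unused.
#' @return `tidy()`: the detection-count pmf; `glance()`: the one-row
#'   summary.
#' @method tidy druggable_yield
#' @export
tidy.druggable_yield <- function(x, ...) {
  tibble::as_tibble(x$pmf)
}

#' @rdname tidy.druggable_yield
#' @method glance druggable_yield
#' @export
glance.druggable_yield <- function(x, ...) {
  out <- tibble::tibble(n_ct = x$n_ct, e_ct = x$e_ct, sd_ct = x$sd_ct,
                        power = 1 - x$beta)
  if (!is.null(x$p_below)) {
    out$below <- x$below
    out$p_below <- x$p_below
  }
  out
}
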