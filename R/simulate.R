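#' Generate a synthetic gene-by-disease causal world
#'
#' Draws one realisation of the causal structure the analytic formulas
#' assume: a binary gene-by-disease incidence matrix plus an independent
#' druggable label per gene. In `"fixed"` mode (the default, matching the
#' exact-count reasoning of the base case) every disease receives exactly
#' `causal_per_disease` causal genes drawn uniformly without replacement; in
#' `"bernoulli"` mode every cell is causal independently with probability
#' `causal_per_disease / n_genes`. Druggable genes are a uniform
#' `n_druggable`-subset, independent of causality.
#'
#' @param space A [sample_space()]. Simulations are typically run with a
#'   scaled-down disease count (e.g. 100) since the analytic quantities are
#'   invariant to it.
#' @param mode Causal assignment mode, `"fixed"` or `"bernoulli"`.
#' @param seed Optional integer seed; the same seed reproduces the world
#'   bit-for-bit and the caller's random stream is left untouched.
#' @return An object of class `causal_world` with elements `space`, `mode`,
#'   `seed`, `causal` (logical genes x diseases matrix) and `druggable`
#'   (logical per-gene vector).
#' @examples
#' world <- generate_world(sample_space(n_diseases = 20), seed = 1)
#' colSums(world$causal)[1:3]
#' @export
generate_world <- function(space, mode = c("fixed", "bernoulli"),
                           seed = NULL) {
  check_space(space)
  mode <- match.arg(mode)
  n_g <- as.integer(space$n_genes)
  n_d <- as.integer(space$n_diseases)
  cbar <- space$causal_per_disease
  if (mode == "fixed" && cbar != round(cbar)) {
    abort_targetodds(
      "Fixed-count worlds need an integer `causal_per_disease`.",
      "targetodds_invalid_argument")
  }
  with_seed(seed, {
    causal <- matrix(FALSE, nrow = n_g, ncol = n_d)
    if (mode == "fixed") {
      for (j in seq_len(n_d)) {
        causal[sample.int(n_g, as.integer(cbar)), j] <- TRUE
      }
    } else {
      causal[] <- stats::runif(n_g * n_d) < cbar / n_g
    }
    druggable <- logical(n_g)
    druggable[sample.int(n_g, as.integer(space$n_druggable))] <- TRUE
    structure(
      list(space = space, mode = mode, seed = seed,
           causal = causal, druggable = druggable),
      class = "causal_world"
    )
  })
}

#' @export
print.causal_world <- function(x, ...) {
  cat(sprintf("Synthetic causal world (%s mode): %d genes x %d diseases\n",
              x$mode, nrow(x$causal), ncol(x$causal)))
  cat(sprintf("  causal cells: %d (fraction %.4g); druggable genes: %d\n",
              sum(x$causal), mean(x$causal), sum(x$druggable)))
  invisible(x)
}

world_truth <- function(world, truth = c("causal", "causal_druggable")) {
  if (!inherits(world, "causal_world")) {
    abort_targetodds("`world` must be created with `generate_world()`.",
                     "targetodds_invalid_argument")
  }
  truth <- match.arg(truth)
  n_true <- if (truth == "causal") {
    sum(world$causal)
  } else {
    sum(world$causal[world$druggable, , drop = FALSE])
  }
  list(truth = truth, n_true = n_true,
       n_pairs = length(world$causal))
}

#' Stochastic replay of a discovery experiment over a synthetic world
#'
#' Declares every gene-disease pair of the world positive with probability
#' `1 - beta` if it is a true relationship and `alpha` otherwise, and
#' summarises the realised confusion table. The prior truth fraction is
#' taken from the world itself (its realised causal or causal-and-druggable
#' fraction), so the empirical discovery rates are directly comparable with
#' [confusion()] evaluated at `gamma_hat`.
#'
#' @param world A [generate_world()] result.
#' @param alpha,beta Per-pair false-positive and false-negative rates.
#' @param truth Which label counts as a true relationship: `"causal"` or
#'   `"causal_druggable"`.
#' @param seed Optional seed for the test-level randomness.
#' @return A one-row tibble with the realised counts (`tp`, `fp`), the
#'   empirical rates (`s_hat`, `tdr_hat`, `fdr_hat`), the world's realised
#'   truth fraction `gamma_hat`, and binomial standard errors `se_s` and
#'   `se_fdr`.
#' @export
simulate_discovery <- function(world, alpha = 0.05, beta = 0.2,
                               truth = c("causal", "causal_druggable"),
                               seed = NULL) {
  tr <- world_truth(world, truth)
  check_probability(alpha, "alpha")
  check_probability(beta, "beta")
  with_seed(seed, {
    tp <- stats::rbinom(1, tr$n_true, 1 - beta)
    fp <- stats::rbinom(1, tr$n_pairs - tr$n_true, alpha)
    declared <- tp + fp
    fdr_hat <- if (declared > 0) fp / declared else NA_real_
    s_hat <- declared / tr$n_pairs
    tibble::tibble(
      truth = tr$truth,
      n_pairs = tr$n_pairs,
      gamma_hat = tr$n_true / tr$n_pairs,
      tp = tp, fp = fp,
      s_hat = s_hat,
      tdr_hat = 1 - fdr_hat,
      fdr_hat = fdr_hat,
      se_s = sqrt(s_hat * (1 - s_hat) / tr$n_pairs),
      se_fdr = if (declared > 0) sqrt(fdr_hat * (1 - fdr_hat) / declared) else NA_real_
    )
  })
}

#' Stochastic replay of the two-stage development pipeline
#'
#' Runs the stage-1 discovery replay over every pair of the world, then
#' applies the clinical stage only to stage-1 declared positives: surviving
#' true positives are binomial with success `1 - beta_c`, surviving false
#' positives with success `alpha_c`. Empirical success rates correspond to
#' [two_stage()] evaluated at the world's realised truth fraction.
#'
#' @inheritParams simulate_discovery
#' @param alpha_pc,beta_pc,alpha_c,beta_c Stage error rates.
#' @return A one-row tibble with empirical `s_pc_hat`, `gamma_c_hat`
#'   (stage-2 truth fraction among advanced pairs), `s_c_hat`, `s_o_hat`
#'   and the standard error `se_s_o`.
#' @export
simulate_two_stage <- function(world, alpha_pc = 0.05, beta_pc = 0.2,
                               alpha_c = 0.05, beta_c = 0.2,
                               truth = c("causal", "causal_druggable"),
                               seed = NULL) {
  tr <- world_truth(world, truth)
  check_probability(alpha_pc, "alpha_pc")
  check_probability(beta_pc, "beta_pc")
  check_probability(alpha_c, "alpha_c")
  check_probability(beta_c, "beta_c")
  with_seed(seed, {
    tp_pc <- stats::rbinom(1, tr$n_true, 1 - beta_pc)
    fp_pc <- stats::rbinom(1, tr$n_pairs - tr$n_true, alpha_pc)
    advanced <- tp_pc + fp_pc
    tp_c <- stats::rbinom(1, tp_pc, 1 - beta_c)
    fp_c <- stats::rbinom(1, fp_pc, alpha_c)
    s_o_hat <- (tp_c + fp_c) / tr$n_pairs
    tibble::tibble(
      truth = tr$truth,
      n_pairs = tr$n_pairs,
      gamma_hat = tr$n_true / tr$n_pairs,
      s_pc_hat = advanced / tr$n_pairs,
      gamma_c_hat = if (advanced > 0) tp_pc / advanced else NA_real_,
      s_c_hat = if (advanced > 0) (tp_c + fp_c) / advanced else NA_real_,
      s_o_hat = s_o_hat,
      se_s_o = sqrt(s_o_hat * (1 - s_o_hat) / tr$n_pairs)
    )
  })
}

#' Monte-Carlo frequency of k diseases sharing no causal gene
#'
#' Repeatedly draws `k` independent causal gene sets of size
#' `causal_per_disease` from the genome and records how often all `k` are
#' pairwise disjoint, the quantity approximated analytically by
#' [prob_no_shared_gene_chain()].
#'
#' @param space A [sample_space()] with integer `causal_per_disease`.
#' @param k Number of diseases per replicate.
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Optional seed.
#' @return A one-row tibble with `p_hat`, its standard error `se`, and the
#'   replicate count.
#' @export
simulate_shared_targets <- function(space, k, replicates = 10000,
                                    seed = NULL) {
  check_space(space)
  k <- check_count(k, "k")
  replicates <- check_count(replicates, "replicates")
  cbar <- space$causal_per_disease
  if (cbar != round(cbar)) {
    abort_targetodds("`causal_per_disease` must be integer-valued to draw causal sets.",
                     "targetodds_invalid_argument")
  }
  n_g <- as.integer(space$n_genes)
  cbar <- as.integer(cbar)
  if (k == 1) {
    return(tibble::tibble(p_hat = 1, se = 0, replicates = replicates))
  }
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(replicates)) {
      draws <- unlist(lapply(seq_len(k), function(i) sample.int(n_g, cbar)),
                      use.names = FALSE)
      if (!anyDuplicated(draws)) hits <- hits + 1L
    }
    p_hat <- hits / replicates
    tibble::tibble(p_hat = p_hat,
                   se = sqrt(p_hat * (1 - p_hat) / replicates),
                   replicates = replicates)
  })
}

#' Monte-Carlo replay of the portfolio draw-test-advance model
#'
#' Stochastic counterpart of [development_success_prob()]: each replicate
#' draws `n_programmes` targets without replacement from the frame, tests
#' each (power `1 - beta` for causal targets, false-positive rate `alpha`
#' otherwise), advances one uniformly chosen nominal positive, and scores a
#' success when the advanced target is truly causal.
#'
#' @inheritParams development_success_prob
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Optional seed.
#' @return A one-row tibble with `p_hat`, `se` and `replicates`.
#' @export
simulate_portfolio <- function(frame_size, n_causal, n_programmes,
                               alpha = 0.05, beta = 0.2,
                               replicates = 10000, seed = NULL) {
  p <- check_portfolio(frame_size, n_causal, n_programmes)
  check_probability(alpha, "alpha")
  check_probability(beta, "beta")
  replicates <- check_count(replicates, "replicates")
  with_seed(seed, {
    a <- stats::rhyper(replicates, p$n_causal, p$frame_size - p$n_causal,
                       p$n_programmes)
    tp <- stats::rbinom(replicates, a, 1 - beta)
    fp <- stats::rbinom(replicates, p$n_programmes - a, alpha)
    pos <- tp + fp
    # uniform choice among nominal positives: success w.p. tp/pos
    success <- pos > 0 & stats::runif(replicates) * pos < tp
    p_hat <- mean(success)
    tibble::tibble(p_hat = p_hat,
                   se = sqrt(p_hat * (1 - p_hat) / replicates),
                   replicates = replicates)
  })
}
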