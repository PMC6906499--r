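# Module tests run on a scaled-down world (2,000 genes x 50 diseases); the
# analytic targets are scale-invariant in the disease count.
small_space <- function() {
  sample_space(n_genes = 2000, n_diseases = 50, n_druggable = 400,
               causal_per_disease = 10)
}

test_that("fixed-count worlds have exactly C causal genes per disease and are seed-reproducible", {
  s <- small_space()
  w1 <- generate_world(s, seed = 11)
  w2 <- generate_world(s, seed = 11)
  expect_identical(w1$causal, w2$causal)
  expect_identical(w1$druggable, w2$druggable)
  expect_true(all(colSums(w1$causal) == 10))
  expect_equal(sum(w1$druggable), 400)
  w3 <- generate_world(s, seed = 12)
  expect_false(identical(w1$causal, w3$causal))
})

test_that("bernoulli worlds hit the causal rate in expectation", {
  s <- small_space()
  w <- generate_world(s, mode = "bernoulli", seed = 21)
  n <- length(w$causal)
  p <- p_causal(s)
  expect_lt(abs(mean(w$causal) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the causal-and-druggable cell fraction matches the product of independent rates", {
  s <- small_space()
  w <- generate_world(s, seed = 31)
  frac <- mean(w$causal[w$druggable, ])
  # per-disease overlap of the C causal genes with the druggable set is
  # hypergeometric; aggregate 3-SE band over all diseases
  nd <- s$n_diseases
  m <- s$causal_per_disease * p_druggable(s)
  v <- s$causal_per_disease * p_druggable(s) * (1 - p_druggable(s)) *
    (s$n_genes - s$causal_per_disease) / (s$n_genes - 1)
  se_frac <- sqrt(nd * v) / (s$n_druggable * nd)
  expect_lt(abs(frac - p_causal_druggable(s) / p_druggable(s)), 3 * se_frac)
})

test_that("replayed discovery matches the analytic confusion table at the world's truth fraction", {
  s <- small_space()
  w <- generate_world(s, seed = 41)
  sim <- simulate_discovery(w, alpha = 0.05, beta = 0.2, seed = 42)
  expect_equal(sim$gamma_hat, p_causal(s)) # fixed-count construction
  analytic <- confusion(sim$gamma_hat, 0.05, 0.2)
  expect_lt(abs(sim$fdr_hat - analytic$fdr), 3 * sim$se_fdr)
  expect_lt(abs(sim$s_hat - analytic$declared_success), 3 * sim$se_s)
  # degenerate corners
  expect_equal(simulate_discovery(w, alpha = 0, beta = 0.2, seed = 43)$fp, 0L)
  expect_equal(simulate_discovery(w, alpha = 0.05, beta = 1, seed = 44)$tdr_hat, 0)
})

test_that("replayed two-stage pipeline matches the forward model within Monte-Carlo error", {
  s <- small_space()
  w <- generate_world(s, seed = 51)
  sim <- simulate_two_stage(w, truth = "causal_druggable", seed = 52)
  analytic <- two_stage(sim$gamma_hat, 0.05, 0.2, 0.05, 0.2)
  expect_lt(abs(sim$s_o_hat - analytic$s_o), 3 * sim$se_s_o)
  perfect <- simulate_two_stage(w, alpha_pc = 0, beta_pc = 0, seed = 53)
  expect_equal(perfect$gamma_c_hat, 1)
})

test_that("empirical shared-gene frequency matches the chained hypergeometric product", {
  s <- small_space() # 10 causal genes from 2,000: sharing is non-trivial
  expect_equal(simulate_shared_targets(s, 1, replicates = 10, seed = 61)$p_hat, 1)
  for (k in 2:4) {
    sim <- simulate_shared_targets(s, k, replicates = 4000, seed = 60 + k)
    expect_lt(abs(sim$p_hat - prob_no_shared_gene_chain(s, k)),
              3 * pmax(sim$se, 1e-4))
  }
})

test_that("portfolio replay agrees with the exact draw-test-advance sum", {
  expect_equal(simulate_portfolio(30, 30, 10, beta = 0, replicates = 500,
                                  seed = 71)$p_hat, 1)
  expect_equal(simulate_portfolio(30, 0, 10, replicates = 500,
                                  seed = 72)$p_hat, 0)
  sim <- simulate_portfolio(4000, 20, 50, replicates = 40000, seed = 73)
  expect_lt(abs(sim$p_hat - development_success_prob(4000, 20, 50)),
            3 * sim$se)
})

test_that("seeded simulations leave the caller's random stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_world(small_space(), seed = 5))
  invisible(simulate_portfolio(100, 10, 5, replicates = 100, seed = 6))
  expect_identical(.Random.seed, before)
})
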