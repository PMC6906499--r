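test_that("parallel programme counts match the worked examples", {
  expect_identical(n_programmes_needed(0.02, 0.9), 114L)
  expect_identical(n_programmes_needed(0.99, 0.9), 1L)
  # the quoted evens-chance count rounds the real-valued solution
  expect_identical(n_programmes_needed(0.02, 0.5, rounding = "nearest"), 34L)
  expect_error(n_programmes_needed(0, 0.9), class = "targetodds_unattainable")
})

test_that("programme count is the smallest integer attaining the confidence", {
  set.seed(404)
  for (i in 1:100) {
    p <- runif(1, 0.005, 0.8)
    conf <- runif(1, 0.05, 0.995)
    n <- n_programmes_needed(p, conf)
    expect_gte(1 - (1 - p)^n, conf)
    if (n > 1) expect_lt(1 - (1 - p)^(n - 1), conf)
  }
  # non-increasing in p, non-decreasing in confidence
  expect_gte(n_programmes_needed(0.02, 0.9), n_programmes_needed(0.05, 0.9))
  expect_gte(n_programmes_needed(0.02, 0.95), n_programmes_needed(0.02, 0.9))
})

test_that("hypergeometric portfolio pmf matches brute-force products and enumeration", {
  pmf <- causal_in_sample_pmf(4000, 20, 20)
  # P(no causal target drawn) as the telescoping product of miss probabilities
  expect_equal(pmf$prob[1], prod((3980 - 0:19) / (4000 - 0:19)),
               tolerance = 1e-12)
  expect_printed(pmf$prob[1], "0.904")
  expect_equal(sum(causal_in_sample_pmf(4000, 20, 200)$prob), 1,
               tolerance = 1e-12)
  # every member of an all-causal frame is causal
  all_causal <- causal_in_sample_pmf(15, 15, 6)
  expect_equal(all_causal$prob[all_causal$n_causal_drawn == 6], 1)
  # exhaustive enumeration on a small frame
  for (cs in list(c(10, 3, 4), c(12, 5, 6), c(8, 8, 3))) {
    expect_equal(causal_in_sample_pmf(cs[1], cs[2], cs[3])$prob,
                 oracle_hyper_pmf(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
})

test_that("expected causal targets in the portfolio follow the finite-population moments", {
  expect_equal(expected_causal_in_sample(4000, 20, 200)$mean, 1)
  exhaustive <- expected_causal_in_sample(4000, 20, 4000)
  expect_equal(exhaustive$mean, 20)
  expect_equal(exhaustive$sd, 0)
  m50 <- expected_causal_in_sample(4000, 20, 50)
  expect_equal(m50$mean, 0.25)
  # cross-check both moments against the exact pmf
  pmf <- causal_in_sample_pmf(4000, 20, 50)
  expect_equal(m50$mean, sum(pmf$n_causal_drawn * pmf$prob), tolerance = 1e-12)
  expect_equal(m50$sd,
               sqrt(sum(pmf$n_causal_drawn^2 * pmf$prob) -
                      sum(pmf$n_causal_drawn * pmf$prob)^2),
               tolerance = 1e-12)
  expect_printed(m50$sd, "0.496")
})

test_that("draw-test-advance success probability matches exhaustive and Monte-Carlo oracles", {
  # degenerate corners
  expect_equal(development_success_prob(15, 15, 6, beta = 0), 1)
  expect_equal(development_success_prob(4000, 0, 50), 0)
  # tiny-frame exhaustive enumeration over portfolios and test outcomes
  expect_equal(development_success_prob(6, 2, 3, alpha = 0.3, beta = 0.25),
               oracle_dev_success(6, 2, 3, 0.3, 0.25), tolerance = 1e-10)
  expect_equal(development_success_prob(5, 3, 2, alpha = 0.1, beta = 0.4),
               oracle_dev_success(5, 3, 2, 0.1, 0.4), tolerance = 1e-10)
  # frozen independent Monte-Carlo estimate (1e6 replicates, seed 424242):
  # p_hat = 0.069955, SE = 2.551e-4
  expect_lt(abs(development_success_prob(4000, 20, 50) - 0.069955),
            3 * 2.551e-4)
})

test_that("portfolio success improves only modestly with more programmes from a large frame", {
  p <- vapply(c(20, 50, 200),
              function(n) development_success_prob(4000, 20, n), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_lt(p[3], 0.35) # even 200 parallel programmes leave success unlikely
})

test_that("true positives outnumber false positives only in small sampling frames", {
  mix <- expected_positive_mix(4000, 20, 200)
  expect_equal(mix$expected_tp, 0.8)
  expect_equal(mix$expected_fp, 9.95)
  mix400 <- expected_positive_mix(400, 20, 400)
  expect_equal(mix400$expected_tp, 16)
  expect_equal(mix400$expected_fp, 19)
  expect_false(mix400$expected_tp > mix400$expected_fp)
  expect_equal(expected_positive_mix(400, 20, 400, alpha = 0)$expected_fp, 0)
  # the break-even frame is below the ~400-target figure
  frontier <- equal_positives_frame(20)
  expect_equal(frontier, 340)
  expect_lt(frontier, 400)
  small <- expected_positive_mix(300, 20, 300)
  expect_gt(small$expected_tp, small$expected_fp)
})
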