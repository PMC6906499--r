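test_that("forward model reproduces the orthodox and genomic base cases", {
  orth <- two_stage(gamma_pc = 0.001, alpha_pc = 0.05, beta_pc = 0.2)
  expect_printed(orth$preclinical$tdr, "0.016")
  expect_printed(orth$preclinical$fdr, "0.984")
  expect_printed(orth$s_pc, "0.05075")
  expect_printed(orth$clinical$tdr, "0.204")
  expect_printed(orth$s_o, "0.003")

  gen <- two_stage(gamma_pc = 0.001, alpha_pc = 5e-8, beta_pc = 0.2)
  expect_printed(gen$s_c, "0.79995")
  expect_printed(gen$s_o, "0.00064")

  none <- two_stage(gamma_pc = 0, alpha_pc = 0.05)
  expect_equal(none$preclinical$tdr, 0)
  expect_equal(none$gamma_c, 0)
  expect_equal(none$clinical$tdr, 0)
})

test_that("clinical TDR closed form equals two composed confusion tables", {
  expect_printed(tdr_clinical(0.001), "0.20398406")
  expect_printed(tdr_clinical(0.01), "0.72112676")
  expect_equal(tdr_clinical(0.3, alpha_c = 0, alpha_pc = 0), 1)
  set.seed(303)
  for (i in 1:100) {
    gp <- runif(1, 1e-4, 0.99)
    ap <- runif(1, 1e-8, 0.5); ac <- runif(1, 1e-4, 0.5)
    bp <- runif(1, 0, 0.9); bc <- runif(1, 0, 0.9)
    expect_equal(tdr_clinical(gp, ap, bp, ac, bc),
                 two_stage(gp, ap, bp, ac, bc)$clinical$tdr,
                 tolerance = 1e-12)
  }
  expect_error(tdr_clinical(0), class = "targetodds_undefined_rate")
})

test_that("clinical TDR is monotone in the prior and the false-positive rates", {
  set.seed(304)
  for (i in 1:50) {
    gp <- runif(1, 0.01, 0.9); ap <- runif(1, 0.01, 0.4)
    ac <- runif(1, 0.01, 0.4); eps <- 0.005
    base <- tdr_clinical(gp, ap, alpha_c = ac)
    expect_gt(tdr_clinical(gp + eps, ap, alpha_c = ac), base)
    expect_lt(tdr_clinical(gp, ap + eps, alpha_c = ac), base)
    expect_lt(tdr_clinical(gp, ap, alpha_c = ac + eps), base)
  }
})

test_that("back-calculation recovers the published a posteriori estimates", {
  bc <- back_calculate(s_pc = 0.4, s_c = 0.1, alpha_c = 0.05, beta_c = 0.2,
                       beta_pc = 0.2)
  expect_equal(bc$gamma_c, 0.05 / 0.75, tolerance = 1e-12)
  expect_lt(abs(bc$gamma_c - 0.0667), 1e-4)
  # printed 0.03335 carries the rounded gamma_c = 0.0667 forward
  expect_lt(abs(bc$gamma_pc - 0.03335), 1e-3)
  expect_lt(abs(bc$alpha_pc - 0.386), 1e-3)
  expect_lt(abs(bc$fdr_pc - 0.933), 1e-3)
  # success observed at exactly the false-positive rate: nothing true
  expect_equal(back_calculate(0.4, 0.05)$gamma_c, 0)
})

test_that("back-calculation and the forward model are mutually inverse", {
  set.seed(305)
  for (i in 1:100) {
    ac <- runif(1, 0.01, 0.3); bc_ <- runif(1, 0.05, 0.6)
    bp <- runif(1, 0.05, 0.6)
    s_c <- runif(1, ac + 0.01, 1 - bc_)
    s_pc <- runif(1, 0.05, 0.95)
    inv <- tryCatch(back_calculate(s_pc, s_c, ac, bc_, bp),
                    targetodds_error = function(e) NULL)
    if (is.null(inv)) next
    fwd <- two_stage(inv$gamma_pc, inv$alpha_pc, bp, ac, bc_)
    expect_equal(fwd$s_pc, s_pc, tolerance = 1e-9)
    expect_equal(fwd$s_c, s_c, tolerance = 1e-9)
    expect_equal(fwd$gamma_c, inv$gamma_c, tolerance = 1e-9)
  }
})

test_that("infeasible observed rates raise structured errors, not clipped values", {
  expect_error(back_calculate(0.4, 0.04, alpha_c = 0.05),
               class = "targetodds_infeasible")
  expect_error(back_calculate(0.4, 0.1, alpha_c = 0.5, beta_c = 0.6),
               class = "targetodds_infeasible")
})

test_that("power sweep brackets the inferred prior truth fraction and its enrichment", {
  sw <- back_calculate_sweep(s_pc = 0.4, s_c = 0.1)
  expect_equal(nrow(sw), 13)
  expect_lt(abs(min(sw$gamma_pc) - 0.033), 5e-4)
  expect_lt(abs(max(sw$gamma_pc) - 0.133), 5e-4)
  enr <- enrichment_factor(range(sw$gamma_pc), baseline_gamma = 0.005)
  expect_printed(enr[1], "6.67")
  expect_printed(enr[2], "26.7")
  expect_equal(enrichment_factor(0.03335, 0.005), 6.67)
  expect_equal(enrichment_factor(0.42, 0.42), 1)
})

test_that("the default development sweep covers both panels and collects per-row errors", {
  sw <- development_sweep()
  expect_equal(nrow(sw), 12)
  expect_true(all(is.na(sw$error)))
  expect_equal(sw$s_o, sw$s_pc * sw$s_c, tolerance = 1e-12)
  expect_equal(sw$tdr_c,
               tdr_clinical(sw$gamma_pc, sw$alpha_pc, sw$beta_pc,
                            sw$alpha_c, sw$beta_c),
               tolerance = 1e-12)
  # degenerate scenario rows are reported, not fatal
  bad <- development_sweep(tibble::tibble(
    label = c("ok", "undefined"),
    gamma_pc = c(0.001, 0), alpha_pc = c(0.05, 0), beta_pc = 0.2,
    alpha_c = 0.05, beta_c = 0.2))
  expect_true(is.na(bad$error[1]))
  expect_false(is.na(bad$error[2]))
  expect_true(is.na(bad$s_o[2]))
})
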