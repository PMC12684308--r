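test_that("delta reproduces the published productivity arithmetic", {
  expect_equal(delta_from_means(90.60, 55.09, 0.25), 1.990, tolerance = 5e-4)
  expect_equal(delta_from_means(65.58, 53.35, 0.25), 0.826, tolerance = 5e-4)
  expect_equal(delta_from_means(70, 70, 0.25), 0)
})

test_that("estimate_delta works on records and carries scheme summaries", {
  out <- tibble::tibble(pupae_count = c(80, 100, 90))
  inb <- tibble::tibble(pupae_count = c(50, 60))
  e <- estimate_delta(out, inb, F = 0.25)
  expect_equal(e$P_O, 90)
  expect_equal(e$P_I, 55)
  expect_equal(e$delta, log(90 / 55) / 0.25)
  expect_equal(e$n_outbred, 3)
  td <- tidy(e)
  expect_equal(td$estimate, e$delta)
  expect_error(estimate_delta(numeric(0), inb), "non-empty")
  expect_error(estimate_delta(out, inb, F = 0), "positive")
  expect_error(estimate_delta(c(0, 0), c(1, 2)), "undefined")
})

test_that("delta is antisymmetric under scheme swap and scale invariant", {
  set.seed(11)
  for (i in 1:5) {
    a <- rpois(20, 80) + 1
    b <- rpois(25, 55) + 1
    d1 <- estimate_delta(a, b, 0.25)$delta
    expect_equal(estimate_delta(b, a, 0.25)$delta, -d1)
    expect_equal(estimate_delta(3.7 * a, 3.7 * b, 0.25)$delta, d1)
  }
})

test_that("bootstrap SE is zero for constant data and deterministic by seed", {
  expect_equal(as.numeric(bootstrap_delta_se(rep(80, 10), rep(60, 10),
                                             seed = 4)), 0)
  a <- rpois(30, 80); b <- rpois(30, 60)
  s1 <- bootstrap_delta_se(a, b, n_boot = 200, seed = 42)
  s2 <- bootstrap_delta_se(a, b, n_boot = 200, seed = 42)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_error(bootstrap_delta_se(a, b, n_boot = 1), "at least 2")
})

test_that("delta recovery from the generative model is unbiased at assay size", {
  true_delta <- 1.2
  ests <- vapply(1:200, function(i) {
    rec <- simulate_productivity(80, 80, mean_outbred = 85,
                                 delta = true_delta, seed = 5000 + i)
    estimate_delta(rec[rec$scheme == "outbred", ],
                   rec[rec$scheme == "inbred", ], 0.25)$delta
  }, numeric(1))
  bias <- mean(ests) - true_delta
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(bias), 2 * se_mean + 1e-8)
})

test_that("expected inbreeding follows the drift recursion", {
  expect_equal(expected_inbreeding(25, 0)$F_t, 0)
  expect_equal(expected_inbreeding(25, 1)$F_t, 0.02)
  expect_equal(round(expected_inbreeding(25, 13)$F_t, 4), 0.2310)
  f <- expected_inbreeding(25, 0:200)$F_t
  expect_true(all(diff(f) > 0))
  expect_gt(expected_inbreeding(10, 50)$F_t, expected_inbreeding(50, 50)$F_t)
  expect_equal(expected_inbreeding(25, 5000)$F_t, 1, tolerance = 1e-8)
  expect_error(expected_inbreeding(0.5, 3), "at least 1")
  w <- expected_inbreeding(25, 13, delta = 1.99)
  expect_equal(w$w_rel, exp(-1.99 * w$F_t))
})

test_that("relative decline arithmetic matches the published comparison", {
  rd <- relative_decline(67.18, 69.18, 65.58, 90.60)
  expect_equal(round(rd$decline_late_net, 3), 0.247)
  expect_equal(round(rd$decline_early, 3), 0.029)
  expect_equal(rd$ratio_pct, 855, tolerance = 1)
  expect_equal(rd$rel_late_pct, 72, tolerance = 0.5)
  expect_equal(rd$ref_increase_pct, 31, tolerance = 0.5)
  z <- relative_decline(50, 50, 50, 50)
  expect_equal(z$decline_early, 0)
  expect_equal(z$decline_late_net, 0)
  expect_true(is.na(z$ratio))
  expect_error(relative_decline(40, 50, 30, 50 * 0), "positive")
})

test_that("Mann-Whitney matches the enumeration oracle", {
  r <- mann_whitney_two_sided(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  r2 <- mann_whitney_two_sided(c(1, 3, 5), c(2, 4, 6))
  o2 <- mw_oracle(c(1, 3, 5), c(2, 4, 6))
  expect_equal(r2$U, o2$U)
  expect_equal(r2$p, o2$p, tolerance = 1e-12)
  # identical multisets: ties force the corrected normal approximation
  ri <- mann_whitney_two_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$p, 1)
  expect_error(mann_whitney_two_sided(numeric(0), 1:3), "non-empty")
})
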