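test_that("the CSF attains its peak sensitivity exactly at the peak frequency", {
  cases <- list(
    list(p = csf_params(150, 1, 1.3), cs = 150, sf = 1),
    list(p = csf_params(100, 2, 1), cs = 100, sf = 2),
    list(p = standard_csf(), cs = 166, sf = 2.5)
  )
  for (cc in cases) {
    expect_equal(csf_sensitivity(cc$p, cc$sf), cc$cs)
    # dense-grid argmax sits at the peak
    sf <- sort(c(cc$sf, 10^seq(-1, 1.6, length.out = 400)))
    sens <- csf_sensitivity(cc$p, sf)
    expect_lt(max(sens), cc$cs + 1e-9)
    expect_equal(sf[which.max(sens)], cc$sf)
  }
})

test_that("the standard CSF evaluates as the log-parabola dictates at 18 c/deg", {
  # frozen from an independent scalar evaluation:
  # 10^(log10(166) - (log10(18) - log10(2.5))^2 * 1.28^2)
  expect_equal(csf_sensitivity(standard_csf(), 18), 10.3717715644, tolerance = 1e-9)
})

test_that("equal branch widths make the parabola symmetric in log frequency", {
  p <- csf_params(120, 3, width_r = 0.9, width_l = 0.9)
  for (k in c(1.3, 2, 5.7)) {
    expect_equal(csf_sensitivity(p, 3 * k), csf_sensitivity(p, 3 / k))
  }
})

test_that("sensitivity rises to the peak, falls beyond it, and falls faster with larger width_r", {
  set.seed(11)
  for (i in 1:5) {
    p <- csf_params(cs_p = runif(1, 20, 300), sf_p = runif(1, 0.8, 6),
                    width_r = runif(1, 0.5, 2))
    left <- csf_sensitivity(p, seq(0.05, p$sf_p, length.out = 50))
    right <- csf_sensitivity(p, seq(p$sf_p, 40, length.out = 50))
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
    wider <- csf_params(p$cs_p, p$sf_p, p$width_r * 1.5)
    sf_hi <- seq(p$sf_p * 1.01, 40, length.out = 30)
    expect_true(all(csf_sensitivity(wider, sf_hi) < csf_sensitivity(p, sf_hi)))
  }
})

test_that("CSF and CRF inputs are validated", {
  expect_error(csf_params(-1, 1, 1), "cs_p")
  expect_error(csf_sensitivity(standard_csf(), 0), "positive")
  expect_error(csf_sensitivity(standard_csf(), -2), "positive")
  expect_error(crf_response(-5, q = 2, Q = 1), "contrast")
  expect_error(crf_response(10, q = 0, Q = 1), "q")
})

test_that("the Naka-Rushton response half-saturates at Q, vanishes at zero contrast, and saturates monotonically", {
  expect_equal(crf_response(10, q = 3, Q = 10, a = 2), 1)
  expect_equal(crf_response(0, q = 3, Q = 10), 0)
  expect_equal(crf_response(30, q = 1, Q = 10, a = 1), 0.75)
  cc <- seq(0, 100, by = 0.5)
  r <- crf_response(cc, q = 2.2, Q = 4, a = 1.7)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r < 1.7))
  # steep slopes approach a step at Q
  expect_gt(crf_response(2 * 4, q = 20, Q = 4, a = 1), 0.99)
})

test_that("the semisaturation contrast is the CSF-implied threshold", {
  expect_equal(semisaturation_from_csf(standard_csf(), 2.5), 100 / 166)
  # a CSF peaking at sensitivity 100 has Q = 1 at its peak
  expect_equal(semisaturation_from_csf(csf_params(100, 2, 1), 2), 1)
  # Q grows along the falling right branch
  q50 <- semisaturation_from_csf(standard_csf(), c(3, 6, 12, 18))
  expect_true(all(diff(q50) > 0))
  # far from the peak the sensitivity floor keeps Q finite and flags it
  q_far <- semisaturation_from_csf(csf_params(10, 1, 3), 1000)
  expect_true(is.finite(q_far))
  expect_true(any(attr(q_far, "floored")))
})

test_that("the composed nCSF response chains threshold and half-saturation", {
  m <- ncsf_model(cs_p = 100, sf_p = 2, width_r = 1, slope_crf = 3,
                  amplitude = 1.4)
  expect_equal(ncsf_response(m, sf = 5, contrast = 0), 0)
  # at the CSF threshold contrast the response is half the amplitude
  thr <- 100 / csf_sensitivity(m$csf, 5)
  expect_equal(ncsf_response(m, sf = 5, contrast = thr), 0.7)
  # frozen from an independent hand chain (sensitivity -> Q -> Naka-Rushton)
  red <- ncsf_model(cs_p = 100, sf_p = 2, width_r = 1, slope_crf = 3)
  expect_equal(ncsf_response(red, sf = 2, contrast = 80), 0.999998046879,
               tolerance = 1e-9)
})

test_that("normalized AUC self-normalizes, clamps, and matches a denser quadrature", {
  expect_equal(auc_normalized(standard_csf())$auc_normalized, 100)
  # sensitivity never above 1 on the interval -> zero area
  expect_equal(auc_normalized(csf_params(1, 2.5, 1.28))$auc_normalized, 0)
  # frozen 10x-density trapezoid oracle for the green model
  green <- auc_normalized(csf_params(150, 1, 1.3))$auc_normalized
  expect_equal(green, 75.107126, tolerance = 0.005 * 75.107126)
  # monotone in peak sensitivity
  aucs <- vapply(c(50, 100, 200, 400), function(cs) {
    auc_normalized(csf_params(cs, 2.5, 1.28))$auc_normalized
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_error(auc_normalized(standard_csf(), sf_lo = 2, sf_hi = 2), "exceed")
})
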