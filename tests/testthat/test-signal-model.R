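test_that("SPGR signal matches the closed form and its limits", {
  # frozen value from an independent evaluation of the closed form
  expect_equal(spgr_signal(1000, 1.0, 15, 0.005), 33.1912400536, tolerance = 1e-10)
  expect_equal(spgr_signal(123, 0.5, 0, 0.01), 0)
  # full recovery limit: 90 degrees, tr*r1 >> 1
  expect_equal(spgr_signal(1000, 100, 90, 1), 1000, tolerance = 1e-10)
  expect_error(spgr_signal(1000, -1, 15, 0.005), "r1")
  expect_error(spgr_signal(1000, 1, 15, 0), "tr")
})

test_that("SPGR signal is monotone in r1 and bounded by m0", {
  r1 <- seq(0.1, 20, length.out = 200)
  for (flip in c(2, 20, 60, 90)) {
    s <- spgr_signal(1000, r1, flip, 0.005)
    expect_true(all(diff(s) > 0))
    expect_true(all(s >= 0 & s <= 1000))
  }
})

test_that("closed-form inversion agrees with bracketed root finding", {
  m0 <- 11000
  for (r1 in c(0.3, 0.91, 1.667, 5)) {
    s <- spgr_signal(m0, r1, 20, 0.005)
    expect_equal(spgr_invert(s, m0, 20, 0.005), r1, tolerance = 1e-8)
  }
  # unattainable signals give NA
  expect_true(is.na(spgr_invert(m0 * sin(20 * pi / 180) * 1.01, m0, 20, 0.005)))
  expect_true(is.na(spgr_invert(-1, m0, 20, 0.005)))
})

test_that("VFA fit recovers generating parameters on noiseless input", {
  angles <- c(2, 8, 15, 20)
  sig <- spgr_signal(1000, 0.91, angles, 0.005)
  fit <- fit_vfa(data.frame(flip_deg = angles, signal = sig), tr = 0.005)
  expect_equal(fit$m0, 1000, tolerance = 1e-6)
  expect_equal(fit$r1, 0.91, tolerance = 1e-6)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "r1"], fit$r1)

  # two angles: determined system, exact recovery
  sig2 <- spgr_signal(800, 1.4, c(5, 25), 0.004)
  fit2 <- fit_vfa(data.frame(flip_deg = c(5, 25), signal = sig2), tr = 0.004)
  expect_equal(fit2$m0, 800, tolerance = 1e-6)
  expect_equal(fit2$r1, 1.4, tolerance = 1e-6)
})

test_that("VFA fit is accurate in the median under 1% noise", {
  angles <- c(2, 8, 15, 20)
  clean <- spgr_signal(1000, 0.91, angles, 0.005)
  set.seed(11)
  est <- t(vapply(seq_len(100), function(i) {
    sig <- clean + rnorm(4, 0, 0.01 * mean(clean))
    f <- fit_vfa(data.frame(flip_deg = angles, signal = abs(sig)), tr = 0.005)
    c(f$m0, f$r1)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1]) / 1000 - 1), 0.05)
  expect_lt(abs(stats::median(est[, 2]) / 0.91 - 1), 0.05)
})

test_that("VFA fit rejects degenerate input", {
  expect_error(fit_vfa(data.frame(flip_deg = c(10, 10), signal = c(5, 5)), 0.005),
               "distinct")
  expect_error(fit_vfa(data.frame(flip_deg = c(2, 20), signal = c(0, 0)), 0.005),
               "zero")
})

test_that("subtraction-method R1 recovery inverts the signal model", {
  m0 <- 470 / (spgr_signal(1, 0.91, 20, 0.005))
  si_pre <- spgr_signal(m0, 0.91, 20, 0.005)
  # no enhancement returns the native rate unchanged
  expect_identical(r1_post_from_subtraction(si_pre, si_pre, 0.91, m0, 20, 0.005),
                   0.91)
  # round-trip through a known post-injection rate
  for (r1p in c(0.95, 1.2, 3)) {
    si_post <- spgr_signal(m0, r1p, 20, 0.005)
    expect_equal(
      r1_post_from_subtraction(si_pre, si_post, 0.91, m0, 20, 0.005),
      r1p, tolerance = 1e-8
    )
  }
  # frozen bisection oracle: baseline 470, +5% enhancement
  expect_equal(
    r1_post_from_subtraction(470, 470 * 1.05, 0.91, m0, 20, 0.005),
    0.9590087973, tolerance = 1e-8
  )
  expect_error(
    r1_post_from_subtraction(470, 470 + m0, 0.91, m0, 20, 0.005),
    "range"
  )
})

test_that("concentration conversion is the definitional ratio", {
  expect_equal(conc_from_delta_r1(4.39), 1.0)
  expect_equal(conc_from_delta_r1(0), 0)
  expect_equal(conc_from_delta_r1(0.025), 0.025 / 4.39)
  # negative delta-R1 propagates, not clipped
  expect_lt(conc_from_delta_r1(-0.01), 0)
})

test_that("signal synthesis and frame-wise inversion are mutual inverses", {
  cp <- study_cp()
  ct <- study_ct_tofts()
  dyn <- si_curve_from_conc(ct, baseline_si = 470, r10 = 1 / 0.6)
  # baseline anchoring under the study conditions
  expect_equal(mean(dyn$si[seq_len(n_baseline(dyn))]), 470, tolerance = 1e-9)
  # zero concentration gives a flat curve
  flat <- si_curve_from_conc(conc_curve(ct$time_s, 0 * ct$conc_mM, 33), 470, 1 / 0.6)
  expect_true(all(abs(flat$si - 470) < 1e-9))
  # round-trip
  back <- conc_curve_from_si(dyn, r10 = 1 / 0.6)
  expect_lt(max(abs(back$conc_mM - ct$conc_mM)), 1e-8)
})
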