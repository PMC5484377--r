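test_that("cumulative integral matches analytic results", {
  t <- seq(0, 100, by = 1.03)
  # constant integrand
  const <- conc_curve(t, rep(2, length(t)))
  expect_equal(cum_integral(const)$value, 2 * t, tolerance = 1e-12)
  # zero integrand
  expect_true(all(cum_integral(conc_curve(t, rep(0, length(t))))$value == 0))
  # gamma-variate vs incomplete-gamma analytic integral at dt = 1.03 s
  a <- 3; b <- 10
  g <- conc_curve(t, t^a * exp(-t / b))
  analytic <- b^(a + 1) * gamma(a + 1) * stats::pgamma(t, shape = a + 1, scale = b)
  num <- cum_integral(g)$value
  i <- t >= 20  # beyond the curve foot, where the integral is resolved
  expect_lt(max(abs(num[i] - analytic[i]) / analytic[i]), 1e-3)
  expect_error(cum_integral(conc_curve(0, 1)), "2 samples")
})

test_that("unidirectional model has its closed forms", {
  cp <- study_cp()
  p <- study_truth()
  # no leakage: purely intravascular
  iv <- tissue_conc_unidirectional(cp, kinetic_params(0, 0.024))
  expect_equal(iv$conc_mM, 0.024 * cp$conc_mM, tolerance = 1e-14)
  # constant plasma, no plasma volume: linear ramp at ktrans/60 mM/s
  t <- seq(0, 200, by = 1.03)
  cpc <- conc_curve(t, rep(1, length(t)))
  ramp <- tissue_conc_unidirectional(cpc, kinetic_params(0.0074, 0))
  expect_equal(ramp$conc_mM, (0.0074 / 60) * t, tolerance = 1e-12)
  # study truths vs an independent loop-summation oracle
  ct <- tissue_conc_unidirectional(cp, p)
  oracle <- numeric(nrow(cp))
  for (i in 2:nrow(cp)) {
    oracle[i] <- p$vp * cp$conc_mM[i] +
      (p$ktrans / 60) * trapz_oracle(cp$time_s[1:i], cp$conc_mM[1:i])
  }
  oracle[1] <- p$vp * cp$conc_mM[1]
  expect_lt(max(abs(ct$conc_mM - oracle)), 1e-10)
})

test_that("Tofts model: limits, boxcar closed form, and backflux ordering", {
  cp <- study_cp()
  # ktrans = 0 reduces to the intravascular term
  z <- tissue_conc_tofts(cp, kinetic_params(0, 0.024, 0.2))
  expect_equal(z$conc_mM, 0.024 * cp$conc_mM, tolerance = 1e-14)
  # vanishing backflux (huge ve) recovers the unidirectional model
  lim <- tissue_conc_tofts(cp, kinetic_params(0.0074, 0.024, 1e9))
  uni <- tissue_conc_unidirectional(cp, kinetic_params(0.0074, 0.024))
  expect_lt(max(abs(lim$conc_mM - uni$conc_mM)), 1e-6)
  # boxcar plasma curve: analytic (ktrans/kep)(1 - exp(-kep t)) + vp during the box
  t <- seq(0, 300, by = 0.5)
  box <- conc_curve(t, as.numeric(t >= 0))  # unit step from t = 0
  p <- kinetic_params(0.012, 0.03, 0.2)
  ct <- tissue_conc_tofts(box, p)
  kep_s <- p$kep / 60
  analytic <- (p$ktrans / 60) / kep_s * (1 - exp(-kep_s * t)) + p$vp
  expect_lt(max(abs(ct$conc_mM - analytic)), 1e-6)
  # backflux only removes tracer
  tof <- study_ct_tofts()
  expect_true(all(tof$conc_mM <= uni$conc_mM + 1e-13))
  expect_true(all(tof$conc_mM >= 0.024 * cp$conc_mM - 1e-13))
  expect_error(tissue_conc_tofts(cp, kinetic_params(0.0074, 0.024)), "ve")
})

test_that("forward models converge under grid refinement", {
  p <- study_truth()
  coarse_cp <- synth_aif(n_frames = 300, dt = 1.03)
  fine_cp <- synth_aif(n_frames = 599, dt = 0.515, n_baseline = 66)
  coarse <- tissue_conc_tofts(coarse_cp, p)
  fine <- tissue_conc_tofts(fine_cp, p)
  # compare on the shared grid (every second fine sample)
  shared <- fine$conc_mM[seq(1, 599, by = 2)]
  i <- shared > 1e-4
  expect_lt(max(abs(coarse$conc_mM[i] - shared[i]) / shared[i]), 1e-3)
})

test_that("stretched time has its analytic forms and masks the baseline", {
  # constant plasma concentration: stretched time is lab time
  t <- seq(0, 100, by = 1.03)
  st <- stretch_time(conc_curve(t, rep(0.5, length(t))))
  expect_equal(st$t_stretch[st$valid], t[st$valid], tolerance = 1e-12)
  # exponential decay: t_stretch = (exp(kt) - 1)/k
  k <- 0.01
  std <- stretch_time(conc_curve(t, exp(-k * t)), cp_floor_frac = 0)
  analytic <- (exp(k * t) - 1) / k
  i <- which(t > 5)
  expect_lt(max(abs(std$t_stretch[i] - analytic[i]) / analytic[i]), 0.005)
  # synthetic bolus: stretched time outruns lab time after the first pass
  cp <- study_cp()
  stb <- stretch_time(cp)
  tau <- cp$time_s - n_baseline(cp) * curve_dt(cp)
  ok <- stb$valid
  ts37 <- approx(tau[ok], stb$t_stretch[ok], 37)$y
  ts157 <- approx(tau[ok], stb$t_stretch[ok], 157)$y
  expect_gt((ts157 - ts37) / (157 - 37), 1)
  # degenerate: everything masked
  expect_error(stretch_time(conc_curve(t, rep(0, length(t)))), "masked")
})
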