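make_phantom <- function(conc_end = c(0, 0.002, 0.006, 0.012),
                         dims = c(10, 10, 3), n_frames = 60, n_baseline = 20,
                         r10 = 1 / 0.6) {
  # each voxel ramps from 0 to its plateau concentration, then holds
  nvox <- prod(dims)
  plateau <- rep_len(conc_end, nvox)
  t <- (seq_len(n_frames) - 1) * 1.03
  dyn <- array(0, c(dims, n_frames))
  for (v in seq_len(nvox)) {
    conc <- c(rep(0, n_baseline),
              seq(0, plateau[v], length.out = 10),
              rep(plateau[v], n_frames - n_baseline - 10))
    si <- si_curve_from_conc(conc_curve(t, conc, n_baseline), 470, r10)$si
    dyn[arrayInd(v, dims)[1], arrayInd(v, dims)[2], arrayInd(v, dims)[3], ] <- si
  }
  list(dyn = dyn, plateau = plateau, dims = dims, n_baseline = n_baseline,
       r10 = r10, m0 = 470 / (spgr_signal(1, r10, 20, 0.005)))
}

test_that("delta-R1 maps recover known plateau concentrations", {
  ph <- make_phantom()
  r1n <- array(ph$r10, ph$dims)
  m0 <- array(ph$m0, ph$dims)
  dr1 <- delta_r1_map(ph$dyn, r1n, m0, n_baseline = ph$n_baseline)
  expect_equal(as.numeric(dr1), 4.39 * ph$plateau, tolerance = 1e-6)
  expect_identical(attr(dr1, "n_failed"), 0L)
  # no enhancement anywhere: identically zero
  flat <- array(470, c(4, 4, 2, 30))
  z <- delta_r1_map(flat, array(ph$r10, c(4, 4, 2)), array(ph$m0, c(4, 4, 2)),
                    n_baseline = 10)
  expect_true(all(abs(z) < 1e-10))
  expect_error(delta_r1_map(flat[, , 1, ], r1n, m0, 10), "4D")
})

test_that("vectorised map agrees with the scalar inversion path per voxel", {
  ph <- make_phantom(dims = c(5, 4, 2))
  r1n <- array(ph$r10, ph$dims)
  m0 <- array(ph$m0, ph$dims)
  dr1 <- delta_r1_map(ph$dyn, r1n, m0, n_baseline = ph$n_baseline)
  nt <- dim(ph$dyn)[4]
  for (v in seq_len(prod(ph$dims))) {
    ix <- arrayInd(v, ph$dims)
    curve <- ph$dyn[ix[1], ix[2], ix[3], ]
    si_pre <- mean(curve[seq_len(ph$n_baseline)])
    si_post <- mean(curve[(nt - 9):nt])
    scalar <- r1_post_from_subtraction(si_pre, si_post, ph$r10, ph$m0,
                                       20, 0.005) - ph$r10
    expect_equal(dr1[ix[1], ix[2], ix[3]], scalar, tolerance = 1e-8)
  }
})

test_that("white-matter mask applies a strict probability threshold", {
  p <- array(c(0.95, 1.0, 0.951, 0, 0.5, NA), c(3, 2, 1))
  m <- wm_mask(p)
  expect_false(m[1, 1, 1])  # exactly at threshold: excluded
  expect_true(m[2, 1, 1])
  expect_true(m[3, 1, 1])
  expect_false(m[3, 2, 1])  # NA treated as excluded
  # counting oracle on a random map
  set.seed(9)
  pr <- array(runif(1000), c(10, 10, 10))
  expect_equal(sum(wm_mask(pr, 0.95)), sum(pr > 0.95))
  expect_error(wm_mask(array(1.2, c(2, 2, 1))), "0, 1")
})

test_that("four-colour classification matches the threshold table", {
  expect_equal(as.character(classify_wm(0.030, 0.02)), "yellow")
  expect_equal(as.character(classify_wm(0.020, 0.005)), "blue")  # low vp wins
  expect_equal(as.character(classify_wm(-0.001, 0.02)), "blue")  # negative dr1
  expect_equal(as.character(classify_wm(0.005, 0.02)), "green")
  expect_equal(as.character(classify_wm(0.012, 0.02)), "red")    # closed lower bound
  expect_equal(as.character(classify_wm(0.025, 0.02)), "yellow") # closed lower bound
  expect_equal(as.character(classify_wm(0, 0.02)), "blue")       # green band open at 0
  expect_true(is.na(classify_wm(NaN, 0.02)))
})

test_that("classification partitions every finite input exactly once", {
  grid <- expand.grid(dr1 = seq(-0.03, 0.05, by = 0.0005),
                      vp = seq(-0.01, 0.05, by = 0.001))
  lab <- classify_wm(grid$dr1, grid$vp)
  expect_false(anyNA(lab))
  expect_setequal(levels(lab), c("blue", "green", "red", "yellow"))
})

test_that("ROI curves are frame-wise means over same-coloured voxels", {
  dims <- c(4, 4, 1)
  nt <- 20
  set.seed(2)
  dyn <- array(rnorm(prod(dims) * nt, 470, 5), c(dims, nt))
  labels <- array(rep(c("red", "blue"), each = 8), dims)
  red <- roi_average_curve(dyn, labels, "red", dt = 1.03, n_baseline = 5)
  mat <- matrix(dyn, nrow = prod(dims))
  oracle <- colMeans(mat[which(as.character(labels) == "red"), ])
  expect_equal(red$si, oracle, tolerance = 1e-12)
  expect_equal(attr(red, "n_voxels"), 8L)
  # single-voxel region returns that voxel's curve
  lab1 <- array(c("yellow", rep("blue", 15)), dims)
  one <- roi_average_curve(dyn, lab1, "yellow", 1.03, 5)
  expect_equal(one$si, dyn[1, 1, 1, ], tolerance = 1e-12)
  expect_error(roi_average_curve(dyn, lab1, "green", 1.03, 5), "empty")
})

test_that("coefficient of variation is sample SD over mean", {
  expect_equal(round(100 * cov_estimates(c(0.0076, 0.0069, 0.0075, 0.0063)), 1),
               8.5)
  expect_equal(cov_estimates(c(2, 2, 2, 2)), 0)
  expect_equal(cov_estimates(c(1, 2, 3)), 0.5)
  expect_error(cov_estimates(1), "2 values")
  expect_error(cov_estimates(c(-1, 1)), "zero")
})

test_that("delta-R1 / Ktrans regression equals the closed-form OLS", {
  set.seed(4)
  d <- tibble::tibble(dr1 = runif(12, 0, 0.04),
                      ktrans = 0.17 * runif(12, 0, 0.04) - 0.001 +
                        rnorm(12, 0, 1e-4))
  r <- regress_dr1_ktrans(d)
  n <- nrow(d)
  sx <- sum(d$dr1); sy <- sum(d$ktrans)
  slope <- (n * sum(d$dr1 * d$ktrans) - sx * sy) / (n * sum(d$dr1^2) - sx^2)
  expect_equal(r$slope, slope, tolerance = 1e-12)
  # collinear data: perfect fit
  col <- tibble::tibble(dr1 = 1:5 / 100, ktrans = 0.2 * (1:5 / 100) + 0.001)
  expect_equal(regress_dr1_ktrans(col)$r2, 1, tolerance = 1e-12)
  expect_error(regress_dr1_ktrans(col[1, ]), "2 pairs")
  expect_error(
    regress_dr1_ktrans(tibble::tibble(dr1 = c(1, 1), ktrans = c(1, 2))),
    "equal"
  )
})

test_that("regional statistics and ANOVA reporting run end to end", {
  set.seed(6)
  n <- 40
  region <- rep(c("blue", "green", "red", "yellow"), each = n)
  value <- rnorm(4 * n, mean = rep(c(0, 0.006, 0.018, 0.039), each = n),
                 sd = 0.003)
  cmp <- compare_regions(tibble::tibble(region = region, value = value))
  expect_lt(cmp$anova$p, 1e-10)
  expect_equal(nrow(cmp$tukey), 6)  # all region pairs
  rs <- region_stats(region, value, value * 0.17, rep(0.02, 4 * n))
  expect_equal(nrow(rs), 4)
  expect_equal(sum(rs$n_voxels), 4 * n)
})
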