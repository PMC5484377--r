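#' Voxel-wise map of the post-injection change in R1
#'
#' For every voxel of a 4D dynamic acquisition: the pre-injection signal
#' is the mean over the baseline frames, the post-injection signal the
#' mean over the last `n_post` frames (frame averaging suppresses Rician
#' noise), the post-injection R1 is recovered with the subtraction
#' method against the native R1 and M0 maps, and
#' \eqn{\Delta R_1 = R_{1,post} - R_{1,N}}. Voxels whose averaged signal
#' falls outside the attainable SPGR range are set to `NA` and counted.
#'
#' @param dyn 4D numeric array (x, y, z, frame) of dynamic signal.
#' @param r1n_map 3D array of native R1 (1/s).
#' @param m0_map 3D array of M0 (same scanner units as `dyn`).
#' @param n_baseline number of pre-injection frames.
#' @param n_post number of trailing frames averaged for the
#'   post-injection signal.
#' @param flip_deg,tr dynamic-sequence flip angle (degrees) and TR (s).
#' @return A 3D array of delta-R1 (1/s) with attribute `n_failed`
#'   (count of voxels whose inversion failed).
#' @export
delta_r1_map <- function(dyn, r1n_map, m0_map, n_baseline,
                         n_post = 10, flip_deg = 20, tr = 0.005) {
  if (length(dim(dyn)) != 4) abort("`dyn` must be a 4D array (x, y, z, t).")
  nt <- dim(dyn)[4]
  if (n_baseline < 1 || n_baseline >= nt) abort("invalid `n_baseline`.")
  if (nt - n_baseline < n_post) {
    abort(sprintf("need at least %d post-injection frames.", n_post))
  }
  d <- dim(dyn)
  nvox <- prod(d[1:3])
  mat <- matrix(dyn, nrow = nvox, ncol = nt)
  si_pre <- rowMeans(mat[, seq_len(n_baseline), drop = FALSE])
  si_post <- rowMeans(mat[, (nt - n_post + 1):nt, drop = FALSE])
  r1n <- as.numeric(r1n_map)
  m0 <- as.numeric(m0_map)
  # subtraction method: target = model baseline + measured difference
  target <- spgr_signal_safe(m0, r1n, flip_deg, tr) + (si_post - si_pre)
  r1_post <- spgr_invert(target, m0, flip_deg, tr)
  dr1 <- r1_post - r1n
  n_failed <- sum(is.na(dr1) & is.finite(r1n) & is.finite(m0))
  out <- array(dr1, dim = d[1:3])
  attr(out, "n_failed") <- n_failed
  out
}

# spgr_signal tolerating non-positive r1 (returns NA there) for map code
spgr_signal_safe <- function(m0, r1, flip_deg, tr) {
  out <- rep(NA_real_, length(r1))
  ok <- is.finite(r1) & r1 > 0 & is.finite(m0) & m0 >= 0
  if (any(ok)) out[ok] <- spgr_signal(m0[ok], r1[ok], flip_deg, tr)
  out
}

#' White-matter mask from a tissue-probability map
#'
#' Boolean mask of voxels whose white-matter probability strictly
#' exceeds the threshold (a voxel at exactly the threshold is excluded).
#'
#' @param prob_map array of probabilities in \[0, 1\].
#' @param threshold probability cut-off; default 0.95.
#' @return Logical array of the same shape.
#' @export
wm_mask <- function(prob_map, threshold = 0.95) {
  p <- as.numeric(prob_map)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("probabilities must lie in [0, 1].")
  }
  out <- array(prob_map > threshold, dim = dim(prob_map) %||% length(p))
  out[is.na(prob_map)] <- FALSE
  out
}

#' Four-colour classification of white-matter voxels
#'
#' Partitions voxels by the magnitude of delta-R1 and the uncorrected
#' first-pass vp:
#' \itemize{
#'   \item blue: `dr1 < 0` or `vp < 0.01` (no residual contrast, or
#'     low-plasma-volume voxels folded in);
#'   \item green: `0 < dr1 < 0.012` and `vp > 0.01`;
#'   \item red: `0.012 <= dr1 < 0.025` and `vp > 0.01`;
#'   \item yellow: `dr1 >= 0.025` and `vp > 0.01`.
#' }
#' `dr1` exactly 0 (with `vp >= 0.01`) falls to blue, since the green
#' band is open at 0. Thresholds are in 1/s. Non-finite inputs return
#' `NA` (unclassified). The partition is exhaustive and mutually
#' exclusive over finite inputs.
#'
#' @param dr1 delta-R1 values (1/s), vectorised.
#' @param vp uncorrected first-pass vp values, same length.
#' @param thresholds named numeric vector with elements `green` and
#'   `yellow` (lower bounds of the red and yellow bands), and `vp_min`.
#' @return A factor with levels blue, green, red, yellow.
#' @export
classify_wm <- function(dr1, vp,
                        thresholds = c(green = 0.012, yellow = 0.025,
                                       vp_min = 0.01)) {
  if (length(dr1) != length(vp)) abort("`dr1` and `vp` must match in length.")
  lab <- rep(NA_character_, length(dr1))
  ok <- is.finite(dr1) & is.finite(vp)
  lab[ok & (dr1 < 0 | vp < thresholds[["vp_min"]])] <- "blue"
  rest <- ok & is.na(lab)
  lab[rest & dr1 < thresholds[["green"]]] <- ifelse(
    dr1[rest & dr1 < thresholds[["green"]]] > 0, "green", "blue")
  rest <- ok & is.na(lab)
  lab[rest & dr1 < thresholds[["yellow"]]] <- "red"
  rest <- ok & is.na(lab)
  lab[rest] <- "yellow"
  factor(lab, levels = c("blue", "green", "red", "yellow"))
}

#' ROI-averaged signal curve for one colour-coded region
#'
#' Frame-wise mean signal over all voxels carrying the requested label
#' (each ROI is the collection of same-coloured voxels); spatial
#' averaging is what makes kinetic analysis feasible at white-matter
#' SNR.
#'
#' @param dyn 4D dynamic array (x, y, z, frame).
#' @param labels factor/character array matching the spatial dimensions.
#' @param region label to average over (`"blue"`, `"green"`, `"red"`,
#'   `"yellow"`).
#' @param dt frame spacing in seconds.
#' @param n_baseline number of pre-injection frames.
#' @return A `dyn_series` with attribute `n_voxels`.
#' @export
roi_average_curve <- function(dyn, labels, region, dt, n_baseline) {
  if (length(dim(dyn)) != 4) abort("`dyn` must be a 4D array.")
  d <- dim(dyn)
  sel <- which(as.character(labels) == region)
  if (length(sel) == 0) abort(sprintf("region '%s' is empty.", region))
  mat <- matrix(dyn, nrow = prod(d[1:3]), ncol = d[4])
  si <- colMeans(mat[sel, , drop = FALSE])
  out <- dyn_series((seq_len(d[4]) - 1) * dt, si, n_baseline)
  attr(out, "n_voxels") <- length(sel)
  out
}

#' Coefficient of variation of a set of estimates
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' the stability metric for parameter estimates across fitting
#' intervals.
#'
#' @param values numeric vector of at least 2 estimates.
#' @return CoV as a fraction (multiply by 100 for percent).
#' @examples
#' cov_estimates(c(0.0076, 0.0069, 0.0075, 0.0063))  # ~0.085
#' @export
cov_estimates <- function(values) {
  if (length(values) < 2) abort("need at least 2 values.")
  m <- mean(values)
  if (abs(m) < 1e-300) abort("mean is zero; CoV undefined.")
  stats::sd(values) / m
}

#' Regression of Ktrans on delta-R1 across regions
#'
#' Ordinary least squares of regional Ktrans on regional delta-R1, the
#' association that lets delta-R1 maps display relative permeability
#' levels.
#'
#' @param data data frame with columns `dr1` and `ktrans`.
#' @return A tibble with `slope`, `intercept`, `r2`, `n`.
#' @export
regress_dr1_ktrans <- function(data) {
  if (!all(c("dr1", "ktrans") %in% names(data))) {
    abort("`data` must have columns `dr1` and `ktrans`.")
  }
  if (nrow(data) < 2) abort("need at least 2 pairs.")
  if (stats::sd(data$dr1) == 0) abort("all `dr1` values are equal; fit undefined.")
  fit <- lm(ktrans ~ dr1, data = data)
  tss <- sum((data$ktrans - mean(data$ktrans))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = nrow(data))
}

#' Regional summary statistics of parametric maps
#'
#' Mean and SD of delta-R1, Ktrans and vp within each colour-coded
#' region, plus voxel counts. A thin reporting utility over maps already
#' computed.
#'
#' @param labels label array/factor from [classify_wm()].
#' @param dr1,ktrans,vp numeric arrays of matching length (Ktrans in
#'   1/min).
#' @return A tibble, one row per region present.
#' @export
region_stats <- function(labels, dr1, ktrans, vp) {
  tibble(region = as.character(labels), dr1 = as.numeric(dr1),
         ktrans = as.numeric(ktrans), vp = as.numeric(vp)) |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      mean_dr1 = mean(.data$dr1, na.rm = TRUE),
      sd_dr1 = stats::sd(.data$dr1, na.rm = TRUE),
      mean_ktrans = mean(.data$ktrans, na.rm = TRUE),
      sd_ktrans = stats::sd(.data$ktrans, na.rm = TRUE),
      mean_vp = mean(.data$vp, na.rm = TRUE),
      sd_vp = stats::sd(.data$vp, na.rm = TRUE),
      .groups = "drop"
    )
}

#' One-way ANOVA with Tukey HSD across regions
#'
#' Reporting utility for user-supplied regional values: one-way analysis
#' of variance of `value` against `region` followed by Tukey's honestly
#' significant difference intervals for every region pair.
#'
#' @param data data frame with columns `region` and `value`.
#' @return A list with `anova` (F statistic, p value) and `tukey`
#'   (tibble of pairwise differences with confidence bounds).
#' @export
compare_regions <- function(data) {
  if (!all(c("region", "value") %in% names(data))) {
    abort("`data` must have columns `region` and `value`.")
  }
  data$region <- factor(data$region)
  if (nlevels(data$region) < 2) abort("need at least 2 regions.")
  fit <- aov(value ~ region, data = data)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$region
  list(
    anova = tibble(f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                   df_between = s[["Df"]][1], df_within = s[["Df"]][2]),
    tukey = tibble(pair = rownames(tk), estimate = tk[, "diff"],
                   lower = tk[, "lwr"], upper = tk[, "upr"],
                   p_adj = tk[, "p adj"])
  )
}
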