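#' Stretched-time fitting interval
#'
#' The interval, on the stretched-time axis, over which Patlak-type
#' regressions are performed. The default 85--250 s is the primary
#' preset; 80--250, 85--300, 0--250 and 0--460 (whole-interval) presets
#' match the stability analysis. Bounds are inclusive.
#'
#' @param lo,hi lower and upper stretched-time bounds in seconds,
#'   `0 <= lo < hi`.
#' @return A list of class `stretch_interval`.
#' @export
stretch_interval <- function(lo = 85, hi = 250) {
  if (lo < 0 || hi <= lo) abort("need 0 <= lo < hi.")
  structure(list(lo = lo, hi = hi), class = "stretch_interval")
}

#' @export
print.stretch_interval <- function(x, ...) {
  cat(sprintf("<stretch_interval> %g-%g s\n", x$lo, x$hi))
  invisible(x)
}

#' Patlak-plot points from tissue and plasma curves
#'
#' Builds the Patlak scatter: ordinate \eqn{v_d(t) = C_t(t)/C_p(t)}
#' (apparent volume of distribution) against abscissa
#' \eqn{t_{stretch}(t)}. With an intact barrier \eqn{v_d \equiv v_p};
#' leakage makes the points rise with slope Ktrans. Points where the
#' plasma concentration is below the validity floor are masked.
#'
#' @param ct tissue concentration curve.
#' @param cp plasma concentration curve on the same time grid.
#' @param cp_floor_frac validity floor, fraction of the `cp` peak.
#' @return A tibble with columns `time_s`, `t_stretch`, `vd`, `valid`.
#' @export
patlak_points <- function(ct, cp, cp_floor_frac = 0.05) {
  if (nrow(ct) != nrow(cp) || max(abs(ct$time_s - cp$time_s)) > 1e-9) {
    abort("`ct` and `cp` must share the same time grid.")
  }
  st <- stretch_time(cp, cp_floor_frac)
  vd <- ct$conc_mM / cp$conc_mM
  vd[!st$valid] <- NA_real_
  tibble(time_s = cp$time_s, t_stretch = st$t_stretch, vd = vd,
         valid = st$valid & is.finite(vd))
}

select_points <- function(points, interval) {
  ok <- points$valid & !is.na(points$t_stretch) &
    points$t_stretch >= interval$lo & points$t_stretch <= interval$hi
  points[ok, , drop = FALSE]
}

#' Conventional Patlak fit (slope = Ktrans, intercept = vp)
#'
#' Ordinary least-squares line through the Patlak points falling inside
#' the stretched-time interval. The slope (per second) is converted to
#' Ktrans in 1/min; the intercept is vp. Negative fitted values are
#' reported as-is.
#'
#' @param points output of [patlak_points()].
#' @param interval a [stretch_interval()].
#' @return An object of class `patlak_fit` with elements `ktrans`
#'   (1/min), `vp`, `r2`, `n_points`, `interval`, `points`,
#'   `fixed_vp` (FALSE). Supports [tidy()], [glance()], [autoplot()].
#' @export
patlak_fit <- function(points, interval = stretch_interval()) {
  sel <- select_points(points, interval)
  if (nrow(sel) < 2) {
    abort(sprintf("only %d valid point(s) in interval %g-%g s; need >= 2.",
                  nrow(sel), interval$lo, interval$hi))
  }
  fit <- lm(vd ~ t_stretch, data = sel)
  # R2 computed directly: summary.lm warns on noiseless synthetic data
  res <- stats::residuals(fit)
  tss <- sum((sel$vd - mean(sel$vd))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  new_patlak_fit(
    ktrans = unname(coef(fit)[2]) * 60,
    vp = unname(coef(fit)[1]),
    r2 = r2, n_points = nrow(sel), interval = interval,
    points = points, fixed_vp = FALSE
  )
}

#' One-parameter Patlak refit with the intercept fixed
#'
#' Least-squares slope through the selected Patlak points with the
#' intercept pinned at a known `vp` (the hybrid method's Step 3):
#' \eqn{K^{trans} = \sum x (y - v_p) / \sum x^2} over the selected
#' points, converted to 1/min.
#'
#' @inheritParams patlak_fit
#' @param vp the fixed intercept (fractional plasma volume).
#' @return A `patlak_fit` with `fixed_vp = TRUE`.
#' @export
patlak_fit_fixed_vp <- function(points, vp, interval = stretch_interval()) {
  if (!is.finite(vp)) abort("`vp` must be finite.")
  sel <- select_points(points, interval)
  if (nrow(sel) < 1) {
    abort(sprintf("no valid points in interval %g-%g s.",
                  interval$lo, interval$hi))
  }
  x <- sel$t_stretch
  y <- sel$vd
  slope <- sum(x * (y - vp)) / sum(x^2)
  res <- y - vp - slope * x
  tss <- sum((y - mean(y))^2)
  new_patlak_fit(
    ktrans = slope * 60, vp = vp,
    r2 = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    n_points = nrow(sel), interval = interval,
    points = points, fixed_vp = TRUE
  )
}

new_patlak_fit <- function(ktrans, vp, r2, n_points, interval, points, fixed_vp) {
  structure(
    list(ktrans = ktrans, vp = vp, r2 = r2, n_points = n_points,
         interval = interval, points = points, fixed_vp = fixed_vp),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "<patlak_fit%s> Ktrans = %.4g /min, vp = %.4g (n = %d, interval %g-%g s, R2 = %.4g)\n",
    if (x$fixed_vp) " fixed-vp" else "",
    x$ktrans, x$vp, x$n_points, x$interval$lo, x$interval$hi, x$r2))
  invisible(x)
}

#' @method tidy patlak_fit
#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble(term = c("ktrans", "vp"),
         estimate = c(x$ktrans, x$vp),
         unit = c("1/min", "fraction"),
         fixed = c(FALSE, x$fixed_vp))
}

#' @method glance patlak_fit
#' @export
glance.patlak_fit <- function(x, ...) {
  tibble(ktrans = x$ktrans, vp = x$vp, r2 = x$r2, n_points = x$n_points,
         interval_lo = x$interval$lo, interval_hi = x$interval$hi,
         fixed_vp = x$fixed_vp)
}
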