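#' Contrast-agent concentration curves and signal-intensity series
#'
#' The two tabular containers used throughout the package. A
#' concentration curve holds a uniformly sampled contrast-agent
#' concentration time course (mM); a dynamic series holds a signal
#' intensity time course in arbitrary scanner units. Both are plain
#' tibbles with a `n_baseline` attribute recording how many leading
#' frames precede the contrast injection, so they pipe through the usual
#' tidyverse verbs (attributes are re-attached by the package's own
#' functions, which always receive `n_baseline` explicitly or read it
#' with [n_baseline()]).
#'
#' @param time_s numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param conc_mM concentration at each time point, in mM.
#' @param si signal intensity at each time point (arbitrary units).
#' @param n_baseline number of pre-injection frames.
#' @return A tibble of class `conc_curve` (columns `time_s`, `conc_mM`)
#'   or `dyn_series` (columns `time_s`, `si`).
#' @examples
#' cp <- conc_curve(time_s = seq(0, 10, by = 1), conc_mM = rep(0, 11), n_baseline = 5)
#' curve_dt(cp)
#' @export
conc_curve <- function(time_s, conc_mM, n_baseline = 0L) {
  check_time_axis(time_s)
  if (length(conc_mM) != length(time_s)) {
    abort("`time_s` and `conc_mM` must have the same length.")
  }
  out <- tibble(time_s = as.numeric(time_s), conc_mM = as.numeric(conc_mM))
  attr(out, "n_baseline") <- as.integer(n_baseline)
  class(out) <- c("conc_curve", class(out))
  out
}

#' @rdname conc_curve
#' @export
dyn_series <- function(time_s, si, n_baseline = 0L) {
  check_time_axis(time_s)
  if (length(si) != length(time_s)) {
    abort("`time_s` and `si` must have the same length.")
  }
  out <- tibble(time_s = as.numeric(time_s), si = as.numeric(si))
  attr(out, "n_baseline") <- as.integer(n_baseline)
  class(out) <- c("dyn_series", class(out))
  out
}

check_time_axis <- function(time_s) {
  if (length(time_s) < 1 || anyNA(time_s)) {
    abort("time axis must be non-empty and free of NA.")
  }
  if (length(time_s) > 1) {
    d <- diff(time_s)
    if (any(d <= 0)) abort("time axis must be strictly increasing.")
    if (diff(range(d)) > 1e-6 * mean(d)) {
      abort("time axis must be uniformly sampled.")
    }
  }
  invisible(time_s)
}

#' Sampling interval and baseline-frame count of a curve
#'
#' @param x a `conc_curve` or `dyn_series`.
#' @return `curve_dt()`: the sampling interval in seconds;
#'   `n_baseline()`: the number of pre-injection frames.
#' @export
curve_dt <- function(x) {
  t <- x$time_s
  if (length(t) < 2) abort("need at least 2 samples to define dt.")
  mean(diff(t))
}

#' @rdname curve_dt
#' @export
n_baseline <- function(x) {
  nb <- attr(x, "n_baseline", exact = TRUE)
  if (is.null(nb)) 0L else as.integer(nb)
}

value_col <- function(x) {
  if ("conc_mM" %in% names(x)) "conc_mM" else if ("si" %in% names(x)) "si" else
    abort("expected a `conc_mM` or `si` column.")
}

#' Cumulative integral of a concentration curve
#'
#' Cumulative trapezoidal integral \eqn{\int_0^t C(\tau)\,d\tau} of a
#' uniformly sampled curve. The result starts at zero and carries units
#' of mM s.
#'
#' @param curve a `conc_curve` (or any data frame with `time_s` and a
#'   value column).
#' @return A tibble with columns `time_s` and `value` (mM s).
#' @examples
#' cp <- conc_curve(0:10, rep(2, 11))
#' cum_integral(cp)$value[11]  # 2 mM * 10 s = 20 mM s
#' @export
cum_integral <- function(curve) {
  if (nrow(curve) < 2) abort("need at least 2 samples to integrate.")
  y <- curve[[value_col(curve)]]
  tibble(time_s = curve$time_s, value = cumtrapz(curve$time_s, y))
}

cumtrapz <- function(t, y) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve> %d frames, dt = %.4g s, %d baseline\n",
              nrow(x), if (nrow(x) > 1) curve_dt(x) else NA_real_, n_baseline(x)))
  NextMethod()
}

#' @export
print.dyn_series <- function(x, ...) {
  cat(sprintf("<dyn_series> %d frames, dt = %.4g s, %d baseline\n",
              nrow(x), if (nrow(x) > 1) curve_dt(x) else NA_real_, n_baseline(x)))
  NextMethod()
}
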