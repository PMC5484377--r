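#' Kinetic parameter set
#'
#' Bundles the transfer constant Ktrans (1/min, the field's printed
#' convention), the fractional plasma volume vp, and optionally the
#' fractional extravascular extracellular volume ve. The backflux rate
#' kep = Ktrans/ve (1/min) is derived. Conversion to 1/s happens only at
#' the integration boundary inside the forward models.
#'
#' @param ktrans volume transfer constant, 1/min.
#' @param vp fractional plasma volume in \[0, 1\].
#' @param ve fractional EES volume (> 0), or `NULL` for the
#'   unidirectional (no-backflux) model. Physically ve is at most 1;
#'   larger values are accepted so the vanishing-backflux limit
#'   (`kep -> 0`) can be expressed.
#' @param allow_negative permit negative `ktrans`/`vp` (useful when
#'   carrying fitted values; forward synthesis rejects them by default).
#' @return A list of class `kinetic_params` with elements `ktrans`,
#'   `vp`, `ve`, `kep`.
#' @examples
#' kinetic_params(ktrans = 0.0074, vp = 0.024, ve = 0.20)
#' @export
kinetic_params <- function(ktrans, vp, ve = NULL, allow_negative = FALSE) {
  if (!allow_negative && (ktrans < 0 || vp < 0)) {
    abort("negative `ktrans`/`vp` need `allow_negative = TRUE`.")
  }
  if (vp > 1) abort("`vp` must not exceed 1.")
  if (!is.null(ve) && ve <= 0) abort("`ve` must be positive.")
  structure(
    list(ktrans = ktrans, vp = vp, ve = ve,
         kep = if (is.null(ve)) NULL else ktrans / ve),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> ktrans = %.4g /min, vp = %.4g%s\n",
              x$ktrans, x$vp,
              if (is.null(x$ve)) "" else
                sprintf(", ve = %.3g (kep = %.4g /min)", x$ve, x$kep)))
  invisible(x)
}

#' Unidirectional two-compartment tissue concentration
#'
#' Forward model with no backflux:
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)\,d\tau.}
#' This is the model the Patlak plot linearises; on data generated by it
#' the plot is exactly a straight line.
#'
#' @param cp plasma concentration curve (`conc_curve`, baseline zero).
#' @param params a [kinetic_params()] (`ve` unused here).
#' @return A `conc_curve` of tissue concentration.
#' @export
tissue_conc_unidirectional <- function(cp, params) {
  stopifnot(inherits(params, "kinetic_params"))
  kt_s <- params$ktrans / 60
  ct <- params$vp * cp$conc_mM + kt_s * cumtrapz(cp$time_s, cp$conc_mM)
  conc_curve(cp$time_s, ct, n_baseline(cp))
}

#' Modified Tofts tissue concentration (with backflux)
#'
#' Forward model including bidirectional exchange with the EES:
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans}\int_0^t C_p(\tau)
#'   e^{-k_{ep}(t - \tau)}\,d\tau, \quad k_{ep} = K^{trans}/v_e.}
#' The convolution is evaluated with the exact recursive update for a
#' piecewise-linear plasma curve under the exponential kernel, which is
#' numerically exact at coarse sampling for small `kep` (no FFT edge
#' effects). As `ve` grows the kernel flattens and the model reduces to
#' [tissue_conc_unidirectional()].
#'
#' @inheritParams tissue_conc_unidirectional
#' @param params a [kinetic_params()] with `ve` set.
#' @return A `conc_curve` of tissue concentration.
#' @export
tissue_conc_tofts <- function(cp, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$ve)) abort("`params$ve` must be set for the Tofts model.")
  kt_s <- params$ktrans / 60
  kep_s <- params$kep / 60
  conv <- exp_conv_plin(cp$time_s, cp$conc_mM, kep_s)
  conc_curve(cp$time_s, params$vp * cp$conc_mM + kt_s * conv, n_baseline(cp))
}

# exact \int_0^t c(tau) exp(-k (t - tau)) dtau for piecewise-linear c.
# The step weights i0 = int_0^h exp(-k(h-s)) ds and
# i1 = int_0^h s exp(-k(h-s)) ds are evaluated with expm1 and, for
# k*h << 1, by series, to stay accurate in the vanishing-backflux limit.
exp_conv_plin <- function(t, c, k) {
  n <- length(c)
  out <- numeric(n)
  dt <- diff(t)
  if (k <= 0) return(cumtrapz(t, c))
  for (i in seq_len(n - 1)) {
    h <- dt[i]
    kh <- k * h
    e <- exp(-kh)
    i0 <- -expm1(-kh) / k
    i1 <- if (kh < 1e-4) {
      h^2 * (0.5 - kh / 6 + kh^2 / 24)
    } else {
      (h - i0) / k
    }
    c0 <- c[i]
    c1 <- c[i + 1]
    out[i + 1] <- e * out[i] + c0 * i0 + (c1 - c0) * i1 / h
  }
  out
}

#' Concentration-stretched time (the Patlak abscissa)
#'
#' Transforms lab time to stretched time
#' \eqn{t_{stretch}(t) = \int_0^t C_p(\tau) d\tau \, / \, C_p(t)}.
#' Early in the bolus this fluctuates; beyond the first pass it grows
#' approximately linearly and faster than lab time. Samples where
#' \eqn{C_p} falls below `cp_floor_frac` of its peak are masked invalid
#' (division blow-up near baseline).
#'
#' @param cp plasma concentration curve, baseline-subtracted (zero
#'   before injection).
#' @param cp_floor_frac validity floor as a fraction of the `cp` peak.
#' @return A tibble with columns `time_s`, `cp`, `t_stretch`, `valid`.
#' @export
stretch_time <- function(cp, cp_floor_frac = 0.05) {
  intg <- cumtrapz(cp$time_s, cp$conc_mM)
  ts <- intg / cp$conc_mM
  floor_val <- cp_floor_frac * max(cp$conc_mM)
  valid <- is.finite(ts) & cp$conc_mM >= floor_val & cp$conc_mM > 0
  if (!any(valid)) abort("all samples masked; no usable plasma signal.")
  ts[!is.finite(ts)] <- NA_real_
  tibble(time_s = cp$time_s, cp = cp$conc_mM, t_stretch = ts, valid = valid)
}
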