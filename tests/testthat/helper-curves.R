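# Shared fixtures: the study-condition plasma curve and truth parameters.
# Built once per test run; everything downstream derives from these.

study_truth <- function() kinetic_params(ktrans = 0.0074, vp = 0.024, ve = 0.20)

study_cp <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- synth_aif()
    cached
  }
})

study_ct_tofts <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- tissue_conc_tofts(study_cp(), study_truth())
    cached
  }
})

study_ct_unidir <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      cached <<- tissue_conc_unidirectional(study_cp(), study_truth())
    }
    cached
  }
})

# independent trapezoid rule (plain loop), used as an oracle
trapz_oracle <- function(t, y) {
  s <- 0
  for (i in 2:length(y)) s <- s + (y[i] + y[i - 1]) / 2 * (t[i] - t[i - 1])
  s
}

pd_pct <- function(measured, true) 100 * (measured - true) / true
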