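#' Read and write per-ROI curves as CSV
#'
#' Curves travel as two-column CSV (`time_s`, `value`); the baseline
#' count rides along as a `n_baseline` argument/attribute since CSV has
#' no header metadata.
#'
#' @param path file path.
#' @param n_baseline number of pre-injection frames in the stored curve.
#' @param kind `"conc"` (mM) or `"si"` (signal intensity).
#' @return A `conc_curve` or `dyn_series`.
#' @export
read_curve_csv <- function(path, n_baseline = 0L, kind = c("conc", "si")) {
  kind <- match.arg(kind)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d))) {
    abort("curve CSV must have columns `time_s` and `value`.")
  }
  if (kind == "conc") {
    conc_curve(d$time_s, d$value, n_baseline)
  } else {
    dyn_series(d$time_s, d$value, n_baseline)
  }
}

#' @rdname read_curve_csv
#' @param x a `conc_curve` or `dyn_series`.
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(
    data.frame(time_s = x$time_s, value = x[[value_col(x)]]),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a 4D dynamic NIfTI series
#'
#' Loads a NIfTI-1 volume whose fourth dimension is time and attaches
#' the acquisition metadata that the header cannot be trusted to carry.
#' When the header's temporal pixdim disagrees with `dt`, the
#' configuration wins and a warning is raised.
#'
#' @param path NIfTI file path.
#' @param dt frame spacing in seconds (authoritative).
#' @param n_baseline number of pre-injection frames.
#' @return A list with `data` (4D array), `dt`, `n_baseline`, `image`
#'   (the RNifti image, for header/affine round-trips).
#' @export
read_dynamic_nifti <- function(path, dt, n_baseline) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4) {
    abort(sprintf("expected a 4D series; got %d dimensions.",
                  length(dim(img))))
  }
  hdr_dt <- RNifti::pixdim(img)[4]
  if (is.finite(hdr_dt) && hdr_dt > 0 && abs(hdr_dt - dt) > 1e-6 * dt) {
    warn(sprintf("header dt %.4g s differs from configured dt %.4g s; using the configuration.",
                 hdr_dt, dt))
  }
  list(data = array(as.numeric(img), dim = dim(img)), dt = dt,
       n_baseline = as.integer(n_baseline), image = img)
}

#' Write a 3D parametric map as NIfTI
#'
#' @param map 3D numeric or logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param template optional RNifti image whose geometry is copied.
#' @export
write_nifti_map <- function(map, path, template = NULL) {
  img <- if (is.null(template)) {
    RNifti::asNifti(array(as.numeric(map), dim = dim(map)))
  } else {
    RNifti::asNifti(array(as.numeric(map), dim = dim(map)),
                    reference = template)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an analysis result with a reproducibility manifest
#'
#' Serialises any of the package's result objects (fits, Monte-Carlo
#' tables) as JSON/CSV next to a manifest recording the configuration
#' hash, seed and package version, so a run can be reproduced from its
#' output directory alone.
#'
#' @param result a `patlak_fit`, `hybrid_fit`, or tibble (e.g. from
#'   [monte_carlo_pd()]).
#' @param outdir output directory (created if missing).
#' @param config optional list describing the run (seed, parameters);
#'   stored and hashed into the manifest.
#' @param name stem for the result files.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(result, outdir, config = NULL, name = "result") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(result, c("patlak_fit", "hybrid_fit"))) {
    payload <- as.list(glance(result))
    jsonlite::write_json(payload, file.path(outdir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (is.data.frame(result)) {
    utils::write.csv(result, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  } else {
    jsonlite::write_json(result, file.path(outdir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest <- list(
    name = name,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("dcehybrid")),
    config = config,
    config_hash = rlang::hash(config),
    result_hash = rlang::hash(strip_env(result))
  )
  jsonlite::write_json(manifest, file.path(outdir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# drop closures/environments so hashing is stable across sessions
strip_env <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (inherits(x, c("patlak_fit", "hybrid_fit"))) return(as.list(glance(x)))
  x
}
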