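# StandardSpectrum container --------------------------------------------------

#' Construct a standard (pure-compound) spectrum
#'
#' A `standard_spectrum` holds one metabolite's 1D spectrum: a strictly
#' monotone chemical-shift axis in ppm and an intensity vector of equal
#' length. Internally all spectra use an ascending ppm axis; the original
#' on-disk direction is recorded so writers can restore it.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities, same length as `ppm`.
#' @param metabolite_id Metabolite identifier.
#' @param experiment_id Experiment identifier (one metabolite may have
#'   several standard spectra, e.g. acquired at different pH).
#' @param stage Processing stage: `"raw"`, `"preprocessed"` or
#'   `"normalized"`.
#' @param ppm_descending Logical; was the source axis stored descending?
#' @return An object of class `standard_spectrum`.
#' @export
standard_spectrum <- function(ppm, intensity, metabolite_id = "unknown",
                              experiment_id = "1", stage = "raw",
                              ppm_descending = FALSE) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop_validation("ppm and intensity must have equal length")
  if (length(ppm) < 2L)
    stop_validation("a spectrum needs at least 2 points")
  d <- diff(ppm)
  if (all(d < 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
    ppm_descending <- TRUE
  } else if (!all(d > 0)) {
    stop_validation("ppm axis must be strictly monotone")
  }
  stage <- match.arg(stage, c("raw", "preprocessed", "normalized"))
  if (stage == "normalized") {
    if (abs(sum(intensity) - 1) > 1e-9)
      stop_validation("normalized spectrum must sum to 1")
    if (min(intensity) < 0)
      stop_validation("normalized spectrum must be non-negative")
  }
  structure(
    list(ppm = ppm, intensity = intensity,
         metabolite_id = as.character(metabolite_id),
         experiment_id = as.character(experiment_id),
         stage = stage, ppm_descending = isTRUE(ppm_descending)),
    class = "standard_spectrum"
  )
}

#' @export
print.standard_spectrum <- function(x, ...) {
  cat(sprintf("<standard_spectrum> %s (experiment %s), %d points, %.3f..%.3f ppm, stage=%s\n",
              x$metabolite_id, x$experiment_id, length(x$ppm),
              min(x$ppm), max(x$ppm), x$stage))
  invisible(x)
}

#' @export
length.standard_spectrum <- function(x) length(x$ppm)

# replace intensities, keep axis/metadata; stage may change
update_intensity <- function(spectrum, intensity, stage = spectrum$stage) {
  spectrum$intensity <- as.numeric(intensity)
  spectrum$stage <- stage
  spectrum
}

#' Build a uniform ppm grid
#'
#' @param ppm_min,ppm_max Grid limits in ppm.
#' @param n Number of points (>= 2).
#' @return Ascending numeric vector of `n` equally spaced ppm values.
#' @export
ppm_grid <- function(ppm_min, ppm_max, n) {
  assert_scalar_number(ppm_min, "ppm_min")
  assert_scalar_number(ppm_max, "ppm_max")
  if (ppm_min >= ppm_max) stop_validation("ppm_min must be < ppm_max")
  if (n < 2) stop_validation("grid needs at least 2 points")
  seq(ppm_min, ppm_max, length.out = as.integer(n))
}
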