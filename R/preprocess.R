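# Standard-spectrum preprocessing ---------------------------------------------
#
# Pipeline order (a fixed contract): regrid -> exclusion zeroing ->
# moving-median baseline correction -> negative-artifact removal ->
# kernel smoothing; unit-integral normalisation is applied before mixing.
# Threshold comparisons are strict '<': values equal to a threshold are
# never modified.

#' Linearly interpolate a spectrum onto a target ppm grid
#'
#' Grid points outside the spectrum's ppm range get intensity 0.
#'
#' @param spectrum A [standard_spectrum()].
#' @param grid Ascending numeric ppm vector (see [ppm_grid()]).
#' @return The spectrum resampled on `grid`.
#' @export
regrid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "standard_spectrum"))
  y <- stats::approx(spectrum$ppm, spectrum$intensity, xout = grid,
                     method = "linear", rule = 1)$y
  y[is.na(y)] <- 0
  out <- spectrum
  out$ppm <- as.numeric(grid)
  out$intensity <- y
  out
}

#' Zero intensities inside exclusion regions
#'
#' Every grid point whose ppm lies in any closed interval is set to
#' exactly 0; defaults target the internal-reference (TSP) region below
#' 0.2 ppm and the residual water/urea region 4.5--6.0 ppm.
#'
#' @param spectrum A [standard_spectrum()].
#' @param regions List of length-2 numeric intervals `c(lo, hi)` in ppm.
#' @return The spectrum with excluded points zeroed.
#' @export
apply_exclusion_regions <- function(spectrum, regions) {
  y <- spectrum$intensity
  for (r in regions) {
    y[spectrum$ppm >= r[1L] & spectrum$ppm <= r[2L]] <- 0
  }
  update_intensity(spectrum, y)
}

#' Moving-median baseline correction
#'
#' The grid is partitioned into consecutive windows of width `window` ppm;
#' the within-window median, assigned at the window centre and linearly
#' interpolated between centres (constant beyond the outermost centres),
#' estimates the baseline. A threshold of `max(intensity) / divisor`
#' protects peaks: only points strictly below it have the baseline
#' subtracted.
#'
#' @param spectrum A [standard_spectrum()] on the target grid.
#' @param window Window width in ppm (default 0.3125).
#' @param divisor Threshold divisor (default 10).
#' @return Baseline-corrected spectrum with attributes `baseline` and
#'   `threshold`.
#' @export
baseline_correct <- function(spectrum, window = 0.3125, divisor = 10) {
  assert_scalar_number(window, "window", lower = 1e-15)
  assert_scalar_number(divisor, "divisor", lower = 1e-15)
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  spacing <- (ppm[length(ppm)] - ppm[1L]) / (length(ppm) - 1L)
  if (window < spacing)
    stop_validation("baseline window (", window,
                    " ppm) is smaller than the grid spacing (", spacing, ")")
  range_ppm <- ppm[length(ppm)] - ppm[1L]
  n_windows <- max(1L, ceiling(range_ppm / window))
  # a point landing exactly on the upper edge joins the last window
  win_id <- pmin(floor((ppm - ppm[1L]) / window), n_windows - 1L) + 1L
  centres <- tapply(ppm, win_id, mean)
  medians <- tapply(y, win_id, stats::median)
  if (length(centres) == 1L) {
    baseline <- rep(medians[[1L]], length(y))
  } else {
    baseline <- stats::approx(as.numeric(centres), as.numeric(medians),
                              xout = ppm, method = "linear", rule = 2)$y
  }
  threshold <- max(y) / divisor
  corrected <- y
  low <- y < threshold
  corrected[low] <- y[low] - baseline[low]
  out <- update_intensity(spectrum, corrected)
  attr(out, "baseline") <- baseline
  attr(out, "threshold") <- threshold
  out
}

# noise SD estimate: median of per-bin SDs over n_bins contiguous
# equal-count (in points) bins
estimate_sigma_med <- function(y, n_bins) {
  n <- length(y)
  n_bins <- max(1L, min(as.integer(n_bins), n))
  bin <- if (n_bins == 1L) rep(1L, n)
         else as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  sds <- tapply(y, bin, stats::sd)
  sds[is.na(sds)] <- 0
  stats::median(as.numeric(sds))
}

#' Remove negative artifacts by clipping at a noise-derived limit
#'
#' The spectrum is split into `n_bins` contiguous bins (equal point
#' counts); the median of the per-bin SDs estimates the noise SD
#' `sigma_med`. With `M` the median intensity, the limit is
#' `l = M - 3 * sigma_med` and every intensity strictly below `l` is set
#' equal to `l`.
#'
#' @param spectrum A [standard_spectrum()].
#' @param n_bins Number of bins (default 32).
#' @return Clipped spectrum with attributes `limit`, `sigma_med`, `M`.
#' @export
remove_negative_artifacts <- function(spectrum, n_bins = 32L) {
  assert_scalar_number(n_bins, "n_bins", lower = 1)
  y <- spectrum$intensity
  if (n_bins > length(y))
    stop_validation("n_bins exceeds the number of points")
  sigma_med <- estimate_sigma_med(y, n_bins)
  M <- stats::median(y)
  l <- M - 3 * sigma_med
  y[y < l] <- l
  out <- update_intensity(spectrum, y)
  attr(out, "limit") <- l
  attr(out, "sigma_med") <- sigma_med
  attr(out, "M") <- M
  out
}

kernel_weight_fun <- function(kernel) {
  switch(kernel,
         normal = function(u) stats::dnorm(u),
         box = function(u) as.numeric(abs(u) <= 1),
         triangle = function(u) pmax(1 - abs(u), 0),
         epanechnikov = function(u) pmax(0.75 * (1 - u^2), 0),
         stop_validation("unknown kernel: ", kernel))
}

kernel_halfwidth <- function(kernel, bandwidth) {
  if (kernel == "normal") as.integer(ceiling(3 * bandwidth))
  else as.integer(ceiling(bandwidth))
}

#' Kernel smoothing of sub-threshold intensities
#'
#' Points with intensity strictly below `threshold_fraction * max` are
#' replaced by the kernel-weighted mean of the available (sub-threshold)
#' neighbours within +/- 3 bandwidths (normal kernel) or +/- 1 bandwidth
#' (compact kernels), with weights `K(index distance / bandwidth)`
#' renormalised over those neighbours. Points at or above the threshold
#' are untouched and excluded as sources, so peaks are neither broadened
#' nor leaked into the noise floor.
#'
#' @param spectrum A [standard_spectrum()].
#' @param kernel One of `"normal"`, `"box"`, `"triangle"`,
#'   `"epanechnikov"`.
#' @param bandwidth Bandwidth in data points (>= 1).
#' @param threshold_fraction Fraction of the maximum intensity in (0, 1].
#' @return Smoothed spectrum.
#' @export
kernel_smooth <- function(spectrum, kernel = "normal", bandwidth = 5L,
                          threshold_fraction = 0.8) {
  assert_scalar_number(bandwidth, "bandwidth", lower = 1)
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop_validation("threshold_fraction must be in (0, 1]")
  wf <- kernel_weight_fun(kernel)
  hw <- kernel_halfwidth(kernel, bandwidth)
  y <- spectrum$intensity
  n <- length(y)
  threshold <- threshold_fraction * max(y)
  low <- y < threshold
  offsets <- (-hw):hw
  w <- wf(offsets / bandwidth)
  num <- numeric(n)
  den <- numeric(n)
  mask <- as.numeric(low)   # only sub-threshold points act as sources
  ym <- y * mask
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    if (w[j] == 0) next
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w[j] * ym[src[ok]]
    den[ok] <- den[ok] + w[j] * mask[src[ok]]
  }
  out_y <- y
  out_y[low] <- num[low] / den[low]   # den > 0: the point itself is low
  update_intensity(spectrum, out_y)
}

#' Normalise a spectrum to unit integrated intensity
#'
#' Divides every intensity by the total so that the intensities sum to 1,
#' putting all standards on a comparable scale before mixing.
#'
#' @param spectrum A [standard_spectrum()] with positive total intensity.
#' @return Spectrum with `stage = "normalized"`.
#' @export
normalize_unit_integral <- function(spectrum) {
  tot <- sum(spectrum$intensity)
  if (tot <= 0)
    stop_validation("cannot normalise: spectrum of '",
                    spectrum$metabolite_id,
                    "' has non-positive total intensity ",
                    "(metabolite contributes no signal)")
  update_intensity(spectrum, spectrum$intensity / tot, stage = "normalized")
}

#' Full preprocessing of a raw standard spectrum
#'
#' Applies, in order: regridding, exclusion zeroing, baseline correction,
#' negative-artifact removal and kernel smoothing, returning the
#' preprocessed (not yet normalised) spectrum plus a report of the
#' quantities used.
#'
#' @param spectrum Raw [standard_spectrum()].
#' @param params A `simulation_parameters` list
#'   (see [default_parameters()]).
#' @param grid Optional precomputed ppm grid; built from `params` if
#'   omitted.
#' @return List with elements `spectrum` (stage `"preprocessed"`) and
#'   `report` (a `preprocess_report`).
#' @export
preprocess_standard <- function(spectrum, params = default_parameters(),
                                grid = NULL) {
  if (is.null(grid))
    grid <- ppm_grid(params$ppm_min, params$ppm_max, params$n_points)
  s <- regrid(spectrum, grid)
  s <- apply_exclusion_regions(s, params$exclusion_regions)
  s <- baseline_correct(s, params$baseline_window, params$baseline_divisor)
  bl_threshold <- attr(s, "threshold")
  s <- remove_negative_artifacts(s, params$n_noise_bins)
  sigma_med <- attr(s, "sigma_med")
  limit <- attr(s, "limit")
  M <- attr(s, "M")
  pre_smooth <- s$intensity
  s <- kernel_smooth(s, params$kernel, params$kernel_bandwidth,
                     params$smoothing_threshold_fraction)
  s$stage <- "preprocessed"
  report <- structure(list(
    metabolite_id = spectrum$metabolite_id,
    experiment_id = spectrum$experiment_id,
    baseline_threshold = bl_threshold,
    sigma_med = sigma_med,
    M = M,
    clip_limit = limit,
    exclusion_regions = params$exclusion_regions,
    kernel = params$kernel,
    kernel_bandwidth = params$kernel_bandwidth,
    points_smoothed = sum(s$intensity != pre_smooth)
  ), class = "preprocess_report")
  list(spectrum = s, report = report)
}

#' Serialise a preprocessing report to JSON
#' @param report A `preprocess_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
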