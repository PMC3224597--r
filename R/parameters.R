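# Simulation parameters -------------------------------------------------------

#' Default simulation parameters
#'
#' Returns the full parameter set with its documented defaults:
#' \describe{
#'   \item{n_replicates}{replicates per group (50)}
#'   \item{ppm_min, ppm_max, n_points}{target ppm grid (0 to 10 ppm, 2^14)}
#'   \item{snr}{signal-to-noise ratio of the final mixture; `Inf` disables
#'     noise (default 200)}
#'   \item{exclusion_regions}{list of ppm intervals zeroed in every
#'     standard: below 0.2 ppm (internal reference, TSP) and 4.5--6.0 ppm
#'     (residual water and urea)}
#'   \item{baseline_window}{moving-median window width, 0.3125 ppm}
#'   \item{baseline_divisor}{baseline threshold = max intensity / 10}
#'   \item{n_noise_bins}{bins for the noise-SD estimate in negative-artifact
#'     removal (32)}
#'   \item{kernel, kernel_bandwidth}{smoothing kernel (`"normal"`) and
#'     bandwidth in data points (5)}
#'   \item{smoothing_threshold_fraction}{only intensities below this
#'     fraction of the maximum are smoothed (0.8)}
#'   \item{peak_min_height_fraction, peak_noise_multiple}{peak-detection
#'     thresholds (0.01 of the global maximum; 5 times the noise SD)}
#'   \item{multiplet_tolerance}{max ppm distance for matching a detected
#'     peak to a tabulated multiplet peak (0.03 ppm)}
#'   \item{shift_enabled}{simulate pH-driven peak shifts (TRUE)}
#'   \item{ph_mode, ph_value, ph_mean, ph_sd}{`"fixed"` uses `ph_value` for
#'     every replicate; `"sampled"` draws pH per replicate from
#'     N(ph_mean, ph_sd^2); urine default mean 6.3, sd 0.3}
#'   \item{pka_mean, pka_sd}{normal fallback for missing pKa (6.5, 0.5)}
#'   \item{limit_offset_mean, limit_offset_sd}{normal fallback for missing
#'     acid/base limits, sampled as +/- offsets (ppm) around the tabulated
#'     peak position (0.05, 0.01)}
#'   \item{noise_enabled, final_smoothing}{switches for the mixture noise
#'     and the final apodization-like smoothing pass (both TRUE)}
#'   \item{max_attempts_factor}{rejection-sampling budget, attempts per
#'     requested draw (1000)}
#'   \item{case_mode}{`"explicit_template"` or `"fold_change"`}
#'   \item{rng_seed}{root seed (1)}
#' }
#'
#' @return A `simulation_parameters` list.
#' @export
default_parameters <- function() {
  structure(list(
    n_replicates = 50L,
    ppm_min = 0, ppm_max = 10, n_points = 16384L,
    snr = 200,
    exclusion_regions = list(c(-Inf, 0.2), c(4.5, 6.0)),
    baseline_window = 0.3125,
    baseline_divisor = 10,
    n_noise_bins = 32L,
    kernel = "normal",
    kernel_bandwidth = 5L,
    smoothing_threshold_fraction = 0.8,
    peak_min_height_fraction = 0.01,
    peak_noise_multiple = 5,
    multiplet_tolerance = 0.03,
    shift_enabled = TRUE,
    ph_mode = "fixed", ph_value = 6.3, ph_mean = 6.3, ph_sd = 0.3,
    pka_mean = 6.5, pka_sd = 0.5,
    limit_offset_mean = 0.05, limit_offset_sd = 0.01,
    noise_enabled = TRUE,
    final_smoothing = TRUE,
    max_attempts_factor = 1000L,
    case_mode = "explicit_template",
    rng_seed = 1L
  ), class = "simulation_parameters")
}

validate_parameters <- function(p) {
  assert_scalar_number(p$n_replicates, "n_replicates", lower = 1)
  if (p$ppm_min >= p$ppm_max) stop_validation("ppm_min must be < ppm_max")
  assert_scalar_number(p$n_points, "n_points", lower = 2)
  if (!is.numeric(p$snr) || length(p$snr) != 1L || is.na(p$snr) || p$snr <= 0)
    stop_validation("snr must be > 0 (Inf allowed)")
  assert_scalar_number(p$baseline_window, "baseline_window", lower = 1e-12)
  assert_scalar_number(p$baseline_divisor, "baseline_divisor", lower = 1e-12)
  assert_scalar_number(p$n_noise_bins, "n_noise_bins", lower = 1)
  if (!p$kernel %in% c("normal", "box", "triangle", "epanechnikov"))
    stop_validation("unknown kernel: ", p$kernel)
  assert_scalar_number(p$kernel_bandwidth, "kernel_bandwidth", lower = 1)
  if (p$smoothing_threshold_fraction <= 0 ||
      p$smoothing_threshold_fraction > 1)
    stop_validation("smoothing_threshold_fraction must be in (0, 1]")
  if (!p$ph_mode %in% c("fixed", "sampled"))
    stop_validation("ph_mode must be 'fixed' or 'sampled'")
  if (p$ph_sd < 0) stop_validation("ph_sd must be >= 0")
  if (!p$case_mode %in% c("explicit_template", "fold_change"))
    stop_validation("unknown case_mode: ", p$case_mode)
  for (r in p$exclusion_regions)
    if (length(r) != 2L || r[1L] > r[2L])
      stop_validation("exclusion region must be an interval lo <= hi")
  invisible(p)
}

#' Load simulation parameters from a key=value config file
#'
#' Flat `key = value` text with `#` comments. Absent keys take the defaults
#' of [default_parameters()]; unknown keys produce a warning but do not
#' fail. Exclusion regions are written as semicolon-separated intervals,
#' e.g. `exclusion_regions = -Inf:0.2; 4.5:6.0`. Logical values accept
#' true/false; `snr = Inf` disables noise.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A validated `simulation_parameters` list.
#' @export
load_parameters <- function(path = NULL) {
  p <- default_parameters()
  if (is.null(path)) return(validate_parameters(p))
  if (!file.exists(path)) stop_format("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      stop_format("unparseable line ", i, " in ", path, ": ", lines[i])
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(p)) {
      warning("unknown parameter '", key, "' in ", path, " (ignored)",
              call. = FALSE)
      next
    }
    p[[key]] <- parse_parameter_value(key, val, p[[key]], path, i)
  }
  validate_parameters(p)
}

parse_parameter_value <- function(key, val, default, path, lineno) {
  oops <- function() stop_format("unparseable value for '", key,
                                 "' at line ", lineno, " of ", path,
                                 ": ", val)
  if (key == "exclusion_regions") {
    if (toupper(val) %in% c("NONE", "")) return(list())
    parts <- strsplit(val, ";", fixed = TRUE)[[1L]]
    regs <- lapply(parts, function(s) {
      lohi <- suppressWarnings(as.numeric(strsplit(trimws(s), ":")[[1L]]))
      if (length(lohi) != 2L || anyNA(lohi)) oops()
      lohi
    })
    return(regs)
  }
  if (is.logical(default)) {
    lv <- toupper(val)
    if (lv %in% c("TRUE", "T", "YES", "1")) return(TRUE)
    if (lv %in% c("FALSE", "F", "NO", "0")) return(FALSE)
    oops()
  }
  if (is.character(default)) return(val)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num) && toupper(val) != "NA") {
    if (toupper(val) %in% c("INF", "INFINITE")) return(Inf)
    oops()
  }
  if (is.na(num)) oops()
  if (is.integer(default)) return(as.integer(num))
  num
}

#' Write simulation parameters as a key=value snapshot
#' @param params A `simulation_parameters` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  fmt <- function(key) {
    v <- params[[key]]
    if (key == "exclusion_regions") {
      if (length(v) == 0L) return("none")
      return(paste(vapply(v, function(r) paste0(r[1L], ":", r[2L]), ""),
                   collapse = "; "))
    }
    as.character(v)
  }
  writeLines(sprintf("%s = %s", names(params),
                     vapply(names(params), fmt, "")), path)
  invisible(path)
}
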