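# pH-driven peak positional shifts --------------------------------------------
#
# Peaks are detected in each preprocessed standard, matched to tabulated
# multiplets, and each multiplet is translated rigidly by an amount given
# by the Henderson-Hasselbalch relation between its acid-limit and
# base-limit positions at the replicate's pH. As the titration relation
# is written here, pH >> pKa drives a peak to its tabulated acid-limit
# position and pH << pKa to the base-limit position; callers supply the
# limit columns in whichever order matches their titration data.

#' Detect peaks in a spectrum
#'
#' Local maxima strictly greater than both neighbours whose intensity
#' reaches `max(min_height_fraction * global max, noise_multiple *
#' sigma_med)`, where `sigma_med` is the binned noise-SD estimate used in
#' negative-artifact removal. Plateau apexes take the centre point, ties
#' broken toward lower ppm.
#'
#' @param spectrum Preprocessed [standard_spectrum()].
#' @param min_height_fraction Fraction of the global maximum (default
#'   0.01).
#' @param noise_multiple Multiple of the noise SD (default 5).
#' @param n_noise_bins Bins for the noise estimate (default 32).
#' @return Data frame with columns `index`, `ppm`, `intensity`,
#'   `multiplet` (NA until assigned).
#' @export
detect_peaks <- function(spectrum, min_height_fraction = 0.01,
                         noise_multiple = 5, n_noise_bins = 32L) {
  y <- spectrum$intensity
  n <- length(y)
  sigma_med <- estimate_sigma_med(y, n_noise_bins)
  threshold <- max(min_height_fraction * max(y),
                   noise_multiple * sigma_med)
  apexes <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      # walk over a possible plateau
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) {
        # plateau centre; ties toward lower ppm
        apexes <- c(apexes, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- apexes[y[apexes] >= threshold & y[apexes] > 0]
  data.frame(index = keep, ppm = spectrum$ppm[keep],
             intensity = y[keep],
             multiplet = rep(NA_integer_, length(keep)))
}

#' Assign detected peaks to tabulated multiplets
#'
#' Each detected peak is assigned to the multiplet containing the nearest
#' tabulated peak position within `tolerance` ppm; unmatched peaks remain
#' unassigned (and are never shifted). When two tabulated peaks are
#' equidistant within tolerance the lower-ppm entry wins and a warning is
#' issued. All peaks of one multiplet shift together downstream.
#'
#' @param peaks Data frame from [detect_peaks()] for one metabolite.
#' @param multiplets List of multiplets for that metabolite (one element
#'   of a `multiplet_table`).
#' @param tolerance Maximum match distance in ppm (default 0.03).
#' @return `peaks` with the `multiplet` column filled where matched.
#' @export
group_multiplets <- function(peaks, multiplets, tolerance = 0.03) {
  if (nrow(peaks) == 0L || length(multiplets) == 0L) return(peaks)
  tab <- do.call(rbind, lapply(seq_along(multiplets), function(m) {
    data.frame(multiplet = m, position = multiplets[[m]]$peaks)
  }))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(tab$position - peaks$ppm[i])
    if (min(d) > tolerance) next
    hits <- which(d == min(d))
    if (length(hits) > 1L) {
      hits <- hits[which.min(tab$position[hits])]
      warning("peak at ", format(peaks$ppm[i]),
              " ppm equidistant from several tabulated peaks; ",
              "assigned to the lower-ppm entry", call. = FALSE)
    }
    peaks$multiplet[i] <- tab$multiplet[hits]
  }
  peaks
}

#' Sample per-replicate pH values
#'
#' In fixed mode every replicate gets the user's pH; in sampled mode pH
#' values are i.i.d. normal with the configured mean and SD.
#'
#' @param params `simulation_parameters` (uses `ph_mode`, `ph_value`,
#'   `ph_mean`, `ph_sd`).
#' @param n_replicates Number of values.
#' @return Numeric vector of pH values.
#' @export
sample_ph <- function(params, n_replicates) {
  if (params$ph_sd < 0) stop_validation("ph_sd must be >= 0")
  if (params$ph_mode == "fixed") {
    rep(params$ph_value, n_replicates)
  } else {
    stats::rnorm(n_replicates, params$ph_mean, params$ph_sd)
  }
}

#' Henderson-Hasselbalch peak shift
#'
#' Computes the shift (ppm) of a peak at `delta` between its acid-limit
#' position `a` and base-limit position `b`:
#' `eta = (exp(pH - pKa) * (a - delta) - delta + b) / (exp(pH - pKa) + 1)`,
#' evaluated in the overflow-safe logistic form
#' `eta = s * (a - delta) + (1 - s) * (b - delta)` with
#' `s = plogis(pH - pKa)`. The shifted position `delta + eta` is the
#' logistic interpolation `s * a + (1 - s) * b`: at pH = pKa it is the
#' midpoint `(a + b) / 2`, and the limits are `a` (pH - pKa -> +Inf) and
#' `b` (pH - pKa -> -Inf).
#'
#' @param delta Unshifted peak position (ppm).
#' @param a,b Acid- and base-limit positions (ppm).
#' @param pKa Metabolite pKa (one per metabolite).
#' @param pH Sample pH.
#' @return Shift `eta` in ppm (vectorised).
#' @export
henderson_hasselbalch_shift <- function(delta, a, b, pKa, pH) {
  if (any(!is.finite(c(delta, a, b, pKa, pH))))
    stop_validation("all titration inputs must be finite")
  s <- stats::plogis(pH - pKa)
  s * (a - delta) + (1 - s) * (b - delta)
}

#' Build shift assignments for one metabolite and replicate
#'
#' Detects peaks, groups them into multiplets, fills in missing pKa and
#' acid/base limits from the configured normal fallbacks (one draw per
#' metabolite-replicate; limits are sampled as symmetric offsets around
#' the tabulated positions so their ordering stays sane), and evaluates
#' one shift per multiplet at the multiplet's mean position.
#'
#' @param spectrum Preprocessed [standard_spectrum()].
#' @param multiplets Multiplet list for this metabolite (may be empty).
#' @param params `simulation_parameters`.
#' @param pH The replicate's pH.
#' @return A `shift_assignment`: data frame with one row per assigned
#'   multiplet (`multiplet`, `delta`, `a`, `b`, `pKa`, `pH`, `eta`) plus
#'   attribute `peaks` (the detected-peak table).
#' @export
build_shift_assignment <- function(spectrum, multiplets, params, pH) {
  peaks <- detect_peaks(spectrum, params$peak_min_height_fraction,
                        params$peak_noise_multiple, params$n_noise_bins)
  peaks <- group_multiplets(peaks, multiplets, params$multiplet_tolerance)
  assigned <- sort(unique(peaks$multiplet[!is.na(peaks$multiplet)]))
  # one pKa per metabolite: take the first tabulated value, else sample once
  pka_tab <- if (length(multiplets))
    vapply(multiplets, function(m) m$pKa, 0) else numeric(0)
  pKa <- if (any(!is.na(pka_tab))) pka_tab[!is.na(pka_tab)][1L]
         else stats::rnorm(1L, params$pka_mean, params$pka_sd)
  rows <- lapply(assigned, function(m) {
    mult <- multiplets[[m]]
    delta <- mean(mult$peaks)
    if (is.null(mult$acid)) {
      off <- abs(stats::rnorm(1L, params$limit_offset_mean,
                              params$limit_offset_sd))
      a <- delta + off
      b <- delta - off
    } else {
      a <- mean(mult$acid)
      b <- mean(mult$base)
    }
    data.frame(multiplet = m, delta = delta, a = a, b = b, pKa = pKa,
               pH = pH,
               eta = henderson_hasselbalch_shift(delta, a, b, pKa, pH))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(multiplet = integer(0), delta = numeric(0), a = numeric(0),
               b = numeric(0), pKa = numeric(0), pH = numeric(0),
               eta = numeric(0))
  attr(out, "peaks") <- peaks
  class(out) <- c("shift_assignment", "data.frame")
  out
}

# flanking local minima around a multiplet's detected apex indices
segment_bounds <- function(y, apex_idx) {
  n <- length(y)
  lo <- min(apex_idx)
  hi <- max(apex_idx)
  while (lo > 1L && y[lo - 1L] < y[lo]) lo <- lo - 1L
  while (hi < n && y[hi + 1L] < y[hi]) hi <- hi + 1L
  c(lo, hi)
}

#' Shift assigned multiplets in a spectrum
#'
#' For each assigned multiplet, the spectral segment spanning its detected
#' peaks out to the nearest flanking local minima is translated by the
#' nearest-grid-point rounding of its shift `eta`; vacated points are
#' filled with the pre-shift local baseline level (the smaller of the two
#' original segment-edge intensities). A shift that would push a segment
#' off the grid is clipped at the edge with a warning. Finally the whole
#' spectrum is kernel-smoothed once more below the smoothing threshold to
#' suppress translation artifacts.
#'
#' @param spectrum Preprocessed [standard_spectrum()].
#' @param assignment A `shift_assignment` from [build_shift_assignment()].
#' @param params `simulation_parameters`.
#' @param resmooth Apply the final smoothing pass? Default `TRUE`.
#' @return The shifted spectrum.
#' @export
shift_spectrum <- function(spectrum, assignment, params, resmooth = TRUE) {
  y <- spectrum$intensity
  n <- length(y)
  spacing <- (spectrum$ppm[n] - spectrum$ppm[1L]) / (n - 1L)
  peaks <- attr(assignment, "peaks")
  for (r in seq_len(nrow(assignment))) {
    m <- assignment$multiplet[r]
    apex_idx <- peaks$index[!is.na(peaks$multiplet) & peaks$multiplet == m]
    if (length(apex_idx) == 0L) next
    shift_pts <- as.integer(round(assignment$eta[r] / spacing))
    if (shift_pts == 0L) next
    seg <- segment_bounds(y, apex_idx)
    lo <- seg[1L]; hi <- seg[2L]
    new_lo <- lo + shift_pts; new_hi <- hi + shift_pts
    if (new_lo < 1L || new_hi > n) {
      warning("shift clips multiplet ", m, " of ",
              spectrum$metabolite_id, " at the grid edge", call. = FALSE)
      shift_pts <- if (new_lo < 1L) 1L - lo else n - hi
      new_lo <- lo + shift_pts; new_hi <- hi + shift_pts
      if (shift_pts == 0L) next
    }
    fill <- min(y[lo], y[hi])
    segment <- y[lo:hi]
    y[lo:hi] <- fill
    y[new_lo:new_hi] <- segment
  }
  out <- update_intensity(spectrum, y)
  if (resmooth)
    out <- kernel_smooth(out, params$kernel, params$kernel_bandwidth,
                         params$smoothing_threshold_fraction)
  out
}

#' Write shift assignments for one replicate as CSV
#' @param assignments Named list (by metabolite) of `shift_assignment`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_assignments <- function(assignments, path) {
  rows <- lapply(names(assignments), function(met) {
    a <- assignments[[met]]
    if (nrow(a) == 0L) return(NULL)
    cbind(metabolite = met, as.data.frame(a))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), multiplet = integer(0),
               delta = numeric(0), a = numeric(0), b = numeric(0),
               pKa = numeric(0), pH = numeric(0), eta = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
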