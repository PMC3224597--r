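# Synthetic standards database ------------------------------------------------
#
# A self-contained generator of pure-compound fixtures with Lorentzian
# multiplets, polynomial baselines, optional noise, negative dips and
# optional lineshape asymmetry (two half-widths mixed), together with the
# metadata files of a complete standards database. Ground-truth peak
# positions and areas are recorded so end-to-end recovery can be checked.

#' Specify a synthetic Lorentzian standard
#'
#' @param multiplets List of multiplet specs, each a list with `centre`
#'   (ppm), `j_spacing` (ppm between adjacent multiplet peaks), `weights`
#'   (relative peak heights, e.g. `c(1, 2, 1)` for a triplet),
#'   `half_width` (Lorentzian half-width at half-maximum, ppm), `area`
#'   (total multiplet area weight), and optional `asymmetry` (> 0 mixes a
#'   second half-width `half_width * (1 + asymmetry)` into the right wing).
#' @param baseline Polynomial coefficients (constant first) of a baseline
#'   in ppm.
#' @param noise_sd SD of additive white noise.
#' @param dips Optional data frame with columns `ppm`, `depth` adding
#'   narrow negative artifacts.
#' @return A `lorentzian_spec`.
#' @export
lorentzian_spec <- function(multiplets, baseline = 0, noise_sd = 0,
                            dips = NULL) {
  for (m in multiplets) {
    if (m$half_width <= 0) stop_validation("half_width must be > 0")
    if (any(m$weights <= 0)) stop_validation("weights must be positive")
  }
  structure(list(multiplets = multiplets, baseline = baseline,
                 noise_sd = noise_sd, dips = dips),
            class = "lorentzian_spec")
}

# unit-area Lorentzian: (1/pi) * gamma / ((x - x0)^2 + gamma^2)
lorentzian <- function(x, x0, gamma) {
  (gamma / pi) / ((x - x0)^2 + gamma^2)
}

#' Render a synthetic standard spectrum from a Lorentzian spec
#'
#' Peak `i` of a multiplet gets area
#' `area * weights[i] / sum(weights)`; the rendered intensity adds the
#' baseline polynomial, noise, and any negative dips. The returned truth
#' record lists every peak's exact position and analytic area.
#'
#' @param spec A [lorentzian_spec()].
#' @param grid Ascending ppm grid.
#' @param metabolite_id,experiment_id Identifiers for the result.
#' @return List with `spectrum` (a raw [standard_spectrum()]) and `truth`
#'   (data frame: `multiplet`, `peak`, `ppm`, `area`, `half_width`).
#' @export
make_lorentzian_standard <- function(spec, grid, metabolite_id = "synthetic",
                                     experiment_id = "1") {
  stopifnot(inherits(spec, "lorentzian_spec"))
  y <- numeric(length(grid))
  truth <- list()
  for (mi in seq_along(spec$multiplets)) {
    m <- spec$multiplets[[mi]]
    k <- length(m$weights)
    positions <- m$centre + (seq_len(k) - (k + 1) / 2) * m$j_spacing
    areas <- m$area * m$weights / sum(m$weights)
    asym <- if (is.null(m$asymmetry)) 0 else m$asymmetry
    for (i in seq_len(k)) {
      if (asym > 0) {
        # asymmetric line: wider right wing, heights matched at the apex,
        # whole shape renormalised to unit analytic area
        g1 <- m$half_width
        g2 <- g1 * (1 + asym)
        left <- grid <= positions[i]
        shape <- numeric(length(grid))
        shape[left] <- lorentzian(grid[left], positions[i], g1)
        shape[!left] <- lorentzian(grid[!left], positions[i], g2) * (g2 / g1)
        shape <- shape / ((1 + g2 / g1) / 2)
        y <- y + areas[i] * shape
      } else {
        y <- y + areas[i] * lorentzian(grid, positions[i], m$half_width)
      }
      truth[[length(truth) + 1L]] <-
        data.frame(multiplet = mi, peak = i, ppm = positions[i],
                   area = areas[i], half_width = m$half_width)
    }
  }
  for (j in seq_along(spec$baseline))
    y <- y + spec$baseline[j] * grid^(j - 1)
  if (spec$noise_sd > 0)
    y <- y + stats::rnorm(length(grid), 0, spec$noise_sd)
  if (!is.null(spec$dips)) {
    for (i in seq_len(nrow(spec$dips))) {
      idx <- which.min(abs(grid - spec$dips$ppm[i]))
      y[idx] <- y[idx] - spec$dips$depth[i]
    }
  }
  list(spectrum = standard_spectrum(grid, y, metabolite_id, experiment_id,
                                    stage = "raw"),
       truth = do.call(rbind, truth))
}

#' Generate a complete synthetic standards database
#'
#' Writes `n_metabolites` synthetic standards (in both the text and the
#' Bruker-style dialect) plus all metadata files — proton counts,
#' multiplet table (with pKa and acid/base limits for roughly half the
#' metabolites, omitted for the rest to exercise the fallback sampling),
#' experiment selection, synonyms and a control concentration template —
#' into `out_dir`. Deterministic given `seed`. Peak positions avoid the
#' default exclusion regions (below 0.2 ppm and 4.5--6.0 ppm).
#'
#' @param n_metabolites Number of metabolites (>= 1).
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param n_points Points per stored standard spectrum (default 4096).
#' @param noise_sd Noise SD in each standard (default 0.002; peak areas
#'   are of order 1).
#' @param baseline_amplitude Scale of random linear baselines (default
#'   0.01).
#' @return Invisibly, a list with `dir`, `metabolites` and `truth`
#'   (named list of truth data frames).
#' @export
make_synthetic_nssd <- function(n_metabolites, out_dir, seed = 1L,
                                n_points = 4096L, noise_sd = 0.002,
                                baseline_amplitude = 0.01) {
  if (n_metabolites < 1) stop_validation("n_metabolites must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra_text"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
  grid <- ppm_grid(0, 10, n_points)
  mets <- sprintf("met%02d", seq_len(n_metabolites))
  patterns <- list(1, c(1, 1), c(1, 2, 1), c(1, 3, 3, 1))
  truth <- list()
  mtable <- list()
  with_seed(seed, {
    # spread multiplet centres over usable (non-excluded) ppm ranges
    usable <- rbind(c(0.5, 4.3), c(6.2, 9.5))
    for (i in seq_len(n_metabolites)) {
      n_mult <- 1L + (i %% 3L)
      mults <- list()
      mrecords <- list()
      met_pka <- stats::runif(1, 5.5, 7.5)   # one pKa per metabolite
      for (mi in seq_len(n_mult)) {
        seg <- usable[1L + (mi + i) %% 2L, ]
        centre <- stats::runif(1, seg[1L] + 0.2, seg[2L] - 0.2)
        weights <- patterns[[1L + (i + mi) %% length(patterns)]]
        hw <- stats::runif(1, 0.004, 0.010)
        jsp <- stats::runif(1, 0.015, 0.03)
        mults[[mi]] <- list(centre = centre, j_spacing = jsp,
                            weights = weights, half_width = hw,
                            area = stats::runif(1, 0.5, 2))
        k <- length(weights)
        peaks <- centre + (seq_len(k) - (k + 1) / 2) * jsp
        rec <- list(peaks = sort(peaks), pKa = NA_real_,
                    acid = NULL, base = NULL)
        if (i %% 2L == 0L) {         # half the metabolites get full data
          rec$pKa <- met_pka
          off <- stats::runif(1, 0.03, 0.08)
          rec$acid <- rec$peaks + off
          rec$base <- rec$peaks - off
        }
        mrecords[[mi]] <- rec
      }
      spec <- lorentzian_spec(
        mults,
        baseline = c(stats::runif(1, 0, baseline_amplitude),
                     stats::runif(1, -baseline_amplitude,
                                  baseline_amplitude) / 10),
        noise_sd = noise_sd)
      std <- make_lorentzian_standard(spec, grid, mets[i])
      truth[[mets[i]]] <- std$truth
      mtable[[mets[i]]] <- mrecords
      write_standard_spectrum(std$spectrum,
                              file.path(out_dir, "spectra_text",
                                        paste0(mets[i], "__1.txt")), "text")
      write_standard_spectrum(std$spectrum,
                              file.path(out_dir, "spectra", mets[i], "1"),
                              "bruker")
    }
    utils::write.csv(
      data.frame(metabolite = mets,
                 protons = sample(1:9, n_metabolites, replace = TRUE)),
      file.path(out_dir, "protons.csv"), row.names = FALSE, quote = FALSE)
    write_multiplet_table(structure(mtable, class = "multiplet_table"),
                          file.path(out_dir, "multiplets.txt"))
    utils::write.csv(data.frame(metabolite = mets, experiment = "1"),
                     file.path(out_dir, "experiments.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(external_name = toupper(mets),
                                nssd_id = mets),
                     file.path(out_dir, "synonyms.csv"),
                     row.names = FALSE, quote = FALSE)
    means <- round(stats::runif(n_metabolites, 50, 500), 1)
    write_concentration_template(
      concentration_template(mets, means, round(means / 1.95, 1)),
      file.path(out_dir, "templates_control.csv"))
  })
  invisible(list(dir = out_dir, metabolites = mets, truth = truth))
}
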