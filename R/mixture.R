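# Mixture assembly and experiment orchestration -------------------------------
#
# A mixture spectrum is the concentration- and proton-weighted sum of the
# normalised standards, plus white Gaussian noise at a user-controlled
# SNR, finally kernel-smoothed once to mimic the line-broadening effect
# of exponential apodization (which also gives the added noise a
# realistic autocorrelation structure).

#' Noise standard deviation from SNR
#'
#' `sigma_n = max_intensity / SNR`; an infinite SNR gives zero noise.
#'
#' @param max_intensity Maximum intensity of the noise-free mixture.
#' @param snr Signal-to-noise ratio (> 0, `Inf` allowed).
#' @return The noise SD.
#' @export
noise_sigma <- function(max_intensity, snr) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop_validation("SNR must be > 0 (Inf allowed)")
  if (max_intensity < 0)
    stop_validation("max_intensity must be >= 0")
  if (is.infinite(snr)) return(0)
  max_intensity / snr
}

#' Assemble one mixture spectrum from normalised standards
#'
#' Computes `y(delta) = sum_k y_k(delta) * c_k * p_k` over the normalised
#' standards, adds i.i.d. N(0, sigma_n^2) noise with
#' `sigma_n = max(y) / SNR`, and (optionally) kernel-smooths the
#' composite below the smoothing threshold.
#'
#' @param standards Named list of normalised [standard_spectrum()]s, all
#'   on the same grid.
#' @param concentrations Named numeric vector `c_k > 0` (names must match
#'   `standards`).
#' @param protons Named integer vector `p_k >= 1`.
#' @param params `simulation_parameters` (uses `snr`, `kernel`,
#'   `kernel_bandwidth`, `smoothing_threshold_fraction`,
#'   `noise_enabled`, `final_smoothing`).
#' @param group_label,replicate Metadata stored on the result.
#' @param pH pH recorded for this replicate (metadata).
#' @return A `mixture_spectrum`: list with `ppm`, `intensity`,
#'   `group_label`, `replicate`, `concentrations`, `pH`, `sigma_n`.
#' @export
assemble_mixture <- function(standards, concentrations, protons,
                             params = default_parameters(),
                             group_label = "control", replicate = 1L,
                             pH = NA_real_) {
  mets <- names(standards)
  if (is.null(mets) || !all(mets %in% names(concentrations)) ||
      !all(mets %in% names(protons)))
    stop_validation("standards, concentrations and protons must share names")
  ref_ppm <- standards[[1L]]$ppm
  y <- numeric(length(ref_ppm))
  for (met in mets) {
    s <- standards[[met]]
    if (s$stage != "normalized")
      stop_validation("standard '", met, "' is not normalised")
    if (length(s$ppm) != length(ref_ppm) ||
        any(s$ppm != ref_ppm))
      stop_validation("grid mismatch for standard '", met, "'")
    if (concentrations[[met]] <= 0)
      stop_validation("concentration for '", met, "' must be > 0")
    if (protons[[met]] < 1)
      stop_validation("proton count for '", met, "' must be >= 1")
    y <- y + s$intensity * concentrations[[met]] * protons[[met]]
  }
  sigma_n <- noise_sigma(max(y), params$snr)
  if (isTRUE(params$noise_enabled) && sigma_n > 0)
    y <- y + stats::rnorm(length(y), 0, sigma_n)
  else sigma_n <- 0
  if (isTRUE(params$final_smoothing)) {
    tmp <- standard_spectrum(ref_ppm, y, "mixture", stage = "raw")
    tmp <- kernel_smooth(tmp, params$kernel, params$kernel_bandwidth,
                         params$smoothing_threshold_fraction)
    y <- tmp$intensity
  }
  structure(list(ppm = ref_ppm, intensity = y, group_label = group_label,
                 replicate = as.integer(replicate),
                 concentrations = concentrations[mets], pH = pH,
                 sigma_n = sigma_n),
            class = "mixture_spectrum")
}

#' @export
print.mixture_spectrum <- function(x, ...) {
  cat(sprintf("<mixture_spectrum> group=%s replicate=%d, %d points, %d metabolites, sigma_n=%.4g\n",
              x$group_label, x$replicate, length(x$ppm),
              length(x$concentrations), x$sigma_n))
  invisible(x)
}

# NSSD on-disk layout ---------------------------------------------------------
#
#   <dir>/protons.csv                 metabolite,protons
#   <dir>/multiplets.txt              pipe-delimited multiplet records
#   <dir>/experiments.csv             metabolite,experiment
#   <dir>/synonyms.csv                external_name,nssd_id
#   <dir>/spectra/<met>/<exp>/        bruker dialect (1r + procs)
#   <dir>/spectra_text/<met>__<exp>.txt   text dialect

#' Load an NMR standard spectra database directory
#'
#' @param dir Database directory (see layout in the package README).
#' @param dialect Which spectrum dialect to read, `"text"` or
#'   `"bruker"`.
#' @return An `nssd` object: list with `dir`, `dialect`, `protons`,
#'   `multiplets`, `experiments`, `synonyms`, `metabolites`.
#' @export
load_nssd <- function(dir, dialect = c("text", "bruker")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) stop_format("no such NSSD directory: ", dir)
  protons <- read_proton_table(file.path(dir, "protons.csv"))
  mpath <- file.path(dir, "multiplets.txt")
  multiplets <- if (file.exists(mpath)) read_multiplet_table(mpath)
                else structure(list(), class = "multiplet_table")
  epath <- file.path(dir, "experiments.csv")
  experiments <- if (file.exists(epath)) read_experiment_file(epath)
                 else stats::setNames(rep("1", length(protons)),
                                      names(protons))
  spath <- file.path(dir, "synonyms.csv")
  synonyms <- if (file.exists(spath)) read_synonym_file(spath)
              else stats::setNames(character(0), character(0))
  structure(list(dir = dir, dialect = dialect, protons = protons,
                 multiplets = multiplets, experiments = experiments,
                 synonyms = synonyms, metabolites = names(protons)),
            class = "nssd")
}

#' @export
print.nssd <- function(x, ...) {
  cat(sprintf("<nssd> %s: %d metabolites (%s dialect)\n",
              x$dir, length(x$metabolites), x$dialect))
  invisible(x)
}

#' Read one raw standard spectrum from an NSSD
#' @param nssd An `nssd` from [load_nssd()].
#' @param metabolite Metabolite id.
#' @return Raw [standard_spectrum()].
#' @export
nssd_spectrum <- function(nssd, metabolite) {
  exp_id <- if (metabolite %in% names(nssd$experiments))
    nssd$experiments[[metabolite]] else "1"
  if (nssd$dialect == "text") {
    path <- file.path(nssd$dir, "spectra_text",
                      paste0(metabolite, "__", exp_id, ".txt"))
    read_standard_spectrum(path, "text", metabolite, exp_id)
  } else {
    path <- file.path(nssd$dir, "spectra", metabolite, exp_id)
    read_standard_spectrum(path, "bruker", metabolite, exp_id)
  }
}

# stable numeric digest of a template so that identical group templates
# yield identical random substreams (and hence identical groups under a
# noise-free, shift-free run with the same root seed)
template_digest <- function(template) {
  s <- paste(template$metabolite, format(template$mean, digits = 15),
             format(template$sd, digits = 15), collapse = "|")
  chars <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(chars))
    h <- (h * 31 + chars[i]) %% 2147483647
  as.integer(h)
}

#' Simulate a two-group mixture experiment
#'
#' For each group the pipeline: resolve template metabolites against the
#' database (via synonyms), draw replicate concentrations (correlated if
#' a correlation spec is given), preprocess each required standard once,
#' optionally apply per-replicate pH-driven peak shifts, normalise, and
#' assemble each replicate mixture with noise and final smoothing. The
#' whole run is deterministic given `params$rng_seed`.
#'
#' @param nssd An `nssd` from [load_nssd()].
#' @param control,case [concentration_template()]s for the two groups
#'   (`case` may be `NULL` for a single-group run).
#' @param params `simulation_parameters`.
#' @param correlations Optional correlation spec data frame (applies to
#'   both groups).
#' @return An `experiment_result`: list with `control` and `case` (lists
#'   of `mixture_spectrum`), `draws` (per-group `concentration_draws`),
#'   `ph` (per-group pH vectors), `params`, `seed`.
#' @export
simulate_experiment <- function(nssd, control, case = NULL,
                                params = default_parameters(),
                                correlations = NULL) {
  validate_parameters(params)
  groups <- list(control = control)
  if (!is.null(case)) groups$case <- case
  grid <- ppm_grid(params$ppm_min, params$ppm_max, params$n_points)

  # resolve ids and preprocess every required standard once, cached
  resolve <- function(template) apply_synonyms(template, nssd$synonyms)
  groups <- lapply(groups, resolve)
  needed <- unique(unlist(lapply(groups, function(g) g$metabolite)))
  missing_spec <- setdiff(needed, nssd$metabolites)
  if (length(missing_spec))
    stop_validation("metabolite(s) not in the standards database: ",
                    paste(missing_spec, collapse = ", "))
  missing_prot <- setdiff(needed, names(nssd$protons))
  if (length(missing_prot))
    stop_validation("metabolite(s) missing a proton count: ",
                    paste(missing_prot, collapse = ", "))
  pre <- lapply(stats::setNames(needed, needed), function(met) {
    preprocess_standard(nssd_spectrum(nssd, met), params, grid)
  })
  reports <- lapply(pre, `[[`, "report")
  pre_spectra <- lapply(pre, `[[`, "spectrum")

  root <- as.integer(params$rng_seed)
  result_groups <- list()
  draws_out <- list()
  ph_out <- list()
  shift_tables <- list()
  for (gname in names(groups)) {
    template <- groups[[gname]]
    gdig <- template_digest(template)
    draws <- simulate_concentrations(
      template, params$n_replicates, correlations,
      seed = derive_seed(root, gdig, 1L),
      max_attempts_factor = params$max_attempts_factor)
    ph <- with_seed(derive_seed(root, gdig, 2L),
                    sample_ph(params, params$n_replicates))
    mets <- template$metabolite
    specs <- list()
    gshifts <- list()
    for (r in seq_len(params$n_replicates)) {
      if (isTRUE(params$shift_enabled)) {
        rep_standards <- list()
        rep_assign <- list()
        with_seed(derive_seed(root, gdig, 3L, r), {
          for (met in mets) {
            mlist <- if (met %in% names(nssd$multiplets))
              nssd$multiplets[[met]] else list()
            asg <- build_shift_assignment(pre_spectra[[met]], mlist,
                                          params, ph[r])
            rep_assign[[met]] <- asg
            rep_standards[[met]] <- normalize_unit_integral(
              shift_spectrum(pre_spectra[[met]], asg, params))
          }
        })
        gshifts[[r]] <- rep_assign
      } else {
        rep_standards <- lapply(pre_spectra[mets], normalize_unit_integral)
      }
      specs[[r]] <- with_seed(
        derive_seed(root, gdig, 4L, r),
        assemble_mixture(rep_standards[mets],
                         stats::setNames(draws$draws[r, mets], mets),
                         nssd$protons[mets], params,
                         group_label = gname, replicate = r, pH = ph[r]))
    }
    result_groups[[gname]] <- specs
    draws_out[[gname]] <- draws
    ph_out[[gname]] <- ph
    if (isTRUE(params$shift_enabled)) shift_tables[[gname]] <- gshifts
  }
  structure(list(control = result_groups$control,
                 case = result_groups$case,
                 draws = draws_out, ph = ph_out,
                 shift_assignments = if (length(shift_tables))
                   shift_tables else NULL,
                 preprocess_reports = reports,
                 params = params, seed = root),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> control: %d replicates%s, seed=%d\n",
              length(x$control),
              if (!is.null(x$case))
                sprintf(", case: %d replicates", length(x$case)) else "",
              x$seed))
  invisible(x)
}

#' Stack a group's mixture spectra into a matrix
#' @param result An `experiment_result`.
#' @param group `"control"` or `"case"`.
#' @return Matrix (n_points x n_replicates) with the ppm axis as
#'   attribute `ppm`.
#' @export
spectra_matrix <- function(result, group = "control") {
  specs <- result[[group]]
  if (is.null(specs)) stop_validation("no such group: ", group)
  m <- vapply(specs, function(s) s$intensity, numeric(length(specs[[1L]]$ppm)))
  colnames(m) <- paste0(group, "_", seq_along(specs))
  attr(m, "ppm") <- specs[[1L]]$ppm
  m
}

#' Write all artifacts of an experiment to a directory
#'
#' Emits, per group: the spectra matrix as TSV (first column `ppm`, one
#' column per replicate), the concentration draws and pH values as CSV;
#' plus the requested/repaired correlation and covariance matrices (when
#' correlated), the per-standard preprocessing reports (JSON), and a
#' parameter snapshot.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_experiment_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gname in c("control", "case")) {
    if (is.null(result[[gname]])) next
    m <- spectra_matrix(result, gname)
    df <- data.frame(ppm = attr(m, "ppm"), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("spectra_", gname, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    draws <- result$draws[[gname]]
    utils::write.csv(as.data.frame(draws$draws),
                     file.path(dir, paste0("concentrations_", gname, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(replicate = seq_along(result$ph[[gname]]),
                                pH = result$ph[[gname]]),
                     file.path(dir, paste0("ph_", gname, ".csv")),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(draws$R_repaired)) {
      utils::write.csv(as.data.frame(draws$R_requested),
                       file.path(dir, paste0("correlation_requested_",
                                             gname, ".csv")))
      utils::write.csv(as.data.frame(draws$R_repaired),
                       file.path(dir, paste0("correlation_repaired_",
                                             gname, ".csv")))
      utils::write.csv(as.data.frame(draws$Sigma),
                       file.path(dir, paste0("covariance_", gname, ".csv")))
    }
    if (!is.null(result$shift_assignments[[gname]])) {
      for (r in seq_along(result$shift_assignments[[gname]]))
        write_shift_assignments(
          result$shift_assignments[[gname]][[r]],
          file.path(dir, sprintf("shifts_%s_rep%03d.csv", gname, r)))
    }
  }
  for (met in names(result$preprocess_reports))
    write_preprocess_report(result$preprocess_reports[[met]],
                            file.path(dir, paste0("preprocess_", met,
                                                  ".json")))
  write_parameters(result$params, file.path(dir, "parameters.txt"))
  invisible(dir)
}
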