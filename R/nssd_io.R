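# Reading and writing standard spectra and metadata tables -------------------
#
# Two spectrum dialects are supported:
#   * "text": two whitespace- or comma-separated columns (ppm, intensity),
#     '#' starts a comment line.
#   * "bruker": a Bruker-style processed-data directory holding the real
#     spectrum as 32-bit signed integers in a file named "1r" plus a "procs"
#     text parameter file. The subset of parameters read is
#       ##$SI       number of points
#       ##$OFFSET   ppm of the first stored point
#       ##$SW       spectral width in ppm
#       ##$BYTORDP  byte order (0 = little endian, 1 = big endian)
#       ##$NC_proc  intensity scaling exponent (intensities x 2^NC_proc)
#     Point i (0-based) sits at OFFSET - i * SW / SI, i.e. the stored axis
#     descends, as in Bruker processed data.

#' Read a standard spectrum from disk
#'
#' @param path File (text dialect) or directory (bruker dialect).
#' @param dialect `"text"` or `"bruker"`.
#' @param metabolite_id,experiment_id Identifiers attached to the result;
#'   default to the file/directory name.
#' @return A [standard_spectrum()] with `stage = "raw"` and an ascending
#'   ppm axis (the on-disk direction is recorded in `ppm_descending`).
#' @export
read_standard_spectrum <- function(path, dialect = c("text", "bruker"),
                                   metabolite_id = NULL,
                                   experiment_id = "1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_format("no such file or directory: ", path)
  if (is.null(metabolite_id))
    metabolite_id <- basename(sub("/+$", "", path))
  if (dialect == "text") {
    read_spectrum_text(path, metabolite_id, experiment_id)
  } else {
    read_spectrum_bruker(path, metabolite_id, experiment_id)
  }
}

read_spectrum_text <- function(path, metabolite_id, experiment_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_format("empty spectrum file: ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop_format("line ", bad[1L], " of ", path,
                " does not have two columns")
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(ppm) || anyNA(intensity))
    stop_format("non-numeric value in ", path)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop_validation("ppm axis in ", path, " is not strictly monotone")
  standard_spectrum(ppm, intensity, metabolite_id, experiment_id,
                    stage = "raw")
}

read_procs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_par <- function(key) {
    rx <- paste0("^##\\$", key, "=\\s*(.+)\\s*$")
    hit <- grep(rx, lines, value = TRUE)
    if (length(hit) == 0L)
      stop_format("parameter ", key, " missing from ", path)
    as.numeric(sub(rx, "\\1", hit[1L]))
  }
  list(si = as.integer(get_par("SI")), offset = get_par("OFFSET"),
       sw = get_par("SW"), bytordp = as.integer(get_par("BYTORDP")),
       nc_proc = as.integer(get_par("NC_proc")))
}

read_spectrum_bruker <- function(dir, metabolite_id, experiment_id) {
  f1r <- file.path(dir, "1r")
  fpr <- file.path(dir, "procs")
  if (!file.exists(f1r)) stop_format("missing binary spectrum file: ", f1r)
  if (!file.exists(fpr)) stop_format("missing parameter file: ", fpr)
  p <- read_procs(fpr)
  if (!p$bytordp %in% c(0L, 1L))
    stop_format("unknown byte order BYTORDP=", p$bytordp, " in ", fpr)
  endian <- if (p$bytordp == 0L) "little" else "big"
  nbytes <- file.size(f1r)
  if (nbytes < 4L * p$si)
    stop_format("binary file ", f1r, " too short: expected ",
                4L * p$si, " bytes, found ", nbytes)
  con <- file(f1r, "rb")
  on.exit(close(con))
  raw_int <- readBin(con, integer(), n = p$si, size = 4L, endian = endian)
  intensity <- raw_int * 2^p$nc_proc
  i <- seq_len(p$si) - 1
  ppm <- p$offset - i * p$sw / p$si   # descending, as stored
  standard_spectrum(ppm, intensity, metabolite_id, experiment_id,
                    stage = "raw")
}

#' Write a standard spectrum to disk
#'
#' The text dialect writes full double precision and round-trips to 1e-9.
#' The bruker dialect scales intensities into 32-bit signed integers,
#' choosing the smallest scaling exponent `NC_proc` such that all values
#' fit; integer-valued inputs with `NC_proc = 0` round-trip exactly.
#'
#' @param spectrum A [standard_spectrum()].
#' @param path Output file (text) or directory (bruker; created).
#' @param dialect `"text"` or `"bruker"`.
#' @return `path`, invisibly.
#' @export
write_standard_spectrum <- function(spectrum, path,
                                    dialect = c("text", "bruker")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spectrum, "standard_spectrum"))
  if (dialect == "text") {
    # emit in the recorded on-disk direction for display compatibility
    ppm <- spectrum$ppm; y <- spectrum$intensity
    if (spectrum$ppm_descending) { ppm <- rev(ppm); y <- rev(y) }
    lines <- c(sprintf("# %s spectrum, experiment %s",
                       spectrum$metabolite_id, spectrum$experiment_id),
               sprintf("%.17g %.17g", ppm, y))
    writeLines(lines, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    ppm <- spectrum$ppm; y <- spectrum$intensity
    # store descending per the Bruker convention
    ppm <- rev(ppm); y <- rev(y)
    si <- length(ppm)
    spacing <- ppm[1L] - ppm[2L]
    sw <- spacing * si
    offset <- ppm[1L]
    # smallest exponent that avoids int32 overflow; integer-valued data
    # keeps NC_proc = 0 and round-trips exactly
    maxabs <- max(abs(y), 1)
    nc <- 0L
    while (maxabs / 2^nc > (2^31 - 1)) nc <- nc + 1L
    if (nc == 0L && !all(y == round(y))) {
      while (nc > -20L && maxabs / 2^(nc - 1L) <= (2^31 - 1)) nc <- nc - 1L
    }
    ints <- as.integer(round(y / 2^nc))
    writeLines(c("##TITLE= processed spectrum parameters",
                 sprintf("##$SI= %d", si),
                 sprintf("##$OFFSET= %.17g", offset),
                 sprintf("##$SW= %.17g", sw),
                 "##$BYTORDP= 0",
                 sprintf("##$NC_proc= %d", nc)),
               file.path(path, "procs"))
    con <- file(file.path(path, "1r"), "wb")
    writeBin(ints, con, size = 4L, endian = "little")
    close(con)
  }
  invisible(path)
}

# Metadata tables -------------------------------------------------------------

#' Construct a concentration template
#'
#' Per-metabolite mean and standard deviation of concentration for one
#' group, in consistent (micromolar-like) units.
#'
#' @param metabolite Character vector of unique metabolite ids.
#' @param mean,sd Non-negative numeric vectors.
#' @param group_label Group name, e.g. `"control"`.
#' @param units Units label.
#' @return A `concentration_template` (data.frame-backed).
#' @export
concentration_template <- function(metabolite, mean, sd,
                                   group_label = "control", units = "uM") {
  metabolite <- as.character(metabolite)
  if (anyDuplicated(metabolite))
    stop_validation("duplicate metabolite id: ",
                    metabolite[duplicated(metabolite)][1L])
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (any(!is.finite(mean)) || any(mean < 0))
    stop_validation("concentration means must be finite and non-negative")
  if (any(!is.finite(sd)) || any(sd < 0))
    stop_validation("concentration sds must be finite and non-negative")
  structure(
    data.frame(metabolite = metabolite, mean = mean, sd = sd,
               stringsAsFactors = FALSE),
    group_label = group_label, units = units,
    class = c("concentration_template", "data.frame")
  )
}

#' Read a concentration template file
#'
#' Delimited text with header columns `metabolite`, `mean`, `sd`.
#' A blank `sd` is filled in with [estimate_sd_from_mean()], i.e. mean / 1.95,
#' matching the convention used when a source database reports only a mean
#' or a half-range.
#'
#' @param path CSV file path.
#' @param group_label Group name attached to the template.
#' @return A [concentration_template()].
#' @export
read_concentration_template <- function(path, group_label = "control") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  need <- c("metabolite", "mean", "sd")
  if (!all(need %in% names(df)))
    stop_format(path, " must have columns metabolite, mean, sd")
  mean_num <- suppressWarnings(as.numeric(df$mean))
  bad <- which(is.na(mean_num))
  if (length(bad))
    stop_validation("non-numeric mean in row ", bad[1L], " of ", path)
  if (any(mean_num < 0))
    stop_validation("negative mean in ", path)
  sd_chr <- df$sd
  sd_num <- suppressWarnings(as.numeric(sd_chr))
  blank <- is.na(sd_num) & (is.na(sd_chr) | !nzchar(trimws(sd_chr)))
  if (any(is.na(sd_num) & !blank))
    stop_validation("non-numeric sd in row ",
                    which(is.na(sd_num) & !blank)[1L], " of ", path)
  sd_num[blank] <- estimate_sd_from_mean(mean_num[blank])
  concentration_template(df$metabolite, mean_num, sd_num,
                         group_label = group_label)
}

#' Write a concentration template
#' @param template A [concentration_template()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_template <- function(template, path) {
  utils::write.csv(as.data.frame(template), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a proton-count table
#'
#' CSV with columns `metabolite`, `protons`; proton counts are the number
#' of observed 1H nuclei per metabolite and must be positive integers.
#'
#' @param path CSV file path.
#' @return Named integer vector, names = metabolite ids.
#' @export
read_proton_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("metabolite", "protons") %in% names(df)))
    stop_format(path, " must have columns metabolite, protons")
  p <- as.integer(df$protons)
  if (anyNA(p) || any(p < 1L))
    stop_validation("proton counts must be integers >= 1 in ", path)
  if (anyDuplicated(df$metabolite))
    stop_validation("duplicate metabolite in ", path)
  stats::setNames(p, df$metabolite)
}

#' Read a multiplet table
#'
#' One multiplet per record, pipe-delimited:
#' ```
#' metabolite | peak1,peak2,... [| pKa=x] [| acid=a1,a2,...] [| base=b1,b2,...]
#' ```
#' Peak positions are chemical shifts in ppm; `acid`/`base` are the peak
#' positions in the acid and base titration limits and, when given, must
#' match the peak count. Lines starting with `#` are comments. Peaks are
#' sorted ascending within each multiplet (limits permuted alongside).
#'
#' @param path File path.
#' @return A `multiplet_table`: named list (by metabolite) of lists of
#'   multiplets, each with elements `peaks`, `pKa`, `acid`, `base`
#'   (the latter three may be `NA`/`NULL` when absent).
#' @export
read_multiplet_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- list()
  for (k in seq_along(lines)) {
    fields <- trimws(strsplit(lines[k], "|", fixed = TRUE)[[1L]])
    if (length(fields) < 2L)
      stop_format("record ", k, " in ", path,
                  " needs at least metabolite and peak list")
    met <- fields[1L]
    peaks <- as.numeric(strsplit(fields[2L], ",")[[1L]])
    if (anyNA(peaks))
      stop_format("non-numeric peak position in record ", k, " of ", path)
    m <- list(peaks = peaks, pKa = NA_real_, acid = NULL, base = NULL)
    for (f in fields[-(1:2)]) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop_format("malformed field '", f, "' in record ", k, " of ", path)
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (key == "pKa") {
        m$pKa <- as.numeric(val)
      } else if (key %in% c("acid", "base")) {
        v <- as.numeric(strsplit(val, ",")[[1L]])
        if (length(v) != length(peaks))
          stop_validation(key, " list length (", length(v),
                          ") != peak count (", length(peaks),
                          ") in record ", k, " of ", path)
        m[[key]] <- v
      } else {
        warning("unknown multiplet field '", key, "' in ", path,
                call. = FALSE)
      }
    }
    if (xor(is.null(m$acid), is.null(m$base)))
      stop_validation("record ", k, " in ", path,
                      " gives only one of acid/base limits")
    ord <- order(m$peaks)
    m$peaks <- m$peaks[ord]
    if (!is.null(m$acid)) { m$acid <- m$acid[ord]; m$base <- m$base[ord] }
    tab[[met]] <- c(tab[[met]], list(m))
  }
  # the titration model assumes one pKa per metabolite: enforce consistency
  for (met in names(tab)) {
    pkas <- vapply(tab[[met]], function(m) m$pKa, 0)
    known <- pkas[!is.na(pkas)]
    if (length(unique(known)) > 1L)
      stop_validation("metabolite ", met, " has conflicting pKa values in ",
                      path, " (one pKa per metabolite is assumed)")
  }
  structure(tab, class = "multiplet_table")
}

#' Write a multiplet table
#' @param table A `multiplet_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiplet_table <- function(table, path) {
  fmt_num <- function(v) paste(sprintf("%.6g", v), collapse = ",")
  lines <- character(0)
  for (met in names(table)) {
    for (m in table[[met]]) {
      rec <- paste(met, fmt_num(m$peaks), sep = " | ")
      if (!is.na(m$pKa)) rec <- paste0(rec, " | pKa=", sprintf("%.6g", m$pKa))
      if (!is.null(m$acid))
        rec <- paste0(rec, " | acid=", fmt_num(m$acid),
                      " | base=", fmt_num(m$base))
      lines <- c(lines, rec)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pairwise inter-metabolite correlation file
#'
#' CSV with columns `metabolite_a`, `metabolite_b`, `r`.
#'
#' @param path CSV file path.
#' @return Data frame with the three columns, validated: `|r| <= 1`, no
#'   self-pairs, no duplicate unordered pairs.
#' @export
read_correlation_spec <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("metabolite_a", "metabolite_b", "r") %in% names(df)))
    stop_format(path, " must have columns metabolite_a, metabolite_b, r")
  validate_correlation_spec(df)
}

validate_correlation_spec <- function(df) {
  if (any(!is.finite(df$r)) || any(abs(df$r) > 1))
    stop_validation("correlations must lie in [-1, 1]")
  if (any(df$metabolite_a == df$metabolite_b))
    stop_validation("self-correlation pair not allowed")
  key <- apply(cbind(df$metabolite_a, df$metabolite_b), 1L,
               function(x) paste(sort(x), collapse = "\r"))
  if (anyDuplicated(key))
    stop_validation("duplicate unordered metabolite pair in correlation spec")
  df
}

#' Read an experiment-selection file
#'
#' CSV with columns `metabolite`, `experiment`, choosing which standard
#' spectrum to use when a metabolite has several.
#'
#' @param path CSV file path.
#' @return Named character vector metabolite -> experiment id.
#' @export
read_experiment_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!all(c("metabolite", "experiment") %in% names(df)))
    stop_format(path, " must have columns metabolite, experiment")
  stats::setNames(df$experiment, df$metabolite)
}

#' Read a synonym map
#'
#' Two-column CSV (`external_name`, `nssd_id`) used to translate external
#' metabolite names (e.g. from a concentration database) to local standard
#' spectra ids.
#'
#' @param path CSV file path.
#' @return Named character vector external_name -> nssd_id.
#' @export
read_synonym_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!all(c("external_name", "nssd_id") %in% names(df)))
    stop_format(path, " must have columns external_name, nssd_id")
  stats::setNames(df$nssd_id, df$external_name)
}

#' Apply a synonym map to a concentration template
#'
#' Metabolite names found in the map are translated to their local ids;
#' names absent from the map are kept as-is if `keep_unmatched = TRUE`
#' (the default matches ids already in local form), otherwise dropped with
#' a warning listing them.
#'
#' @param template A [concentration_template()].
#' @param synonyms Named character vector from [read_synonym_file()].
#' @param keep_unmatched Keep rows whose names are not in the map?
#' @return A [concentration_template()] with translated ids.
#' @export
apply_synonyms <- function(template, synonyms, keep_unmatched = TRUE) {
  idx <- match(template$metabolite, names(synonyms))
  translated <- ifelse(is.na(idx), template$metabolite, synonyms[idx])
  if (!keep_unmatched && any(is.na(idx))) {
    missing <- template$metabolite[is.na(idx)]
    warning("dropping metabolites with no synonym match: ",
            paste(missing, collapse = ", "), call. = FALSE)
    keep <- !is.na(idx)
    return(concentration_template(translated[keep], template$mean[keep],
                                  template$sd[keep],
                                  group_label = attr(template, "group_label")))
  }
  concentration_template(translated, template$mean, template$sd,
                         group_label = attr(template, "group_label"))
}
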