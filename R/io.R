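# On-disk dialect: per dyad a long-format CSV
#   (subject, channel, wavelength_nm, sample_index, value)
# plus a JSON sidecar with sampling rate, sequence, channel gain/CV,
# video-onset markers, questionnaire items and satisfaction metadata.
# Cohorts add a cohort_manifest.tsv. The dialect round-trips exactly: readr
# writes shortest round-trip decimal representations of doubles.

sidecar_path <- function(csv_path) sub("_timeseries\\.csv$", "_meta.json", csv_path)

#' Write a dyad recording to disk
#'
#' @param recording A `dyad_recording`.
#' @param dir Output directory (created if needed).
#' @return The path of the time-series CSV, invisibly.
#' @export
write_dyad_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(recording$dyad_id, "_timeseries.csv"))
  readr::write_csv(recording$od, csv, progress = FALSE)
  meta <- list(
    dyad_id = recording$dyad_id,
    sequence_label = recording$sequence_label,
    sampling_rate = recording$sampling_rate,
    n_samples = recording$n_samples,
    channels = recording$channels,
    markers = recording$markers,
    ras = recording$ras,
    delta_sat = recording$delta_sat,
    kappa = recording$kappa
  )
  jsonlite::write_json(meta, sidecar_path(csv), auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(csv)
}

#' Read a dyad recording from the package's CSV dialect
#'
#' Validates completeness: both subjects present, the 8 analysis channels,
#' both wavelengths, sampling rate and video-onset markers in the sidecar.
#' Channels absent from the file stay absent (they are never zero-filled).
#'
#' @param path Path to the `*_timeseries.csv` file (its `*_meta.json`
#'   sidecar must sit next to it).
#' @param format Input dialect; only `"csv"` is supported. (`"snirf"` is
#'   reserved and raises a not-supported error.)
#' @return A `dyad_recording`.
#' @export
read_dyad_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf") {
    abort("SNIRF input is not supported by this build; use the CSV dialect.",
          class = "dyadsync_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "dyadsync_format_error")
  }
  od <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject", "channel", "wavelength_nm", "sample_index", "value")
  assert_columns(od, required, sprintf("\"%s\"", basename(path)))
  bad <- which(!is.finite(od$value) | is.na(od$channel))
  if (length(bad)) {
    abort(sprintf("Malformed record at row %d of %s.", bad[1], basename(path)),
          class = "dyadsync_format_error")
  }
  meta_file <- sidecar_path(path)
  if (!file.exists(meta_file)) {
    abort(sprintf("Sidecar %s not found.", basename(meta_file)),
          class = "dyadsync_format_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)

  subjects <- sort(unique(od$subject))
  if (length(subjects) != 2L) {
    abort(sprintf("Recording must contain two subjects, found: %s.",
                  paste(subjects, collapse = ", ")),
          class = "dyadsync_dyad_completeness_error")
  }
  if (!setequal(unique(od$wavelength_nm), c(760L, 850L))) {
    abort("Recording must contain both 760 nm and 850 nm series.",
          class = "dyadsync_format_error")
  }
  if (is.null(meta$markers) || length(meta$markers) == 0L ||
      is.null(meta$markers$onset_s) || length(meta$markers$onset_s) == 0L) {
    abort("Video-onset markers are missing from the sidecar.",
          class = "dyadsync_marker_missing_error")
  }
  if (is.null(meta$sampling_rate)) {
    abort("Sampling rate missing from the sidecar.",
          class = "dyadsync_format_error")
  }
  structure(list(
    dyad_id = meta$dyad_id %||% sub("_timeseries\\.csv$", "", basename(path)),
    sequence_label = meta$sequence_label,
    sampling_rate = meta$sampling_rate,
    n_samples = meta$n_samples %||% (max(od$sample_index) + 1L),
    od = tibble::as_tibble(od),
    channels = tibble::as_tibble(meta$channels),
    markers = tibble::as_tibble(meta$markers),
    ras = if (is.null(meta$ras)) NULL else lapply(meta$ras, as.integer),
    delta_sat = meta$delta_sat,
    kappa = meta$kappa %||% NA_real_
  ), class = "dyad_recording")
}

#' Write a simulated cohort and its manifest
#'
#' @param cohort List of recordings from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) write_dyad_recording(rec, dir)
  readr::write_tsv(cohort_manifest(cohort),
                   file.path(dir, "cohort_manifest.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `*_timeseries.csv` files and
#'   `cohort_manifest.tsv`.
#' @return A list of `dyad_recording`s with the manifest attached.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "_timeseries\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("No recordings found in %s.", dir),
          class = "dyadsync_format_error")
  }
  cohort <- lapply(files, read_dyad_recording)
  names(cohort) <- vapply(cohort, function(r) r$dyad_id, character(1))
  manifest_file <- file.path(dir, "cohort_manifest.tsv")
  if (file.exists(manifest_file)) {
    attr(cohort, "manifest") <- readr::read_tsv(manifest_file,
                                                show_col_types = FALSE,
                                                progress = FALSE)
  }
  cohort
}

#' Write the statistics report as JSON
#'
#' @param stats A `synchrony_stats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(stats, path) {
  report <- list(
    kw_three_way = stats$kw_three_way,
    kw_two_way = stats$kw_two_way,
    regression = lapply(stats$regression, function(f) {
      list(terms = tidy(f), df_residual = f$fit$df.residual, n = f$n)
    }),
    pearson = stats$pearson,
    options = stats$options
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
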