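#' Read a 12-lead pattern file
#'
#' Pattern files are plain CSV with header
#' `time_ms,I,II,III,aVR,aVL,aVF,V1,V2,V3,V4,V5,V6` and 500 data rows
#' (amplitudes in microvolts on a 1 ms grid). Metadata travels in a JSON
#' sidecar `<stem>.meta.json` holding `subject_id`, `session`,
#' `fiducial_index`, `qt_ms` and `rr_ms`. Files recorded on a different time
#' grid must be resampled to 1 ms before ingestion; [read_pattern()] does not
#' resample.
#'
#' @param path path to the pattern CSV; the sidecar is located by replacing
#'   the `.csv` extension with `.meta.json`.
#' @return A validated [ecg_pattern()].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("pattern file not found: %s", path),
          class = "ecgmatch_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("time_ms", LEADS)
  if (!identical(names(df), expected)) {
    abort(sprintf("bad pattern header in %s: expected columns %s",
                  path, paste(expected, collapse = ",")),
          class = "ecgmatch_format_error")
  }
  if (nrow(df) != PQRST_LEN) {
    abort(sprintf("%s: expected %d data rows, found %d",
                  path, PQRST_LEN, nrow(df)),
          class = "ecgmatch_format_error")
  }
  bad <- which(!purrr::map_lgl(df, is.numeric))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric values in column(s) %s",
                  path, paste(names(df)[bad], collapse = ", ")),
          class = "ecgmatch_format_error")
  }
  meta_path <- meta_sidecar(path)
  if (!file.exists(meta_path)) {
    abort(sprintf("missing metadata sidecar: %s", meta_path),
          class = "ecgmatch_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("subject_id", "session", "fiducial_index", "qt_ms", "rr_ms")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("%s: missing metadata field(s) %s",
                  meta_path, paste(miss, collapse = ", ")),
          class = "ecgmatch_format_error")
  }
  samples <- t(as.matrix(df[LEADS]))
  rownames(samples) <- LEADS
  ecg_pattern(samples, meta$subject_id, meta$session,
              meta$fiducial_index, meta$qt_ms, meta$rr_ms)
}

meta_sidecar <- function(path) {
  sub("\\.csv$", ".meta.json", path)
}

#' Write a 12-lead pattern file
#'
#' Writes the CSV body and the JSON metadata sidecar of the pattern file
#' dialect described in [read_pattern()]. Round-trips through
#' `read_pattern(write_pattern(p, path))` reproduce the pattern well within
#' 1e-3 microvolts.
#'
#' @param p a validated [ecg_pattern()].
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(p, path) {
  stopifnot(inherits(p, "ecg_pattern"))
  validate_ecg_pattern(p)
  df <- tibble(time_ms = 0:(PQRST_LEN - 1L))
  for (ld in LEADS) df[[ld]] <- signif(p$samples[ld, ], 7)
  readr::write_csv(df, path, progress = FALSE)
  meta <- list(subject_id = p$subject_id, session = p$session,
               fiducial_index = p$fiducial_index,
               qt_ms = p$qt_ms, rr_ms = p$rr_ms)
  jsonlite::write_json(meta, meta_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write the global aVR reference pattern
#'
#' The reference pattern is the 500-sample aVR PQRST trace of one healthy
#' enrolment recording, selected once per study and used to time-align every
#' pattern (see [align_to_reference()]). It is stored as a single-column CSV
#' of 500 aVR samples.
#'
#' @param path file path.
#' @return `read_reference()` returns a numeric vector of 500 samples.
#' @export
read_reference <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ref <- df[[1]]
  if (length(ref) != PQRST_LEN || !is.numeric(ref)) {
    abort(sprintf("%s: reference pattern must be %d numeric samples",
                  path, PQRST_LEN),
          class = "ecgmatch_format_error")
  }
  if (sd(ref) == 0) {
    abort("reference pattern is constant", class = "ecgmatch_degenerate_error")
  }
  ref
}

#' @rdname read_reference
#' @param ref numeric vector of 500 aVR samples (non-constant).
#' @export
write_reference <- function(ref, path) {
  stopifnot(length(ref) == PQRST_LEN, is.numeric(ref))
  readr::write_csv(tibble(aVR = ref), path, progress = FALSE)
  invisible(path)
}

#' Read a cohort directory into a tibble
#'
#' A cohort directory contains pattern files plus a `manifest.csv` with
#' columns `subject_id`, `session`, `file` (as written by
#' [generate_cohort()]). The returned tibble carries patterns as a
#' list-column so cohorts compose with the usual dplyr verbs.
#'
#' @param dir cohort directory.
#' @return A tibble with columns `subject_id`, `session` and `pattern`
#'   (list-column of [ecg_pattern()] objects).
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) {
    abort(sprintf("no manifest.csv in %s", dir),
          class = "ecgmatch_format_error")
  }
  m <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("subject_id", "session", "file") %in% names(m)))
  m |>
    mutate(
      subject_id = as.character(.data$subject_id),
      pattern = map(.data$file, ~ read_pattern(file.path(dir, .x)))
    ) |>
    select("subject_id", "session", "pattern")
}
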