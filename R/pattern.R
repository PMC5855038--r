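#' Construct a 12-lead beat pattern
#'
#' An `ecg_pattern` holds one subject-session: a 12-lead averaged PQRST beat
#' pattern of 500 ms sampled on a 1 ms grid (a 12 x 500 matrix in microvolts),
#' together with the fiducial index of the R-peak alignment point and beat
#' timing metadata (QT and RR intervals).
#'
#' Time indices in files and in `fiducial_index` are 0-based (matching the
#' `time_ms` column of the pattern file dialect, 0...499); matrix columns in R
#' are the usual 1-based columns, so 0-based time `t` lives in column `t + 1`.
#'
#' @param samples numeric 12 x 500 matrix, rows in the canonical lead order
#'   (I, II, III, aVR, aVL, aVF, V1...V6), amplitudes in microvolts.
#' @param subject_id opaque subject identifier string.
#' @param session session label, `"T1"` (enrolment) or `"T2"` (matching).
#' @param fiducial_index 0-based sample index of the R peak; must lie in
#'   \[30, 430\] so the 100 ms QRS window fits inside the pattern.
#' @param qt_ms,rr_ms QT and RR intervals in milliseconds (both > 0).
#'
#' @return An object of class `ecg_pattern`.
#' @seealso [read_pattern()], [extract_qrs()], [preprocess_pattern()]
#' @export
#' @examples
#' p <- ecg_pattern(matrix(rnorm(12 * 500), 12, 500), "s1", "T1",
#'                  fiducial_index = 250, qt_ms = 400, rr_ms = 900)
#' p
ecg_pattern <- function(samples, subject_id, session,
                        fiducial_index, qt_ms, rr_ms) {
  samples <- as.matrix(samples)
  p <- structure(
    list(
      subject_id = as.character(subject_id),
      session = as.character(session),
      samples = samples,
      fiducial_index = as.integer(fiducial_index),
      qt_ms = as.numeric(qt_ms),
      rr_ms = as.numeric(rr_ms)
    ),
    class = "ecg_pattern"
  )
  validate_ecg_pattern(p)
}

validate_ecg_pattern <- function(p) {
  s <- p$samples
  if (!is.matrix(s) || !is.numeric(s)) {
    abort("`samples` must be a numeric matrix.", class = "ecgmatch_format_error")
  }
  if (nrow(s) != 12L || ncol(s) != PQRST_LEN) {
    abort(sprintf("`samples` must be 12 x %d (got %d x %d).",
                  PQRST_LEN, nrow(s), ncol(s)),
          class = "ecgmatch_format_error")
  }
  if (anyNA(s) || any(!is.finite(s))) {
    abort("`samples` contains non-finite values.",
          class = "ecgmatch_format_error")
  }
  if (is.null(rownames(s))) {
    rownames(p$samples) <- LEADS
  } else if (!identical(rownames(s), LEADS)) {
    abort("lead rows must be exactly I, II, III, aVR, aVL, aVF, V1...V6 in order.",
          class = "ecgmatch_format_error")
  }
  if (!p$session %in% c("T1", "T2")) {
    abort('`session` must be "T1" or "T2".', class = "ecgmatch_format_error")
  }
  if (is.na(p$fiducial_index) ||
      p$fiducial_index < QRS_PRE || p$fiducial_index > PQRST_LEN - QRS_POST) {
    abort(sprintf("`fiducial_index` must lie in [%d, %d].",
                  QRS_PRE, PQRST_LEN - QRS_POST),
          class = "ecgmatch_format_error")
  }
  if (!isTRUE(p$qt_ms > 0) || !isTRUE(p$rr_ms > 0)) {
    abort("`qt_ms` and `rr_ms` must be positive.",
          class = "ecgmatch_format_error")
  }
  p
}

#' @export
print.ecg_pattern <- function(x, ...) {
  cat(sprintf(
    "<ecg_pattern> subject %s, session %s\n  12 leads x %d samples (1 ms grid), fiducial at %d ms\n  QT %.0f ms, RR %.0f ms, QTc %.0f ms\n",
    x$subject_id, x$session, ncol(x$samples), x$fiducial_index,
    x$qt_ms, x$rr_ms, bazett_qtc(x$qt_ms, x$rr_ms)))
  invisible(x)
}

#' Extract one lead of a pattern
#'
#' @param p an [ecg_pattern()].
#' @param lead lead name, one of I, II, III, aVR, aVL, aVF, V1...V6.
#' @return Numeric vector of 500 samples (microvolts).
#' @export
pattern_lead <- function(p, lead) {
  stopifnot(inherits(p, "ecg_pattern"))
  lead <- match.arg(lead, LEADS)
  p$samples[lead, ]
}

#' Convert a pattern to a tidy tibble
#'
#' @param x an [ecg_pattern()].
#' @param ... unused.
#' @return A tibble with columns `subject_id`, `session`, `lead`, `time_ms`
#'   and `amplitude_uv`, one row per lead-sample.
#' @method tidy ecg_pattern
#' @export
tidy.ecg_pattern <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    session = x$session,
    lead = rep(LEADS, each = PQRST_LEN),
    time_ms = rep(0:(PQRST_LEN - 1L), times = 12L),
    amplitude_uv = as.vector(t(x$samples))
  )
}
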