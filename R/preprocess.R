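#' Remove DC offset and linear trend from a signal
#'
#' Least-squares detrending: subtracts the best-fitting straight line so the
#' result has zero mean and zero linear slope. Applied to every lead before
#' any template comparison, this removes baseline wander and amplifier
#' offsets without touching beat morphology.
#'
#' @param x numeric vector of at least 2 samples.
#' @return Numeric vector of the same length with zero mean and zero
#'   least-squares slope.
#' @export
#' @examples
#' detrend_signal(3 * seq_len(10) + 7)  # a pure ramp vanishes
detrend_signal <- function(x) {
  n <- length(x)
  if (n < 2L) abort("detrending needs at least 2 samples.")
  t <- seq_len(n) - (n + 1) / 2            # centred time axis
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Bazett heart-rate corrected QT interval
#'
#' QTc = QT / sqrt(RR) with RR expressed in seconds, the standard Bazett
#' correction. Computed and stored as beat metadata; it does not enter the
#' similarity features.
#'
#' @param qt_ms QT interval in milliseconds (> 0).
#' @param rr_ms RR interval in milliseconds (> 0).
#' @return QTc in milliseconds.
#' @export
#' @examples
#' bazett_qtc(400, 1000)  # 400: RR of 1 s is the identity point
#' bazett_qtc(380, 640)   # 475
bazett_qtc <- function(qt_ms, rr_ms) {
  if (any(qt_ms <= 0) || any(rr_ms <= 0)) {
    abort("`qt_ms` and `rr_ms` must be positive.")
  }
  qt_ms / sqrt(rr_ms / 1000)
}

# Cross-correlation numerator at every lag in [-(N-1), N-1], computed by FFT.
# c(lag) = sum_i a(i) * b(i + lag), out-of-range b samples contributing 0.
ccf_numerator <- function(a, b) {
  rev(convolve(a, b, type = "open"))
}

#' Time-align a pattern to the global aVR reference
#'
#' Finds the single integer lag in \[-500, 500\] that maximizes the
#' normalized cross-correlation between the pattern's aVR lead and the
#' reference trace, then shifts all 12 leads synchronously by that lag
#' (the maximum of the signed correlation is taken, not of its absolute
#' value). Samples shifted in from outside the 500 ms window hold the edge
#' value, avoiding step artifacts in later correlations. The fiducial index
#' moves with the shift.
#'
#' @param p a detrended [ecg_pattern()].
#' @param ref numeric vector of 500 reference aVR samples
#'   (see [read_reference()]).
#' @return The shifted `ecg_pattern`, with attribute `"lag"` giving the
#'   applied lag.
#' @export
align_to_reference <- function(p, ref) {
  stopifnot(inherits(p, "ecg_pattern"), length(ref) == PQRST_LEN)
  avr <- p$samples["aVR", ]
  na <- sqrt(sum(avr^2)); nb <- sqrt(sum(ref^2))
  if (na == 0) {
    abort("flat aVR lead: cannot align.", class = "ecgmatch_degenerate_error")
  }
  if (nb == 0) {
    abort("flat reference pattern.", class = "ecgmatch_degenerate_error")
  }
  r <- c(0, ccf_numerator(avr, ref) / (na * nb), 0)  # lags -500 ... 500
  lags <- -PQRST_LEN:PQRST_LEN
  lag <- lags[which.max(r)]
  out <- p
  out$samples <- t(apply(p$samples, 1L, shift_hold, lag = lag))
  rownames(out$samples) <- LEADS
  out$fiducial_index <- p$fiducial_index + as.integer(lag)
  out <- validate_ecg_pattern(out)
  attr(out, "lag") <- lag
  out
}

# Shift x so content at index i lands at i + lag, holding edge values.
shift_hold <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (abs(lag) >= n) return(rep(if (lag > 0) x[1] else x[n], n))
  if (lag > 0) c(rep(x[1], lag), x[seq_len(n - lag)])
  else c(x[seq.int(1 - lag, n)], rep(x[n], -lag))
}

#' Extract the 100 ms QRS pattern from each lead
#'
#' Cuts the window from 30 ms before to 70 ms after the fiducial point,
#' synchronously in all 12 leads, yielding exactly 100 samples per lead.
#' This short pattern isolates the R and S waves, whose morphology carries
#' most of the subject-specific information.
#'
#' @param p an [ecg_pattern()] with `fiducial_index` in \[30, 430\].
#' @return A 12 x 100 numeric matrix, rows named by lead.
#' @export
extract_qrs <- function(p) {
  stopifnot(inherits(p, "ecg_pattern"))
  fid <- p$fiducial_index
  if (fid < QRS_PRE || fid > PQRST_LEN - QRS_POST) {
    abort(sprintf("QRS window out of bounds: fiducial_index %d not in [%d, %d].",
                  fid, QRS_PRE, PQRST_LEN - QRS_POST))
  }
  # 0-based samples fid-30 ... fid+69  ->  1-based columns fid-29 ... fid+70
  p$samples[, (fid - QRS_PRE + 1L):(fid + QRS_POST), drop = FALSE]
}

#' Standard pre-processing chain for one pattern
#'
#' Detrends every lead and, when a reference trace is supplied, time-aligns
#' the pattern to it by maximal aVR cross-correlation. Run this on each
#' pattern before computing any pairwise features.
#'
#' @param p an [ecg_pattern()].
#' @param ref optional 500-sample reference aVR trace; `NULL` skips alignment.
#' @return The pre-processed `ecg_pattern`.
#' @export
preprocess_pattern <- function(p, ref = NULL) {
  stopifnot(inherits(p, "ecg_pattern"))
  p$samples <- t(apply(p$samples, 1L, detrend_signal))
  rownames(p$samples) <- LEADS
  if (!is.null(ref)) p <- align_to_reference(p, ref)
  p
}

#' Pre-process every pattern of a cohort tibble
#'
#' @param cohort tibble with a `pattern` list-column (see [read_cohort()],
#'   [generate_cohort()]).
#' @param ref optional reference aVR trace passed to [preprocess_pattern()].
#' @return The cohort tibble with patterns pre-processed.
#' @export
prepare_cohort <- function(cohort, ref = NULL) {
  stopifnot(is.data.frame(cohort), "pattern" %in% names(cohort))
  cohort$pattern <- map(cohort$pattern, preprocess_pattern, ref = ref)
  cohort
}
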