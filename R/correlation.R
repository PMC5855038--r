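#' Fixed-norm cross-correlation between two beat patterns
#'
#' The correlation at lag `k` is
#' \deqn{r(k) = \frac{\sum_i a(i)\, b(i+k)}{\sqrt{\sum_i a(i)^2}\sqrt{\sum_i b(i)^2}}}
#' with out-of-range samples of the shifted operand contributing zero. The
#' denominator uses the full-pattern norms and does not change with the lag,
#' so partial overlaps are penalized — a deliberate property of the template
#' comparison: a pattern only matches well when it matches in place.
#'
#' @param a,b numeric vectors of equal length (100 for QRS, 500 for PQRST
#'   patterns), both with non-zero norm.
#' @param lag integer lag(s), each in `[-length(a), length(a)]`.
#' @return Raw correlation value(s) in `[-1, 1]`, one per lag.
#' @export
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 100))
#' cross_correlation(x, x, 0)    # 1
#' cross_correlation(x, -x, 0)   # -1
cross_correlation <- function(a, b, lag) {
  check_correlation_inputs(a, b)
  n <- length(a)
  stopifnot(all(abs(lag) <= n))
  denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  full <- c(0, ccf_numerator(a, b), 0) / denom   # lags -n ... n
  full[lag + n + 1L]
}

check_correlation_inputs <- function(a, b) {
  if (length(a) != length(b)) {
    abort("patterns must have equal length.")
  }
  if (sum(a^2) == 0 || sum(b^2) == 0) {
    abort("flat pattern: correlation undefined.",
          class = "ecgmatch_degenerate_error")
  }
  invisible(TRUE)
}

# Correlation percentages used in the feature matrix: max over all lags and
# the zero-lag value, both on the clamped [0, 100] similarity scale.
#' Maximum and zero-lag correlation on the percentage scale
#'
#' `r_max()` is the maximum of [cross_correlation()] over all integer lags in
#' `[-PD, PD]` (PD = pattern length), times 100. It measures the best
#' achievable waveform match irrespective of residual timing offset.
#' `r_lag0()` is the correlation at lag zero, times 100 — similarity without
#' any re-synchronization, which also captures timing desynchronization
#' between subjects. Negative raw correlations are clamped to 0 so every
#' feature lives on the common \[0, 100\] similarity scale.
#'
#' @inheritParams cross_correlation
#' @return A percentage in \[0, 100\].
#' @export
r_max <- function(a, b) {
  check_correlation_inputs(a, b)
  denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  clamp_pct(100 * max(0, ccf_numerator(a, b) / denom))
}

#' @rdname r_max
#' @export
r_lag0 <- function(a, b) {
  check_correlation_inputs(a, b)
  clamp_pct(100 * sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2))))
}

clamp_pct <- function(x) pmin(100, pmax(0, x))

#' Peak-to-peak QRS amplitude ratio
#'
#' Ratio of the smaller to the larger peak-to-peak (max minus min) amplitude
#' of two raw QRS patterns from the same lead, times 100. Equal identity with
#' stable electrode placement should give values near 100; the feature is
#' symmetric in its arguments.
#'
#' @param qa,qb numeric vectors of 100 raw (unnormalized) QRS samples, in
#'   microvolts.
#' @return A percentage in \[0, 100\]; 0 when exactly one pattern is flat.
#' @export
ratio_qrs <- function(qa, qb) {
  ppa <- diff(range(qa)); ppb <- diff(range(qb))
  if (ppa == 0 && ppb == 0) {
    abort("both QRS patterns are flat.", class = "ecgmatch_degenerate_error")
  }
  100 * min(ppa, ppb) / max(ppa, ppb)
}
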