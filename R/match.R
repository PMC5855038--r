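#' Binary time-amplitude matching of QRS patterns
#'
#' The MATCH-QRS method approximates each normalized 100 ms QRS pattern by a
#' 100 x 80 binary matrix over a joint time-amplitude grid and compares two
#' such matrices cell-wise. The grid has 1 ms time resolution and 0.025
#' amplitude resolution over the normalized scale; tolerances of +/-1 sample
#' in time and +/-0.05 (two grid steps) in amplitude absorb small intra- and
#' inter-subject variations of the depolarization waveform.
#'
#' @param dt_ms time resolution in ms (fixed grid step, default 1).
#' @param da amplitude resolution on the normalized scale (default 0.025).
#' @param n_time,n_amp grid dimensions (default 100 x 80).
#' @param equt_mode how the time-equality measure reduces over amplitude
#'   bins: `"column"` (default) counts a time index as overlapping when any
#'   amplitude bin overlaps; `"cell"` averages the AND mask over all cells.
#' @return A `bin_config` list with the grid (`amp_grid`), tolerances and
#'   mode.
#' @export
bin_config <- function(dt_ms = 1, da = 0.025, n_time = 100L, n_amp = 80L,
                       equt_mode = c("column", "cell")) {
  equt_mode <- match.arg(equt_mode)
  structure(
    list(dt_ms = dt_ms, da = da, n_time = as.integer(n_time),
         n_amp = as.integer(n_amp),
         amp_tol = 2 * da, time_tol = 1L,
         # A(aj) = -1 + (aj - 1) * da, aj = 1 ... n_amp (top point 0.975;
         # amplitude 1 still maps into the last bins via the +/-2da tolerance)
         amp_grid = -1 + (seq_len(n_amp) - 1) * da,
         equt_mode = equt_mode),
    class = "bin_config"
  )
}

# Closed-interval comparisons use a small epsilon so grid-aligned amplitudes
# land on the boundary deterministically despite floating-point rounding.
BIN_EPS <- 1e-9

#' Normalize a pair of QRS patterns to the joint [-1, 1] scale
#'
#' Both patterns are divided by the same scalar: the maximal absolute
#' amplitude observed across the two patterns. This puts every pair, in
#' every lead, on one computational scale regardless of signal amplitude,
#' while preserving their relative amplitudes.
#'
#' @param qa,qb numeric vectors of 100 raw QRS samples from the same lead.
#' @return A list with elements `a` and `b` (the scaled patterns; their
#'   pooled absolute maximum is exactly 1) and `scale` (the divisor, in
#'   microvolts).
#' @export
normalize_pair <- function(qa, qb) {
  s <- max(abs(c(qa, qb)))
  if (s == 0) {
    abort("both QRS patterns are flat: cannot normalize.",
          class = "ecgmatch_degenerate_error")
  }
  list(a = qa / s, b = qb / s, scale = s)
}

#' Binarize a normalized QRS pattern on the time-amplitude grid
#'
#' Cell (ti, aj) of the binary matrix is set when the grid amplitude A(aj)
#' lies within +/-0.05 of the pattern value at time ti, or within the closed
#' amplitude interval spanned by the pattern over the time-tolerance window
#' ti-1, ti, ti+1 (edge samples use their single neighbour). The second
#' clause fills the bins the waveform crosses between consecutive samples on
#' steep slopes; because the window includes the centre sample, every time
#' column is a contiguous band around the waveform, which in turn makes the
#' amplitude-difference measure of two identical patterns exactly zero.
#'
#' @param q numeric vector of 100 samples in `[-1, 1]`
#'   (see [normalize_pair()]).
#' @param cfg a [bin_config()].
#' @return A 100 x 80 logical matrix (time x amplitude).
#' @export
binarize_qrs <- function(q, cfg = bin_config()) {
  stopifnot(length(q) == cfg$n_time)
  if (max(abs(q)) > 1 + BIN_EPS) {
    abort("pattern is not normalized to [-1, 1]; use normalize_pair() first.")
  }
  A <- cfg$amp_grid
  nt <- cfg$n_time; na <- cfg$n_amp
  # amplitude-tolerance clause
  m1 <- abs(outer(q, A, "-")) <= cfg$amp_tol + BIN_EPS
  # time-tolerance clause: interval spanned by q over ti-1, ti, ti+1
  prv <- c(q[2L], q[-nt])    # edge rows use the single existing neighbour
  nxt <- c(q[-1L], q[nt - 1L])
  lo <- pmin(prv, nxt, q); hi <- pmax(prv, nxt, q)
  Am <- matrix(A, nt, na, byrow = TRUE)
  m2 <- Am >= lo - BIN_EPS & Am <= hi + BIN_EPS
  m1 | m2
}

check_masks <- function(bt, br) {
  if (!identical(dim(bt), dim(br))) {
    abort("binary QRS matrices have mismatched shapes.")
  }
  invisible(TRUE)
}

#' Time-scale equality of two binarized QRS patterns (EQUT)
#'
#' The fraction of the 100 time indices at which the element-wise AND of the
#' two binary matrices has at least one set amplitude bin, as a percentage:
#' the time during which the two approximated waveforms overlap. Identical
#' patterns give 100; patterns whose amplitude bands never meet give 0.
#' With `equt_mode = "cell"` in the config the AND mask is instead averaged
#' over all cells (a stricter, non-default reduction).
#'
#' @param bt,br 100 x 80 logical matrices from [binarize_qrs()].
#' @param cfg the [bin_config()] both matrices were built with.
#' @return A percentage in \[0, 100\].
#' @export
equt <- function(bt, br, cfg = bin_config()) {
  check_masks(bt, br)
  both <- bt & br
  if (cfg$equt_mode == "cell") return(100 * mean(both))
  100 * mean(rowSums(both) > 0)
}

#' Amplitude-scale difference and equality (DIFA, EQUA)
#'
#' `difa()` measures the normalized area enclosed between the
#' non-overlapping parts of the two binary approximations. At each time
#' index the integration band runs from the lowest to the highest amplitude
#' bin set in either matrix; within that band, cells where the two matrices
#' do not both agree (the NAND of the masks) are summed, scaled by the grid
#' cell area relative to the full time-amplitude extent (100 ms x the
#' normalized amplitude span of 2). Identical matrices give exactly 0;
#' fully separated full-range patterns reach 100.
#' `equa()` is its complement, `100 - difa()`.
#'
#' @inheritParams equt
#' @return A percentage in \[0, 100\].
#' @export
difa <- function(bt, br, cfg = bin_config()) {
  check_masks(bt, br)
  u <- bt | br
  if (any(rowSums(u) == 0)) {
    abort("empty time column in binary QRS matrix.")
  }
  amin <- max.col(u, ties.method = "first")
  amax <- max.col(u, ties.method = "last")
  env_cells <- amax - amin + 1L
  and_cells <- rowSums(bt & br)       # AND cells always lie inside the band
  nand_in_env <- sum(env_cells - and_cells)
  (cfg$dt_ms / (cfg$dt_ms * cfg$n_time)) * (cfg$da / 2) * nand_in_env * 100
}

#' @rdname difa
#' @export
equa <- function(bt, br, cfg = bin_config()) {
  100 - difa(bt, br, cfg)
}
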