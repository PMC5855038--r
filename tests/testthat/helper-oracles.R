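# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, literal formula transcription) so they
# check the vectorized implementations from a different direction.

# Cross-correlation numerator/denominator, literal double loop.
brute_ccf <- function(a, b, lag) {
  n <- length(a)
  num <- 0
  for (i in seq_len(n)) {
    j <- i + lag
    if (j >= 1 && j <= n) num <- num + a[i] * b[j]
  }
  num / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Cell-by-cell evaluation of the binary time-amplitude transform.
brute_binarize <- function(q, cfg = bin_config()) {
  eps <- 1e-9
  A <- cfg$amp_grid
  nt <- cfg$n_time
  m <- matrix(FALSE, nt, cfg$n_amp)
  for (ti in seq_len(nt)) {
    nb <- q[c(if (ti > 1) ti - 1 else ti + 1, ti,
              if (ti < nt) ti + 1 else ti - 1)]
    for (aj in seq_len(cfg$n_amp)) {
      in_band <- abs(A[aj] - q[ti]) <= cfg$amp_tol + eps
      in_nb <- A[aj] >= min(nb) - eps && A[aj] <= max(nb) + eps
      m[ti, aj] <- in_band || in_nb
    }
  }
  m
}

# Time-equality: AND the masks, count columns with any set cell.
brute_equt <- function(bt, br) {
  hits <- 0
  for (ti in seq_len(nrow(bt))) {
    if (any(bt[ti, ] & br[ti, ])) hits <- hits + 1
  }
  100 * hits / nrow(bt)
}

# Amplitude-difference: NAND summed over the joint set-cell band per column,
# normalized so a full-range fully-non-overlapping pair scores 100.
brute_difa <- function(bt, br, cfg = bin_config()) {
  total <- 0
  for (ti in seq_len(nrow(bt))) {
    u <- which(bt[ti, ] | br[ti, ])
    band <- min(u):max(u)
    total <- total + sum(!(bt[ti, band] & br[ti, band]))
  }
  (cfg$dt_ms / (cfg$dt_ms * cfg$n_time)) * (cfg$da / 2) * total * 100
}

# A smooth beat-like normalized 100-sample QRS (R upstroke + S undershoot).
smooth_qrs <- function(r_amp = 1, s_amp = -0.35, r_width = 7, s_width = 6,
                       normalize = TRUE) {
  t <- 0:99
  q <- r_amp * exp(-0.5 * ((t - 30) / r_width)^2) +
       s_amp * exp(-0.5 * ((t - 52) / s_width)^2)
  if (normalize) q / max(abs(q)) else q
}

# A valid pattern with prescribed samples (defaults to smooth random beats).
make_pattern <- function(samples = NULL, subject_id = "sub", session = "T1",
                         fiducial_index = 250, qt_ms = 400, rr_ms = 900,
                         seed = 1) {
  if (is.null(samples)) {
    m <- withr::with_seed(seed, synth_morphology(
      cohort_config(n_subjects = 2, seed = seed)))[[1]]
    p <- render_session(m, no_noise(), session, seed = seed)
    p$subject_id <- subject_id
    return(p)
  }
  ecg_pattern(samples, subject_id, session, fiducial_index, qt_ms, rr_ms)
}

# A small pre-processed two-session cohort (memoised per (n, seed)).
small_cohort <- local({
  cache <- list()
  function(n = 10, seed = 3, noise = session_noise()) {
    key <- paste(n, seed, digest_noise(noise), sep = "|")
    if (is.null(cache[[key]])) {
      cohort <- generate_cohort(cohort_config(n, seed = seed, noise = noise))
      cache[[key]] <<- prepare_cohort(cohort, synth_reference())
    }
    cache[[key]]
  }
})
digest_noise <- function(noise) paste(unlist(noise), collapse = ",")

cohort_sessions <- function(cohort) ecgmatch:::split_sessions(cohort)
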