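# Batched pairwise feature computation.
#
# Cross-correlations over all lags are circular correlations of zero-padded
# signals, so each pattern-lead's padded spectrum can be computed once per
# cohort; a probe-gallery pair then costs one column-wise inverse FFT per
# pattern length. The per-pair reference implementation (lead_features) and
# this batched path are asserted equal in the test suite.

FFT_P <- stats::nextn(2L * PQRST_LEN - 1L)  # 1024
FFT_Q <- stats::nextn(2L * QRS_LEN - 1L)    # 256

pad_fft <- function(x, m) stats::fft(c(x, numeric(m - length(x))))

# Per-pattern precomputation: spectra (conjugated on the probe side so the
# pair product is Conj(A)*B), norms, raw QRS and peak-to-peak amplitudes.
prep_side <- function(patterns, conjugate) {
  map(patterns, function(p) {
    q <- extract_qrs(p)
    pf <- vapply(seq_len(12L), function(li) pad_fft(p$samples[li, ], FFT_P),
                 complex(FFT_P))
    qf <- vapply(seq_len(12L), function(li) pad_fft(q[li, ], FFT_Q),
                 complex(FFT_Q))
    if (conjugate) { pf <- Conj(pf); qf <- Conj(qf) }
    list(pf = pf, qf = qf,
         p_ss = rowSums(p$samples^2), q_ss = rowSums(q^2),
         q = q, q_pp = apply(q, 1L, function(x) diff(range(x))))
  })
}

# All 7 features for one (probe, gallery) pair from the precomputations.
pair_features_fast <- function(a, b, cfg) {
  vals <- matrix(NA_real_, 7L, 12L)
  ok <- a$p_ss > 0 & b$p_ss > 0 & a$q_pp > 0 & b$q_pp > 0
  if (!any(ok)) return(vals)
  zp <- Re(stats::mvfft(a$pf * b$pf, inverse = TRUE)) / FFT_P
  zq <- Re(stats::mvfft(a$qf * b$qf, inverse = TRUE)) / FFT_Q
  dp <- sqrt(a$p_ss * b$p_ss)
  dq <- sqrt(a$q_ss * b$q_ss)
  for (li in which(ok)) {
    vals[1L, li] <- clamp_pct(100 * max(0, max(zp[, li])) / dp[li])
    vals[2L, li] <- clamp_pct(100 * zp[1L, li] / dp[li])
    vals[3L, li] <- clamp_pct(100 * max(0, max(zq[, li])) / dq[li])
    vals[4L, li] <- clamp_pct(100 * zq[1L, li] / dq[li])
    vals[5L, li] <- 100 * min(a$q_pp[li], b$q_pp[li]) /
                          max(a$q_pp[li], b$q_pp[li])
    s <- max(abs(a$q[li, ]), abs(b$q[li, ]))
    mf <- match_pair_fast(a$q[li, ] / s, b$q[li, ] / s, cfg)
    vals[6L, li] <- mf[["equt"]]
    vals[7L, li] <- 100 - mf[["difa"]]
  }
  vals
}
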