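#' Pairwise feature matrix between two pre-processed patterns
#'
#' Computes the full 7-feature x 12-lead comparison between a tested and a
#' reference pattern. Per lead, the features are: maximum and zero-lag
#' cross-correlation of the 500 ms PQRST pattern and of the 100 ms QRS
#' pattern, the peak-to-peak QRS amplitude ratio, and the time- and
#' amplitude-equality measures of the binary matching transform
#' (applied after pairwise normalization). All values live on the common
#' \[0, 100\] similarity scale. A degenerate (flat) lead in either pattern is
#' flagged unavailable rather than aborting the comparison.
#'
#' @param tested,reference pre-processed [ecg_pattern()] objects
#'   (see [preprocess_pattern()]).
#' @param cfg a [bin_config()] for the matching transform.
#' @return A tibble with columns `feature` (ordered factor over the 7
#'   features), `lead` (ordered factor over the 12 leads), `value` and
#'   `available`; 84 rows.
#' @export
#' @examples
#' m <- synth_morphology(cohort_config(n_subjects = 2, seed = 1))[[1]]
#' p <- render_session(m, session_noise(), session = "T1", seed = 1)
#' pattern_features(p, p)  # self-comparison: every available value is 100
pattern_features <- function(tested, reference, cfg = bin_config()) {
  stopifnot(inherits(tested, "ecg_pattern"), inherits(reference, "ecg_pattern"))
  qt <- extract_qrs(tested); qr <- extract_qrs(reference)
  vals <- matrix(NA_real_, 7L, 12L, dimnames = list(FEATURES, LEADS))
  for (li in seq_along(LEADS)) {
    vals[, li] <- lead_features(
      tested$samples[li, ], reference$samples[li, ], qt[li, ], qr[li, ], cfg)
  }
  feature_matrix_tibble(vals)
}

# One lead's 7 features; NA for degenerate leads.
lead_features <- function(pa, pb, qa, qb, cfg) {
  out <- rep(NA_real_, 7L)
  flat_p <- sum(pa^2) == 0 || sum(pb^2) == 0
  flat_q <- diff(range(qa)) == 0 || diff(range(qb)) == 0
  if (flat_p || flat_q) return(out)
  da <- sqrt(sum(pa^2)) * sqrt(sum(pb^2))
  out[1] <- clamp_pct(100 * max(0, ccf_numerator(pa, pb) / da))
  out[2] <- clamp_pct(100 * sum(pa * pb) / da)
  dq <- sqrt(sum(qa^2)) * sqrt(sum(qb^2))
  out[3] <- clamp_pct(100 * max(0, ccf_numerator(qa, qb) / dq))
  out[4] <- clamp_pct(100 * sum(qa * qb) / dq)
  out[5] <- ratio_qrs(qa, qb)
  nrm <- normalize_pair(qa, qb)
  if (cfg$equt_mode == "column") {
    mf <- match_pair_fast(nrm$a, nrm$b, cfg)
    out[6] <- mf[["equt"]]
    out[7] <- 100 - mf[["difa"]]
  } else {
    bt <- binarize_qrs(nrm$a, cfg); br <- binarize_qrs(nrm$b, cfg)
    out[6] <- equt(bt, br, cfg)
    out[7] <- equa(bt, br, cfg)
  }
  out
}

feature_matrix_tibble <- function(vals) {
  tibble(
    feature = factor(rep(FEATURES, times = 12L), levels = FEATURES),
    lead = factor(rep(LEADS, each = 7L), levels = LEADS),
    value = as.vector(vals),
    available = !is.na(as.vector(vals))
  )
}

# Convert the tidy feature tibble back to the 7 x 12 value matrix.
feature_matrix_values <- function(fm) {
  vals <- matrix(NA_real_, 7L, 12L, dimnames = list(FEATURES, LEADS))
  vals[cbind(as.integer(fm$feature), as.integer(fm$lead))] <- fm$value
  vals
}

#' All pairwise feature matrices between probe and gallery patterns
#'
#' Computes the 7 x 12 feature matrix for every (probe, gallery) pattern
#' pair and returns them as a numeric array. This is the workhorse behind
#' model training and the gallery-size evaluation: computed once per cohort,
#' the array lets any feature/lead sub-model be scored without touching the
#' signals again.
#'
#' @param probes,gallery lists of pre-processed [ecg_pattern()] objects.
#' @param cfg a [bin_config()].
#' @param progress unused placeholder for future progress reporting.
#' @return A numeric array of dimension
#'   `c(length(probes), length(gallery), 7, 12)` with dimnames on the
#'   feature and lead axes; `NA` marks unavailable entries.
#' @export
pairwise_features <- function(probes, gallery, cfg = bin_config(),
                              progress = FALSE) {
  np <- length(probes); ng <- length(gallery)
  stopifnot(np > 0, ng > 0)
  arr <- array(NA_real_, c(np, ng, 7L, 12L),
               dimnames = list(NULL, NULL, FEATURES, LEADS))
  if (cfg$equt_mode == "column") {
    pa <- prep_side(probes, conjugate = TRUE)
    pb <- prep_side(gallery, conjugate = FALSE)
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        arr[i, j, , ] <- pair_features_fast(pa[[i]], pb[[j]], cfg)
      }
    }
    return(arr)
  }
  qp <- map(probes, extract_qrs)
  qg <- map(gallery, extract_qrs)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      for (li in seq_len(12L)) {
        arr[i, j, , li] <- lead_features(
          probes[[i]]$samples[li, ], gallery[[j]]$samples[li, ],
          qp[[i]][li, ], qg[[j]][li, ], cfg)
      }
    }
  }
  arr
}

#' Equal- and different-identity pair counts
#'
#' For a cohort of `n` subjects with one probe (T2) and one reference (T1)
#' recording each, the matching stage compares every probe to every
#' reference: `n` equal-identity pairs and `n * (n - 1)` ordered
#' different-identity pairs (52,670 for n = 230).
#'
#' @param n_subjects number of subjects.
#' @return A one-row tibble with columns `n_subjects`, `equal_pairs`,
#'   `different_pairs`.
#' @export
pair_counts <- function(n_subjects) {
  n <- as.integer(n_subjects)
  stopifnot(n >= 1)
  tibble(n_subjects = n, equal_pairs = n, different_pairs = n * (n - 1L))
}

#' Feature distributions for equal vs. different identity pairs
#'
#' Summarises, per feature, the 12-lead-averaged feature values over all
#' equal-identity pairs (each subject's T2 against their own T1) and all
#' ordered different-identity pairs, with a one-sided Welch t-test of the
#' hypothesis that equal-identity similarity exceeds different-identity
#' similarity. This is the statistical screen run before any model is
#' trained: features whose distributions do not separate carry no biometric
#' information.
#'
#' @param cohort a two-session cohort tibble (see [generate_cohort()],
#'   [read_cohort()]), pre-processed with [prepare_cohort()].
#' @param cfg a [bin_config()].
#' @param features optional precomputed [pairwise_features()] array for the
#'   cohort (probes = T2 in subject order, gallery = T1 in subject order).
#' @return A tibble with one row per feature: means and standard deviations
#'   for the equal and different groups and the one-sided `p_value`.
#' @export
feature_statistics <- function(cohort, cfg = bin_config(), features = NULL) {
  sessions <- split_sessions(cohort)
  if (is.null(features)) {
    features <- pairwise_features(sessions$t2, sessions$t1, cfg)
  }
  n <- length(sessions$t1)
  eq <- diag_mask(n)
  purrr::map_dfr(seq_along(FEATURES), function(fi) {
    perlead <- features[, , fi, , drop = FALSE]
    # average over the 12 leads for each pair, as reported per feature
    pairmean <- apply(perlead, c(1, 2), mean, na.rm = TRUE)
    same <- pairmean[eq]; other <- pairmean[!eq]
    tt <- t.test(same, other, alternative = "greater")
    tibble(feature = FEATURES[fi],
           mean_equal = mean(same), sd_equal = sd(same),
           mean_different = mean(other), sd_different = sd(other),
           p_value = tt$p.value)
  })
}

diag_mask <- function(n) diag(n) == 1

# Split a cohort tibble into subject-ordered T1 and T2 pattern lists.
split_sessions <- function(cohort) {
  stopifnot(all(c("subject_id", "session", "pattern") %in% names(cohort)))
  t1 <- cohort |> filter(.data$session == "T1") |> arrange(.data$subject_id)
  t2 <- cohort |> filter(.data$session == "T2") |> arrange(.data$subject_id)
  if (!identical(t1$subject_id, t2$subject_id)) {
    abort("cohort must hold exactly one T1 and one T2 recording per subject.")
  }
  list(ids = t1$subject_id, t1 = t1$pattern, t2 = t2$pattern)
}
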