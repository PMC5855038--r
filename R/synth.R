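#' Session-to-session noise configuration
#'
#' Controls how a subject's two recording sessions differ. Amplitude effects
#' are multiplicative log-normal scales: one global scale per session,
#' independent per-lead scales for the limb potentials (I and II; the
#' augmented and derived limb leads follow exactly, preserving the
#' Einthoven/Goldberger relations) and larger independent per-lead scales
#' for the chest leads, emulating the morphology changes that small
#' electrode misplacements cause in V1-V6 across sessions. Wave timing and
#' width jitter plus additive noise model residual beat-averaging
#' variability.
#'
#' @param global_scale_sd sd of the log of the whole-session amplitude
#'   scale.
#' @param limb_scale_sd sd of the log per-lead scale applied to the two
#'   frontal potentials.
#' @param chest_scale_sd sd of the log per-lead scale of each chest lead
#'   (larger: electrode misplacement).
#' @param center_jitter_ms sd (ms) of per-wave centre jitter.
#' @param width_jitter sd (fraction) of per-wave width jitter.
#' @param additive_uv sd (microvolts) of additive white noise per sample.
#' @return A `session_noise` list.
#' @export
session_noise <- function(global_scale_sd = 0.06,
                          limb_scale_sd = 0.05,
                          chest_scale_sd = 0.22,
                          center_jitter_ms = 1.5,
                          width_jitter = 0.05,
                          additive_uv = 5) {
  cfg <- list(global_scale_sd = global_scale_sd,
              limb_scale_sd = limb_scale_sd,
              chest_scale_sd = chest_scale_sd,
              center_jitter_ms = center_jitter_ms,
              width_jitter = width_jitter,
              additive_uv = additive_uv)
  if (any(unlist(cfg) < 0)) abort("noise sds must be non-negative.")
  structure(cfg, class = "session_noise")
}

#' Zero session noise (identical repeat recordings)
#' @rdname session_noise
#' @export
no_noise <- function() {
  session_noise(0, 0, 0, 0, 0, 0)
}

#' Population prior for subject beat morphology
#'
#' Each entry is a `c(lo, hi)` uniform range; a zero-width range pins the
#' parameter at its midpoint. Waves are Gaussian bumps; limb-lead
#' projections come from a per-wave frontal dipole (magnitude in microvolts,
#' axis in degrees), chest leads from per-wave V1-V6 projection weights
#' (a canonical progression scaled per subject). The ranges are deliberately
#' narrow — all human beats look alike — so that different-identity
#' similarity is high and identification is non-trivial.
#'
#' @param ... named `c(lo, hi)` overrides of the default ranges.
#' @return A named list of ranges.
#' @export
morphology_prior <- function(...) {
  prior <- list(
    p_center = c(50, 70),   p_width = c(15, 22),
    p_mag = c(70, 150),     p_theta = c(40, 75),
    q_offset = c(-28, -20), q_width = c(3, 5.5),  q_mag = c(-180, -60),
    q_theta_off = c(-15, 15),
    r_center = c(220, 220), r_width = c(5.5, 9),  r_mag = c(800, 1500),
    r_theta = c(10, 70),
    s_offset = c(18, 28),   s_width = c(4.5, 7.5), s_mag = c(-400, -150),
    s_theta_off = c(-10, 25),
    t_offset = c(180, 225), t_width = c(35, 50),  t_mag = c(200, 450),
    t_theta = c(15, 55),
    chest_factor = c(0.7, 1.4),   # per-wave overall chest gain
    chest_jitter = c(-0.3, 0.3),  # per-wave, per-lead weight jitter
    rr_ms = c(660, 1100)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(prior))
  if (length(bad)) abort(sprintf("unknown prior field(s): %s",
                                 paste(bad, collapse = ", ")))
  modifyList(prior, over)
}

# Canonical chest-lead (V1-V6) projection weights per wave, microvolts.
CHEST_BASE <- rbind(
  P = c(50, 60, 65, 70, 65, 55),
  Q = c(-20, -35, -60, -80, -90, -70),
  R = c(420, 700, 950, 1250, 1100, 850),
  S = c(-380, -520, -420, -280, -180, -110),
  T = c(120, 220, 300, 340, 300, 240)
)
WAVES <- c("P", "Q", "R", "S", "T")

#' Cohort generation configuration
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed master seed; every random draw of the cohort flows from it.
#' @param prior a [morphology_prior()].
#' @param noise a [session_noise()] applied independently to both sessions.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 50L, seed = 1L,
                          prior = morphology_prior(),
                          noise = session_noise()) {
  stopifnot(n_subjects >= 2)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 prior = prior, noise = noise),
            class = "cohort_config")
}

runif_range <- function(rng) runif(1, rng[1], rng[2])

#' Draw subject morphologies from the population prior
#'
#' Deterministic under the config seed: the same config always yields the
#' same subjects. Wave centres are ordered P < Q < R < S < T by
#' construction of the prior ranges, and the R magnitude dominates Q and S.
#'
#' @param cfg a [cohort_config()].
#' @return A named list (one element per subject id `S001`, `S002`, ...) of
#'   `subject_morphology` objects.
#' @export
synth_morphology <- function(cfg) {
  withr::with_seed(cfg$seed, {
    out <- map(seq_len(cfg$n_subjects), function(i) sample_subject(cfg$prior))
    names(out) <- sprintf("S%03d", seq_len(cfg$n_subjects))
    for (i in seq_along(out)) out[[i]]$subject_id <- names(out)[i]
    out
  })
}

# One subject's morphology from the prior (uses the current RNG stream).
sample_subject <- function(prior) {
  g <- function(nm) runif_range(prior[[nm]])
  r_theta <- g("r_theta")
  centers <- c(P = g("p_center"),
               Q = NA, R = g("r_center"), S = NA,
               T = NA)
  centers["Q"] <- centers["R"] + g("q_offset")
  centers["S"] <- centers["R"] + g("s_offset")
  centers["T"] <- centers["R"] + g("t_offset")
  widths <- c(P = g("p_width"), Q = g("q_width"), R = g("r_width"),
              S = g("s_width"), T = g("t_width"))
  mags <- c(P = g("p_mag"), Q = g("q_mag"), R = g("r_mag"),
            S = g("s_mag"), T = g("t_mag"))
  thetas <- c(P = g("p_theta"), Q = r_theta + g("q_theta_off"), R = r_theta,
              S = r_theta + g("s_theta_off"), T = g("t_theta"))
  chest <- matrix(NA_real_, 5L, 6L, dimnames = list(WAVES, CHEST_LEADS))
  for (w in WAVES) {
    fac <- runif_range(prior$chest_factor)
    jit <- vapply(1:6, function(j) runif_range(prior$chest_jitter), numeric(1))
    chest[w, ] <- CHEST_BASE[w, ] * fac * (1 + jit)
  }
  structure(
    list(subject_id = NA_character_, centers = centers, widths = widths,
         frontal_mag = mags, frontal_theta = thetas, chest = chest,
         rr_ms = g("rr_ms")),
    class = "subject_morphology"
  )
}

gauss_bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

#' Render one recording session of a subject
#'
#' Builds the 12-lead 500 ms beat pattern on the 1 ms grid from the
#' subject's wave morphology: each wave is a Gaussian bump; leads I and II
#' are frontal-dipole projections (lead axes at 0 and 60 degrees), the
#' remaining limb leads follow the exact Einthoven/Goldberger relations
#' (III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2), and
#' chest leads use the subject's V1-V6 projection weights. Session noise is
#' then applied per [session_noise()]. The fiducial index is the (jittered)
#' R-wave centre; QT and RR metadata are filled from the wave layout.
#'
#' @param m a `subject_morphology` (see [synth_morphology()]).
#' @param noise a [session_noise()].
#' @param session `"T1"` or `"T2"`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return An [ecg_pattern()].
#' @export
render_session <- function(m, noise = session_noise(), session = "T1",
                           seed = NULL) {
  render <- function() {
    t <- 0:(PQRST_LEN - 1L)
    centers <- m$centers + rnorm(5, 0, noise$center_jitter_ms)
    widths <- m$widths * (1 + rnorm(5, 0, noise$width_jitter))
    widths <- pmax(widths, 0.5)
    g_scale <- exp(rnorm(1, 0, noise$global_scale_sd))
    # frontal potentials for leads I (0 deg) and II (60 deg)
    waves <- vapply(seq_along(WAVES), function(w) {
      gauss_bump(t, centers[w], widths[w], 1)
    }, numeric(PQRST_LEN))             # 500 x 5 unit bumps
    amp_I  <- m$frontal_mag * cos(m$frontal_theta * pi / 180)
    amp_II <- m$frontal_mag * cos((m$frontal_theta - 60) * pi / 180)
    lead_I  <- waves %*% amp_I  * exp(rnorm(1, 0, noise$limb_scale_sd))
    lead_II <- waves %*% amp_II * exp(rnorm(1, 0, noise$limb_scale_sd))
    samples <- matrix(0, 12L, PQRST_LEN, dimnames = list(LEADS, NULL))
    samples["I", ] <- lead_I
    samples["II", ] <- lead_II
    samples["III", ] <- lead_II - lead_I
    samples["aVR", ] <- -(lead_I + lead_II) / 2
    samples["aVL", ] <- lead_I - lead_II / 2
    samples["aVF", ] <- lead_II - lead_I / 2
    for (v in seq_len(6L)) {
      lead_scale <- exp(rnorm(1, 0, noise$chest_scale_sd))
      samples[CHEST_LEADS[v], ] <- (waves %*% m$chest[, v]) * lead_scale
    }
    samples <- samples * g_scale
    if (noise$additive_uv > 0) {
      samples <- samples + matrix(rnorm(length(samples), 0, noise$additive_uv),
                                  nrow(samples))
    }
    if (any(!is.finite(samples))) abort("noise produced non-finite samples.")
    fid <- as.integer(round(centers[which(WAVES == "R")]))
    qt <- (centers[which(WAVES == "T")] + 2 * widths[which(WAVES == "T")]) -
          (centers[which(WAVES == "Q")] - 2 * widths[which(WAVES == "Q")])
    rr <- m$rr_ms * (1 + rnorm(1, 0, 0.3 * noise$width_jitter))
    ecg_pattern(samples, m$subject_id %||% "synthetic", session,
                fiducial_index = fid, qt_ms = qt, rr_ms = max(rr, 1))
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Generate a seeded two-session synthetic cohort
#'
#' Draws `n_subjects` morphologies from the population prior and renders
#' independent T1 (enrolment) and T2 (matching) sessions for each, with the
#' configured session noise standing in for more-than-a-year
#' between-session drift. Fully reproducible from the config seed. When
#' `dir` is given, pattern files and a `manifest.csv` are also written in
#' the package's pattern-file dialect.
#'
#' @param cfg a [cohort_config()].
#' @param dir optional output directory for pattern files and manifest.
#' @return A cohort tibble with columns `subject_id`, `session`, `pattern`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 7))
#' dplyr::count(cohort, session)
generate_cohort <- function(cfg, dir = NULL) {
  morphs <- synth_morphology(cfg)
  rows <- withr::with_seed(cfg$seed + 1L, {
    purrr::map_dfr(morphs, function(m) {
      tibble(
        subject_id = m$subject_id,
        session = c("T1", "T2"),
        pattern = list(render_session(m, cfg$noise, "T1"),
                       render_session(m, cfg$noise, "T2"))
      )
    })
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- sprintf("%s_%s.csv", rows$subject_id, rows$session)
    purrr::walk2(rows$pattern, files,
                 ~ write_pattern(.x, file.path(dir, .y)))
    readr::write_csv(
      tibble(subject_id = rows$subject_id, session = rows$session,
             file = files),
      file.path(dir, "manifest.csv"), progress = FALSE)
  }
  rows
}

#' Canonical noiseless reference aVR trace
#'
#' Renders a mid-prior ("textbook") subject without noise and returns its
#' detrended aVR lead, for use as the global alignment reference. In a real
#' deployment this is one healthy subject's enrolment aVR, chosen once per
#' study; here it is generated so the whole pipeline is self-contained.
#'
#' @param prior a [morphology_prior()]; the midpoint of every range is used.
#' @return Numeric vector of 500 samples.
#' @export
synth_reference <- function(prior = morphology_prior()) {
  mid <- purrr::map(prior, ~ rep(mean(.x), 2))
  cfg <- cohort_config(n_subjects = 2, seed = 0L,
                       prior = do.call(morphology_prior, mid),
                       noise = no_noise())
  m <- synth_morphology(cfg)[[1]]
  p <- render_session(m, no_noise(), "T1")
  detrend_signal(p$samples["aVR", ])
}
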