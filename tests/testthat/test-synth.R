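test_that("morphology sampling is seeded and respects the prior structure", {
  cfg <- cohort_config(n_subjects = 5, seed = 9)
  m1 <- synth_morphology(cfg)
  m2 <- synth_morphology(cfg)
  expect_identical(m1, m2)

  big <- synth_morphology(cohort_config(n_subjects = 300, seed = 10))
  for (m in big) {
    cc <- m$centers
    expect_true(cc["P"] < cc["Q"] && cc["Q"] < cc["R"] &&
                cc["R"] < cc["S"] && cc["S"] < cc["T"])
    expect_true(all(m$widths > 0))
    expect_gt(abs(m$frontal_mag["R"]), abs(m$frontal_mag["Q"]))
    expect_gt(abs(m$frontal_mag["R"]), abs(m$frontal_mag["S"]))
  }
})

test_that("a zero-width prior pins every parameter at the range midpoint", {
  prior <- morphology_prior()
  degenerate <- purrr::map(prior, ~ rep(mean(.x), 2))
  cfg <- cohort_config(n_subjects = 2, seed = 1,
                       prior = do.call(morphology_prior, degenerate))
  ms <- synth_morphology(cfg)
  expect_identical(ms[[1]]$centers, ms[[2]]$centers)
  expect_equal(unname(ms[[1]]$centers["R"]), mean(prior$r_center))
  expect_equal(unname(ms[[1]]$widths["T"]), mean(prior$t_width))
  expect_equal(unname(ms[[1]]$rr_ms), mean(prior$rr_ms))
  expect_error(morphology_prior(not_a_field = c(0, 1)), "unknown")
})

test_that("limb leads satisfy the Einthoven/Goldberger identities", {
  m <- synth_morphology(cohort_config(n_subjects = 2, seed = 12))[[1]]
  quiet <- session_noise(additive_uv = 0)   # noise scales but no additive
  p <- render_session(m, quiet, "T1", seed = 4)
  s <- p$samples
  expect_equal(s["III", ], s["II", ] - s["I", ], tolerance = 1e-9)
  expect_equal(s["aVR", ], -(s["I", ] + s["II", ]) / 2, tolerance = 1e-9)
  expect_equal(s["aVL", ], s["I", ] - s["II", ] / 2, tolerance = 1e-9)
  expect_equal(s["aVF", ], s["II", ] - s["I", ] / 2, tolerance = 1e-9)

  # with additive noise the relations hold within a few noise sds
  noisy <- render_session(m, session_noise(), "T1", seed = 4)
  resid <- noisy$samples["III", ] - (noisy$samples["II", ] -
                                     noisy$samples["I", ])
  expect_lt(max(abs(resid)), 6 * sqrt(3) * session_noise()$additive_uv)
})

test_that("noiseless re-rendering is identical and self-similar", {
  m <- synth_morphology(cohort_config(n_subjects = 2, seed = 13))[[1]]
  p1 <- render_session(m, no_noise(), "T1", seed = 1)
  p2 <- render_session(m, no_noise(), "T2", seed = 99)
  expect_equal(p1$samples, p2$samples)   # no noise: seed is irrelevant
  fm <- pattern_features(preprocess_pattern(p1), preprocess_pattern(p2))
  expect_equal(fm$value[fm$available], rep(100, sum(fm$available)),
               tolerance = 1e-9)
})

test_that("cohort generation is reproducible down to the written bytes", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_cohort(cohort_config(n_subjects = 3, seed = 14), dir = d1)
  generate_cohort(cohort_config(n_subjects = 3, seed = 14), dir = d2)
  files <- list.files(d1)
  expect_length(files, 3 * 2 * 2 + 1)    # csv + sidecar per session + manifest
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("chest-lead misplacement noise hurts chest models but not limb models", {
  accs <- function(chest_sd, seed) {
    noise <- session_noise(chest_scale_sd = chest_sd)
    cohort <- small_cohort(n = 16, seed = seed, noise = noise)
    s <- cohort_sessions(cohort)
    feats <- pairwise_features(s$t2, s$t1)
    c(chest = ecgmatch:::accid_from_array(feats, id_model(lead_mask("chest"))),
      limb = ecgmatch:::accid_from_array(feats, id_model(lead_mask("limb"))))
  }
  base <- accs(0.10, seed = 81)
  worse <- accs(0.60, seed = 81)
  expect_lt(worse[["chest"]], base[["chest"]])
  expect_lt(abs(worse[["limb"]] - base[["limb"]]), 2 + 1e-9)
})

test_that("rendered patterns carry consistent timing metadata", {
  cohort <- small_cohort(n = 4, seed = 15)
  for (p in cohort$pattern) {
    expect_gte(p$fiducial_index, 30)
    expect_lte(p$fiducial_index, 430)
    expect_gt(p$qt_ms, 0)
    expect_gt(p$rr_ms, 0)
    expect_equal(bazett_qtc(p$qt_ms, p$rr_ms),
                 p$qt_ms / sqrt(p$rr_ms / 1000))
  }
})
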