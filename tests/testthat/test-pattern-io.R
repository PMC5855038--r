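test_that("pattern construction enforces the 12 x 500 contract", {
  s <- matrix(rnorm(12 * 500), 12, 500)
  p <- ecg_pattern(s, "s1", "T1", 250, 400, 900)
  expect_s3_class(p, "ecg_pattern")
  expect_identical(rownames(p$samples), ecgmatch:::LEADS)

  expect_error(ecg_pattern(s[1:11, ], "s1", "T1", 250, 400, 900),
               class = "ecgmatch_format_error")
  expect_error(ecg_pattern(s[, 1:499], "s1", "T1", 250, 400, 900),
               class = "ecgmatch_format_error")
  s_nan <- s; s_nan[3, 7] <- NaN
  expect_error(ecg_pattern(s_nan, "s1", "T1", 250, 400, 900),
               class = "ecgmatch_format_error")
  expect_error(ecg_pattern(s, "s1", "T3", 250, 400, 900),
               class = "ecgmatch_format_error")
  for (fid in c(29, 431)) {
    expect_error(ecg_pattern(s, "s1", "T1", fid, 400, 900),
                 class = "ecgmatch_format_error")
  }
  expect_error(ecg_pattern(s, "s1", "T1", 250, -1, 900),
               class = "ecgmatch_format_error")
})

test_that("pattern files round-trip within formatting precision", {
  p <- make_pattern(seed = 11)
  path <- file.path(withr::local_tempdir(), "p.csv")
  write_pattern(p, path)
  q <- read_pattern(path)
  expect_lt(max(abs(q$samples - p$samples)), 1e-3)
  expect_identical(q$subject_id, p$subject_id)
  expect_identical(q$session, p$session)
  expect_identical(q$fiducial_index, p$fiducial_index)
  expect_equal(q$qt_ms, p$qt_ms)

  # a zero-valued pattern writes a valid all-zero body
  z <- p; z$samples[] <- 0
  zpath <- file.path(withr::local_tempdir(), "z.csv")
  write_pattern(z, zpath)
  expect_true(all(read_pattern(zpath)$samples == 0))
})

test_that("malformed pattern files are rejected with format errors", {
  dir <- withr::local_tempdir()
  p <- make_pattern(seed = 12)
  good <- file.path(dir, "good.csv")
  write_pattern(p, good)

  # drop a lead column
  df <- readr::read_csv(good, show_col_types = FALSE)
  readr::write_csv(df[, -13], file.path(dir, "eleven.csv"))
  file.copy(ecgmatch:::meta_sidecar(good),
            file.path(dir, "eleven.meta.json"))
  expect_error(read_pattern(file.path(dir, "eleven.csv")),
               class = "ecgmatch_format_error")

  # truncate to 499 rows
  readr::write_csv(df[-500, ], file.path(dir, "short.csv"))
  file.copy(ecgmatch:::meta_sidecar(good), file.path(dir, "short.meta.json"))
  expect_error(read_pattern(file.path(dir, "short.csv")),
               class = "ecgmatch_format_error")

  # non-numeric cell
  bad <- df; bad$V3 <- as.character(bad$V3); bad$V3[17] <- "oops"
  readr::write_csv(bad, file.path(dir, "text.csv"))
  file.copy(ecgmatch:::meta_sidecar(good), file.path(dir, "text.meta.json"))
  expect_error(read_pattern(file.path(dir, "text.csv")),
               regexp = "V3", class = "ecgmatch_format_error")

  # missing sidecar
  file.remove(ecgmatch:::meta_sidecar(good))
  expect_error(read_pattern(good), class = "ecgmatch_format_error")
  expect_error(read_pattern(file.path(dir, "absent.csv")),
               class = "ecgmatch_format_error")
})

test_that("reference pattern I/O validates length and non-constancy", {
  dir <- withr::local_tempdir()
  ref <- synth_reference()
  path <- file.path(dir, "ref.csv")
  write_reference(ref, path)
  expect_equal(read_reference(path), ref, tolerance = 1e-9)

  readr::write_csv(tibble::tibble(aVR = rep(1, 500)),
                   file.path(dir, "flat.csv"))
  expect_error(read_reference(file.path(dir, "flat.csv")),
               class = "ecgmatch_degenerate_error")
  readr::write_csv(tibble::tibble(aVR = rnorm(400)),
                   file.path(dir, "short.csv"))
  expect_error(read_reference(file.path(dir, "short.csv")),
               class = "ecgmatch_format_error")
})

test_that("tidy() flattens a pattern to lead-sample rows", {
  p <- make_pattern(seed = 13)
  td <- tidy(p)
  expect_equal(nrow(td), 12 * 500)
  expect_equal(td$amplitude_uv[td$lead == "aVF"],
               unname(p$samples["aVF", ]))
  expect_equal(range(td$time_ms), c(0, 499))
})

test_that("cohort directories round-trip through manifest I/O", {
  dir <- file.path(withr::local_tempdir(), "cohort")
  cohort <- generate_cohort(cohort_config(n_subjects = 3, seed = 5),
                            dir = dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back), 6)
  expect_setequal(back$session, c("T1", "T2"))
  i <- which(back$subject_id == "S002" & back$session == "T2")
  j <- which(cohort$subject_id == "S002" & cohort$session == "T2")
  expect_lt(max(abs(back$pattern[[i]]$samples - cohort$pattern[[j]]$samples)),
            1e-3)
  expect_error(read_cohort(withr::local_tempdir()),
               class = "ecgmatch_format_error")
})
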