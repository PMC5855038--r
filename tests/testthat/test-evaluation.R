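test_that("confidence half-widths follow the closed-form expressions", {
  expect_equal(confidence_interval(rep(80, 10)), 0)
  expect_equal(confidence_interval(c(70, 90)),
               qnorm(0.975) * sd(c(70, 90)) / sqrt(2))
  expect_equal(confidence_interval(c(70, 90), level = 0.9),
               qnorm(0.95) * sd(c(70, 90)) / sqrt(2))
  expect_equal(confidence_interval(50), 0)
  expect_error(confidence_interval(numeric(0)))
})

test_that("a noise-free cohort is identified perfectly at every gallery size", {
  cohort <- small_cohort(n = 8, seed = 71, noise = no_noise())
  curve <- evaluate_size_sweep(cohort, id_model(), sizes = c(3, 5, 8),
                               n_resamples = 30, seed = 7)
  expect_equal(curve$mean_accid, rep(100, 3))
  expect_s3_class(curve, "accid_curve")
})

test_that("the full-cohort size evaluates the single exhaustive subset", {
  cohort <- small_cohort(n = 8, seed = 72)
  s <- cohort_sessions(cohort)
  feats <- pairwise_features(s$t2, s$t1)
  curve <- evaluate_size_sweep(cohort, id_model(), sizes = 8,
                               n_resamples = 50, seed = 7, features = feats)
  expect_identical(curve$n_subsets, 1L)
  expect_true(curve$exhaustive)
  expect_equal(curve$mean_accid,
               ecgmatch:::accid_from_array(feats, id_model()))
  # Wilson binomial half-width reported for the single subset
  k <- round(curve$mean_accid / 100 * 8)
  expect_equal(curve$ci_halfwidth, ecgmatch:::wilson_halfwidth(k, 8))

  expect_error(evaluate_size_sweep(cohort, id_model(), sizes = 9),
               "exceeds")
  expect_error(evaluate_size_sweep(cohort, id_model(), sizes = 4,
                                   n_resamples = 0))
})

test_that("subset draws are unique, seeded and reproducible", {
  s1 <- withr::with_seed(5, ecgmatch:::draw_subsets(30, 5, 40))
  s2 <- withr::with_seed(5, ecgmatch:::draw_subsets(30, 5, 40))
  expect_identical(s1, s2)
  keys <- vapply(s1, paste, "", collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  expect_false(attr(s1, "exhaustive"))

  all4 <- withr::with_seed(5, ecgmatch:::draw_subsets(6, 4, 40))
  expect_length(all4, choose(6, 4))
  expect_true(attr(all4, "exhaustive"))

  cohort <- small_cohort(n = 8, seed = 72)
  c1 <- evaluate_size_sweep(cohort, id_model(), sizes = c(4, 6),
                            n_resamples = 20, seed = 11)
  c2 <- evaluate_size_sweep(cohort, id_model(), sizes = c(4, 6),
                            n_resamples = 20, seed = 11)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("Monte-Carlo subset means agree with exhaustive enumeration", {
  cohort <- small_cohort(n = 10, seed = 73)
  s <- cohort_sessions(cohort)
  feats <- pairwise_features(s$t2, s$t1)
  model <- id_model(lead_mask("II"))   # weaker model so errors occur
  enum <- evaluate_size_sweep(cohort, model, sizes = 5,
                              n_resamples = choose(10, 5), seed = 1,
                              features = feats)
  expect_true(enum$exhaustive)
  mc <- evaluate_size_sweep(cohort, model, sizes = 5,
                            n_resamples = 200, seed = 2, features = feats)
  expect_false(mc$exhaustive)
  expect_lt(abs(mc$mean_accid - enum$mean_accid), 3)
})

test_that("curve reporting writes the CSV and plot artifacts", {
  cohort <- small_cohort(n = 6, seed = 74)
  curve <- evaluate_size_sweep(cohort, id_model(), sizes = c(3, 6),
                               n_resamples = 10, seed = 3)
  stem <- file.path(withr::local_tempdir(), "curve")
  paths <- report_curve(curve, stem)
  expect_true(all(file.exists(paths)))
  expect_gt(file.size(paste0(stem, ".pdf")), 0)
  back <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_equal(back$mean_accid, curve$mean_accid)
  p <- autoplot(curve)
  expect_s3_class(p, "ggplot")
})
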