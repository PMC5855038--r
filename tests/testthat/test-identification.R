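test_that("the similarity index averages enabled, available entries", {
  vals <- matrix(100, 7, 12, dimnames = list(ecgmatch:::FEATURES,
                                             ecgmatch:::LEADS))
  fm <- ecgmatch:::feature_matrix_tibble(vals)
  expect_equal(similarity_index(fm, id_model()), 100)

  vals[] <- NA_real_
  vals[1, 1] <- 80; vals[2, 1] <- 60
  fm <- ecgmatch:::feature_matrix_tibble(vals)
  expect_equal(similarity_index(fm, id_model()), 70)

  withr::local_seed(61)
  for (rep in 1:10) {
    vals <- matrix(runif(84, 0, 100), 7, 12)
    mask <- matrix(runif(84) < 0.4, 7, 12)
    mask[1, 1] <- TRUE
    fm <- ecgmatch:::feature_matrix_tibble(vals)
    # explicit loop oracle
    acc <- 0; k <- 0
    for (f in 1:7) for (l in 1:12) if (mask[f, l]) {
      acc <- acc + vals[f, l]; k <- k + 1
    }
    expect_equal(similarity_index(fm, id_model(mask)), acc / k)
  }

  nothing <- ecgmatch:::feature_matrix_tibble(matrix(NA_real_, 7, 12))
  expect_error(similarity_index(nothing, id_model()),
               class = "ecgmatch_degenerate_error")
})

test_that("identification picks the own-template match and breaks ties by order", {
  cohort <- small_cohort(n = 5, seed = 62)
  s <- cohort_sessions(cohort)

  # a noise-free duplicate of the probe in the gallery always wins
  probe <- s$t1[[3]]
  res <- identify_probe(probe, s$t1)
  expect_identical(attr(res, "predicted_id"), "S003")
  expect_equal(res$score[res$reference_id == "S003"], 100, tolerance = 1e-9)

  # end-to-end: scores equal an independent per-pair recomputation
  res2 <- identify_probe(s$t2[[3]], s$t1)
  loop_scores <- vapply(s$t1, function(g) {
    similarity_index(pattern_features(s$t2[[3]], g), id_model())
  }, numeric(1))
  expect_equal(res2$score, unname(loop_scores), tolerance = 1e-9)
  expect_identical(attr(res2, "predicted_id"),
                   s$ids[which.max(loop_scores)])

  # exact ties resolve to the earlier gallery position
  twin_gallery <- s$t1[c(2, 2, 4)]
  res3 <- identify_probe(s$t2[[2]], twin_gallery)
  expect_identical(which(res3$predicted), 1L)
  expect_error(identify_probe(probe, list()), "empty")
})

test_that("identification accuracy is the percentage of correct decisions", {
  expect_equal(acc_id(c(TRUE, TRUE, TRUE)), 100)
  expect_equal(acc_id(c(TRUE, TRUE, TRUE, FALSE)), 75)
  cohort <- small_cohort(n = 6, seed = 63)
  res <- identify_cohort(cohort)
  expect_equal(acc_id(res), 100 * mean(res$subject_id == res$predicted_id))
})

test_that("stepwise training finds a perfectly separating entry first", {
  withr::local_seed(64)
  n <- 8
  feats <- array(runif(n * n * 84, 40, 60), c(n, n, 7, 12),
                 dimnames = list(NULL, NULL, ecgmatch:::FEATURES,
                                 ecgmatch:::LEADS))
  # entry (feature 4, lead 9) alone separates every subject
  feats[, , 4, 9] <- 0
  for (i in 1:n) feats[i, i, 4, 9] <- 100
  model <- train_id_model(cohort = NULL, features = feats)
  expect_identical(model$trace$feature[1], "r_lag0_qrs")
  expect_identical(model$trace$lead[1], "V3")
  expect_equal(model$trace$acc_id[1], 100)
  expect_true(model$enabled[4, 9])
  expect_equal(ecgmatch:::accid_from_array(feats, model), 100)
  expect_equal(glance(model)$train_acc_id, 100)
})

test_that("stepwise training is greedy, monotone and deterministic", {
  cohort <- small_cohort(n = 8, seed = 65)
  m1 <- train_id_model(cohort)
  m2 <- train_id_model(cohort)
  expect_identical(m1$enabled, m2$enabled)
  expect_identical(m1$trace, m2$trace)
  expect_true(all(diff(m1$trace$acc_id) > 0))   # strict improvement per step
  expect_identical(sum(m1$enabled), nrow(m1$trace))

  # single-candidate mask: the model is exactly that entry
  single <- matrix(FALSE, 7, 12); single[6, 2] <- TRUE
  ms <- train_id_model(cohort, candidates = single)
  expect_identical(which(ms$enabled), which(single))

  # degenerate cohort: identical patterns cannot train a model
  clones <- cohort
  clones$pattern <- rep(cohort$pattern[1], nrow(cohort))
  expect_error(train_id_model(clones), class = "ecgmatch_training_error")
})

test_that("model masks, serialization and broom methods are consistent", {
  m <- id_model(lead_mask("limb") & feature_mask("match-qrs"))
  expect_equal(sum(m$enabled), 12)   # 2 features x 6 limb leads
  expect_true(all(tidy(m)$enabled == as.vector(m$enabled)))
  expect_error(id_model(matrix(FALSE, 7, 12)))

  cohort <- small_cohort(n = 8, seed = 65)
  trained <- train_id_model(cohort)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model(trained, path)
  back <- read_model(path)
  expect_identical(back$enabled, trained$enabled)
  expect_equal(as.data.frame(back$trace), as.data.frame(trained$trace))

  expect_equal(sum(feature_mask("cor-pqrst")), 24)
  expect_equal(sum(lead_mask("V1")), 7)
})
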