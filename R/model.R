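#' Identification model: an enable-mask over the feature-by-lead grid
#'
#' An `id_model` is a binary mask over the 7 x 12 feature-lead grid
#' selecting which entries enter the similarity index. Restricting the mask
#' reproduces every model family of interest: single feature in a single
#' lead, one feature-extraction method across all leads, all features in a
#' lead set, or the full grid.
#'
#' @param enabled 7 x 12 logical matrix (rows = features in the canonical
#'   order, columns = leads), or `NULL` for the all-enabled model. At least
#'   one entry must be enabled.
#' @param trace optional training trace tibble (filled by
#'   [train_id_model()]).
#' @return An object of class `id_model`.
#' @export
#' @examples
#' id_model()                       # full 7 x 12 model
#' id_model(lead_mask("II"))        # all features, lead II only
id_model <- function(enabled = NULL, trace = NULL) {
  if (is.null(enabled)) enabled <- matrix(TRUE, 7L, 12L)
  enabled <- as.matrix(enabled)
  stopifnot(identical(dim(enabled), c(7L, 12L)))
  mode(enabled) <- "logical"
  if (!any(enabled)) abort("an id_model must enable at least one entry.")
  dimnames(enabled) <- list(FEATURES, LEADS)
  structure(list(enabled = enabled, trace = trace), class = "id_model")
}

#' Build enable-masks for common model families
#'
#' `lead_mask()` enables all 7 features in the given lead(s); `feature_mask()`
#' enables the given feature(s) in all 12 leads. Combine with `&` or `|` on
#' the returned matrices for finer restrictions. Lead sets: `"limb"` is
#' I, II, III, aVR, aVL, aVF; `"chest"` is V1...V6; `"all"` is every lead.
#'
#' @param leads lead names, or one of `"all"`, `"limb"`, `"chest"`.
#' @param features feature names among
#'   `r paste0('\x60', FEATURES, '\x60', collapse = ", ")`, or a method name
#'   among `"cor-pqrst"`, `"cor-qrs"`, `"amp-qrs"`, `"match-qrs"`, or
#'   `"all"`.
#' @return A 7 x 12 logical matrix.
#' @export
lead_mask <- function(leads = "all") {
  if (length(leads) == 1 && leads %in% c("all", "limb", "chest")) {
    leads <- switch(leads, all = LEADS, limb = LIMB_LEADS, chest = CHEST_LEADS)
  } else {
    leads <- match.arg(leads, LEADS, several.ok = TRUE)
  }
  m <- matrix(FALSE, 7L, 12L, dimnames = list(FEATURES, LEADS))
  m[, leads] <- TRUE
  m
}

#' @rdname lead_mask
#' @export
feature_mask <- function(features = "all") {
  groups <- list(
    "all" = FEATURES,
    "cor-pqrst" = FEATURES[1:2], "cor-qrs" = FEATURES[3:4],
    "amp-qrs" = FEATURES[5], "match-qrs" = FEATURES[6:7]
  )
  features <- if (features[1] %in% names(groups)) groups[[features[1]]]
              else match.arg(features, FEATURES, several.ok = TRUE)
  m <- matrix(FALSE, 7L, 12L, dimnames = list(FEATURES, LEADS))
  m[features, ] <- TRUE
  m
}

#' @export
print.id_model <- function(x, ...) {
  cat(sprintf("<id_model> %d of 84 feature-lead entries enabled\n",
              sum(x$enabled)))
  if (!is.null(x$trace)) {
    cat(sprintf("  trained in %d steps, final training AccID %.1f%%\n",
                nrow(x$trace), tail(x$trace$acc_id, 1)))
  }
  invisible(x)
}

#' @describeIn id_model tidy the enable-mask into a (feature, lead, enabled)
#'   tibble.
#' @param x an `id_model`.
#' @param ... unused.
#' @method tidy id_model
#' @export
tidy.id_model <- function(x, ...) {
  tibble(
    feature = factor(rep(FEATURES, times = 12L), levels = FEATURES),
    lead = factor(rep(LEADS, each = 7L), levels = LEADS),
    enabled = as.vector(x$enabled)
  )
}

#' @describeIn id_model one-row model summary (entries enabled, training
#'   steps, final training accuracy).
#' @method glance id_model
#' @export
glance.id_model <- function(x, ...) {
  tibble(
    n_enabled = sum(x$enabled),
    n_steps = if (is.null(x$trace)) NA_integer_ else nrow(x$trace),
    train_acc_id = if (is.null(x$trace)) NA_real_ else tail(x$trace$acc_id, 1)
  )
}

#' Similarity index of a feature matrix under a model
#'
#' The arithmetic mean of the feature-matrix entries that are both enabled
#' by the model and available (non-degenerate), on the \[0, 100\] scale.
#' This single number is what the identification decision maximizes across
#' the gallery.
#'
#' @param fm a feature tibble from [pattern_features()].
#' @param model an [id_model()].
#' @return The similarity index, a value in \[0, 100\].
#' @export
similarity_index <- function(fm, model = id_model()) {
  vals <- feature_matrix_values(fm)
  use <- model$enabled & !is.na(vals)
  if (!any(use)) {
    abort("no enabled feature-lead entry is available.",
          class = "ecgmatch_degenerate_error")
  }
  mean(vals[use])
}

#' Identify a probe pattern against a gallery
#'
#' Computes the similarity index of the probe against every gallery pattern
#' and returns the gallery subject with the maximal score (closed-set
#' identification: the probe's true identity is assumed enrolled). Exact
#' score ties are broken deterministically in favour of the earlier gallery
#' position.
#'
#' @param probe a pre-processed [ecg_pattern()] (typically a T2 recording).
#' @param gallery list of pre-processed [ecg_pattern()] objects (T1
#'   recordings), or a cohort tibble filtered to one session.
#' @param model an [id_model()].
#' @param cfg a [bin_config()].
#' @return A tibble with one row per gallery member: `reference_id`,
#'   `score`, `rank` and `predicted` (TRUE for the decided identity), with
#'   the decided identity in attribute `"predicted_id"`.
#' @export
identify_probe <- function(probe, gallery, model = id_model(),
                           cfg = bin_config()) {
  if (is.data.frame(gallery)) {
    ids <- gallery$subject_id
    gallery <- gallery$pattern
  } else {
    ids <- purrr::map_chr(gallery, "subject_id")
  }
  if (length(gallery) == 0) abort("empty gallery.")
  arr <- pairwise_features(list(probe), gallery, cfg)
  scores <- score_array(arr, model)[1, ]
  best <- which.max(scores)  # first maximum: earlier gallery position wins
  out <- tibble(
    reference_id = ids,
    score = scores,
    rank = rank(-scores, ties.method = "first"),
    predicted = seq_along(scores) == best
  )
  attr(out, "predicted_id") <- ids[best]
  out
}

# Score every (probe, gallery) pair of a pairwise_features() array under a
# model: mean over enabled & available entries. Returns np x ng matrix.
score_array <- function(arr, model) {
  d <- dim(arr)
  flat <- matrix(arr, d[1] * d[2], d[3] * d[4])
  keep <- as.vector(model$enabled)
  sub <- flat[, keep, drop = FALSE]
  matrix(rowMeans(sub, na.rm = TRUE), d[1], d[2])
}

#' Closed-set identification accuracy
#'
#' The percentage of probes whose top-scoring gallery subject is their true
#' identity.
#'
#' @param results a logical vector of per-probe correctness, or a tibble
#'   with a logical `correct` column.
#' @return A percentage in \[0, 100\].
#' @export
acc_id <- function(results) {
  correct <- if (is.data.frame(results)) results$correct else results
  stopifnot(is.logical(correct), length(correct) > 0)
  100 * sum(correct) / length(correct)
}

# AccID of a model over a precomputed feature array whose probes and gallery
# are in the same subject order (probe i's true match is gallery i).
accid_from_array <- function(arr, model) {
  sc <- score_array(arr, model)
  pred <- max.col(sc, ties.method = "first")
  100 * mean(pred == seq_len(nrow(sc)))
}

#' Train an identification model by forward stepwise selection
#'
#' Greedy wrapper selection over the feature-by-lead grid: starting from the
#' empty model, each step evaluates the training identification accuracy
#' (every subject's T2 identified against all subjects' T1) for each
#' not-yet-enabled candidate entry added alone, enables the best strictly
#' improving entry, and stops when no candidate strictly improves. Ties are
#' broken toward the lowest feature index, then the lowest lead index, so
#' training is fully deterministic. The per-step accuracy trace is recorded
#' in the model.
#'
#' @param cohort a pre-processed two-session cohort tibble (>= 2 subjects).
#' @param candidates 7 x 12 logical matrix of candidate entries (see
#'   [lead_mask()], [feature_mask()]); defaults to the full grid.
#' @param cfg a [bin_config()].
#' @param features optional precomputed [pairwise_features()] array
#'   (probes = T2, gallery = T1, both in subject order).
#' @return A trained [id_model()] whose `trace` tibble has one row per step
#'   (`step`, `feature`, `lead`, `acc_id`).
#' @export
train_id_model <- function(cohort, candidates = NULL, cfg = bin_config(),
                           features = NULL) {
  if (is.null(candidates)) candidates <- matrix(TRUE, 7L, 12L)
  mode(candidates) <- "logical"
  stopifnot(identical(dim(candidates), c(7L, 12L)), any(candidates))
  if (is.null(features)) {
    sessions <- split_sessions(cohort)
    if (length(sessions$t1) < 2) abort("training needs at least 2 subjects.")
    if (all_patterns_identical(sessions$t1)) {
      abort("degenerate cohort: all reference patterns are identical.",
            class = "ecgmatch_training_error")
    }
    features <- pairwise_features(sessions$t2, sessions$t1, cfg)
  }
  d <- dim(features)
  enabled <- matrix(FALSE, 7L, 12L)
  best_acc <- -Inf
  trace <- list()
  # incremental sums/counts of enabled & available entries per pair
  flat <- matrix(features, d[1] * d[2], 84L)
  avail <- !is.na(flat)
  flat[!avail] <- 0
  sums <- numeric(d[1] * d[2]); cnts <- numeric(d[1] * d[2])
  truth <- seq_len(d[1])
  repeat {
    cand_idx <- which(as.vector(candidates) & !as.vector(enabled))
    if (!length(cand_idx)) break
    # evaluate in (feature, lead) order so ties resolve to the lowest
    # feature index first, then the lowest lead index
    cand_idx <- cand_idx[order((cand_idx - 1L) %% 7L, (cand_idx - 1L) %/% 7L)]
    accs <- vapply(cand_idx, function(k) {
      s <- sums + flat[, k]; cn <- cnts + avail[, k]
      sc <- matrix(ifelse(cn > 0, s / cn, NA_real_), d[1], d[2])
      100 * mean(max.col(sc, ties.method = "first") == truth)
    }, numeric(1))
    best <- max(accs)
    if (best <= best_acc) break
    k <- cand_idx[which.max(accs)]   # lowest feature index, then lowest lead
    enabled[k] <- TRUE
    sums <- sums + flat[, k]; cnts <- cnts + avail[, k]
    best_acc <- best
    trace[[length(trace) + 1L]] <- tibble(
      step = length(trace) + 1L,
      feature = FEATURES[(k - 1L) %% 7L + 1L],
      lead = LEADS[(k - 1L) %/% 7L + 1L],
      acc_id = best)
  }
  if (!any(enabled)) {
    abort("training failed: no candidate entry achieved a finite accuracy.",
          class = "ecgmatch_training_error")
  }
  id_model(enabled, trace = bind_rows(trace))
}

all_patterns_identical <- function(patterns) {
  first <- patterns[[1]]$samples
  all(purrr::map_lgl(patterns[-1], ~ isTRUE(all.equal(.x$samples, first))))
}

#' Identify every cohort subject's probe against a gallery
#'
#' Runs the closed-set identification of each subject's T2 recording against
#' all subjects' T1 recordings and reports per-subject outcomes. This is the
#' batch evaluation underlying both training and validation accuracies.
#'
#' @param cohort pre-processed two-session cohort tibble.
#' @param model an [id_model()].
#' @param cfg a [bin_config()].
#' @param features optional precomputed [pairwise_features()] array.
#' @return A tibble with columns `subject_id`, `predicted_id`, `score`,
#'   `correct`.
#' @export
identify_cohort <- function(cohort, model = id_model(), cfg = bin_config(),
                            features = NULL) {
  sessions <- split_sessions(cohort)
  if (is.null(features)) {
    features <- pairwise_features(sessions$t2, sessions$t1, cfg)
  }
  sc <- score_array(features, model)
  pred <- max.col(sc, ties.method = "first")
  tibble(
    subject_id = sessions$ids,
    predicted_id = sessions$ids[pred],
    score = sc[cbind(seq_along(pred), pred)],
    correct = pred == seq_along(pred)
  )
}
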