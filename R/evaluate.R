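#' Identification accuracy as a function of reference-database size
#'
#' For each gallery size N, draws subsets of N cohort subjects, identifies
#' every subset member's T2 recording against the subset members' T1
#' recordings, and reports the mean accuracy with a confidence half-width.
#' Enumerating all subsets is combinatorially infeasible beyond tiny sizes,
#' so subsets are seeded Monte-Carlo draws (unique subsets, uniform over
#' combinations); whenever the exact combination count is at most
#' `n_resamples` every subset is enumerated instead — in particular N equal
#' to the cohort size yields the single full-gallery evaluation.
#'
#' @param cohort pre-processed two-session cohort tibble.
#' @param model an [id_model()].
#' @param sizes strictly increasing gallery sizes, each at most the cohort
#'   size.
#' @param n_resamples maximal number of subsets per size (default 1000).
#' @param seed integer seed governing the subset draws.
#' @param level confidence level (default 0.95).
#' @param cfg a [bin_config()].
#' @param features optional precomputed [pairwise_features()] array for the
#'   full cohort.
#' @return An `accid_curve` tibble with one row per size: `n_subjects`,
#'   `mean_accid`, `ci_halfwidth` (normal-approximation across subsets; for
#'   a single exhaustive subset a Wilson binomial interval on the correct
#'   count), `n_subsets`, `exhaustive`. Attributes record `seed`, `level`
#'   and `n_resamples`.
#' @export
evaluate_size_sweep <- function(cohort, model = id_model(), sizes,
                                n_resamples = 1000L, seed = 1L,
                                level = 0.95, cfg = bin_config(),
                                features = NULL) {
  sessions <- split_sessions(cohort)
  n <- length(sessions$t1)
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(diff(sizes) > 0), all(sizes >= 1))
  if (max(sizes) > n) abort("a requested size exceeds the cohort size.")
  if (n_resamples < 1) abort("`n_resamples` must be at least 1.")
  if (is.null(features)) {
    features <- pairwise_features(sessions$t2, sessions$t1, cfg)
  }
  rows <- withr::with_seed(seed, {
    map(sizes, function(N) {
      subsets <- draw_subsets(n, N, n_resamples)
      accs <- map_dbl(subsets, function(idx) {
        accid_from_array(features[idx, idx, , , drop = FALSE], model)
      })
      exhaustive <- attr(subsets, "exhaustive")
      if (length(accs) == 1L) {
        hw <- wilson_halfwidth(round(accs[1] / 100 * N), N, level)
      } else {
        hw <- confidence_interval(accs, level)
      }
      tibble(n_subjects = N, mean_accid = mean(accs), ci_halfwidth = hw,
             n_subsets = length(accs), exhaustive = exhaustive)
    })
  })
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  attr(out, "n_resamples") <- n_resamples
  class(out) <- c("accid_curve", class(out))
  out
}

# Unique subsets of size N from n subjects: full enumeration when feasible,
# otherwise uniform draws deduplicated until `count` unique subsets.
draw_subsets <- function(n, N, count) {
  total <- suppressWarnings(choose(n, N))
  if (is.finite(total) && total <= count) {
    subsets <- combn(n, N, simplify = FALSE)
    attr(subsets, "exhaustive") <- TRUE
    return(subsets)
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  subsets <- vector("list", count)
  got <- 0L
  while (got < count) {
    idx <- sort(sample.int(n, N))
    key <- paste(idx, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      subsets[[got]] <- idx
    }
  }
  attr(subsets, "exhaustive") <- FALSE
  subsets
}

#' Confidence half-width of a mean accuracy
#'
#' Normal-approximation confidence half-width of the mean across resampled
#' subset accuracies: `z * sd(values) / sqrt(length(values))`.
#'
#' @param values accuracy values from repeated subsets (length >= 1).
#' @param level confidence level (default 0.95).
#' @return The half-width in accuracy points (0 for a single value or
#'   constant values).
#' @export
confidence_interval <- function(values, level = 0.95) {
  if (length(values) == 0) abort("no values.")
  if (length(values) == 1) return(0)
  qnorm(1 - (1 - level) / 2) * sd(values) / sqrt(length(values))
}

# Wilson score interval half-width for a binomial proportion, on the
# percentage scale; used when a size admits only the single full subset.
wilson_halfwidth <- function(successes, trials, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  100 * half
}

#' Write an accuracy curve to CSV and plot it
#'
#' Writes `<stem>.csv` (columns `n_subjects`, `mean_accid`, `ci_halfwidth`)
#' and `<stem>.pdf` with the accuracy-versus-gallery-size curve.
#'
#' @param curve an `accid_curve` from [evaluate_size_sweep()].
#' @param stem output path without extension.
#' @return Character vector of the two written paths, invisibly.
#' @export
report_curve <- function(curve, stem) {
  csv <- paste0(stem, ".csv"); pdf <- paste0(stem, ".pdf")
  readr::write_csv(as_tibble(curve), csv, progress = FALSE)
  ggsave(pdf, autoplot(curve), width = 6, height = 4)
  invisible(c(csv, pdf))
}

#' Plot an accuracy-versus-gallery-size curve
#'
#' @param object an `accid_curve` from [evaluate_size_sweep()].
#' @param ... unused.
#' @return A ggplot object: mean identification accuracy against the number
#'   of reference subjects, with the confidence band.
#' @method autoplot accid_curve
#' @export
autoplot.accid_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$n_subjects, y = .data$mean_accid)) +
    geom_ribbon(aes(ymin = .data$mean_accid - .data$ci_halfwidth,
                    ymax = .data$mean_accid + .data$ci_halfwidth),
                alpha = 0.2) +
    geom_line() + geom_point() +
    scale_y_continuous(limits = c(0, 100)) +
    labs(x = "Number of reference subjects", y = "Identification accuracy (%)") +
    theme_minimal()
}

#' @export
print.accid_curve <- function(x, ...) {
  cat(sprintf("<accid_curve> %d sizes, seed %s, %d max subsets per size\n",
              nrow(x), format(attr(x, "seed")), attr(x, "n_resamples")))
  print(as_tibble(x), ...)
  invisible(x)
}
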