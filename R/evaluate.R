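# Scoring and analysis: prediction correlation, the complexity score
# contrasting complex-shaped vs Gabor front-ends, orientation-tuned vs
# higher-order labeling, 1-D threshold classification, and the
# data-efficiency / convergence protocols.

#' Pearson correlation between predictions and observations
#'
#' Standard Pearson r; if either input has zero variance the correlation is
#' undefined and 0 is returned (with a warning unless `warn = FALSE`), so
#' downstream scores stay bounded and order-preserving.
#'
#' @param pred,truth Equal-length numeric vectors (length >= 2).
#' @param warn Warn on zero-variance input (default `TRUE`).
#' @return Pearson r in \[-1, 1\].
#' @examples
#' pearson(1:10, (1:10)^2)
#' @export
pearson <- function(pred, truth, warn = TRUE) {
  if (length(pred) != length(truth)) stop_invalid("length mismatch")
  if (length(pred) < 2) stop_invalid("need at least 2 samples")
  sp <- stats::sd(pred)
  st <- stats::sd(truth)
  if (!is.finite(sp) || !is.finite(st) || sp == 0 || st == 0) {
    if (warn) warning("zero-variance input: Pearson undefined, scoring 0")
    return(0)
  }
  stats::cor(pred, truth)
}

#' Complexity score of a neuron
#'
#' Contrasts the prediction accuracy of a complex-shaped sparse-code
#' front-end model with that of a Gabor front-end model:
#' `(corr_complex - corr_gabor) / (corr_complex + corr_gabor)`.
#' Positive scores mean the complex basis explains the neuron better;
#' when both correlations are positive the score lies in (-1, 1), is 0 at
#' equality, and is antisymmetric under swapping the two models.
#'
#' @param corr_complex Test correlation of the complex-front-end model.
#' @param corr_gabor Test correlation of the Gabor-front-end model.
#' @return The score (vectorized).
#' @examples
#' complexity_score(0.6, 0.2)  # 0.5
#' @export
complexity_score <- function(corr_complex, corr_gabor) {
  denom <- corr_complex + corr_gabor
  if (any(denom == 0)) {
    stop(errorCondition("zero denominator: complexity score undefined",
                        class = c("rfpursuit_undefined_score", "error")))
  }
  (corr_complex - corr_gabor) / denom
}

#' Label neurons as orientation-tuned (OT) or higher-order (HO)
#'
#' A neuron is OT iff at least one qualifying oriented stimulus (by
#' default, category `"bar"`) elicits a response strictly above
#' `peak_fraction` of the neuron's peak response over the whole stimulus
#' set; otherwise it is HO (all its preferred stimuli are complex
#' patterns).
#'
#' @param responses Stimuli x neurons response matrix (or data frame).
#' @param labels Stimulus label tibble with a `category` column (one row
#'   per stimulus).
#' @param peak_fraction Fraction of the peak defining "comparable drive"
#'   (default 0.5).
#' @param ot_categories Categories that count as single oriented stimuli.
#' @return A tibble with `neuron`, `peak`, `best_oriented`, `label`.
#' @export
label_ot_ho <- function(responses, labels, peak_fraction = 0.5,
                        ot_categories = "bar") {
  m <- as.matrix(responses)
  labels <- tibble::as_tibble(labels)
  if (nrow(labels) != nrow(m)) stop_invalid("labels must have one row per stimulus")
  is_ori <- labels$category %in% ot_categories
  if (!any(is_ori)) stop_invalid("no oriented (bar/edge) stimuli in the set")
  peak <- unname(apply(m, 2, max))
  best_ori <- unname(apply(m[is_ori, , drop = FALSE], 2, max))
  tibble::tibble(
    neuron = if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m),
    peak = peak,
    best_oriented = best_ori,
    label = ifelse(best_ori > peak_fraction * peak, "OT", "HO")
  )
}

#' Optimal 1-D threshold classifier
#'
#' Exhaustively scans all decision thresholds (midpoints between sorted
#' unique scores plus the two degenerate extremes) in both orientations
#' (`score > t` labels positive, or `score < t`), and returns the
#' accuracy-maximizing rule, its training accuracy, and the majority-class
#' baseline. This is the exactly optimal linear decision rule on a 1-D
#' score.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (logical, 0/1, or a 2-level factor /
#'   character vector; the second sorted level is "positive").
#' @return A list with `threshold`, `direction` (`">"` or `"<"`),
#'   `accuracy`, `baseline`.
#' @examples
#' threshold_classifier(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
#' @export
threshold_classifier <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) {
    stop_invalid("need exactly two classes, got ", length(lv))
  }
  ybin <- as.character(labels) == lv[2]
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- list(threshold = cand[1], direction = ">", accuracy = -1)
  n <- length(scores)
  for (t in cand) {
    acc_gt <- mean((scores > t) == ybin)
    acc_lt <- mean((scores < t) == ybin)
    if (acc_gt > best$accuracy) best <- list(threshold = t, direction = ">", accuracy = acc_gt)
    if (acc_lt > best$accuracy) best <- list(threshold = t, direction = "<", accuracy = acc_lt)
  }
  best$baseline <- max(mean(ybin), 1 - mean(ybin))
  best
}

#' Data-efficiency experiment
#'
#' For each training fraction and seed, subsamples the training split only
#' (validation and test stay fixed), trains a model via `model_factory`,
#' and records the test Pearson correlation. Reports per-fraction means and
#' the relative performance drop against the full-data run.
#'
#' @param model_factory `function(train_stimuli, train_y, seed)` returning
#'   a fitted object with a `predict(object, stimuli)` method.
#' @param stimuli A `stimulus_set`.
#' @param y Response vector.
#' @param fractions Training fractions in (0, 1\]; must include 1.
#' @param n_seeds Subsampling seeds per fraction (default 3).
#' @param split Length-3 train/val/test fractions (default 60/20/20).
#' @param seed Base seed for the split and subsampling.
#' @return An `efficiency_curve` tibble with columns `fraction`,
#'   `mean_performance`, `sd_performance`, `performance_drop` (relative
#'   drop vs fraction 1, exactly 0 there).
#' @export
data_efficiency_experiment <- function(model_factory, stimuli, y,
                                       fractions = c(1, 0.5, 0.25, 0.125),
                                       n_seeds = 3,
                                       split = c(0.6, 0.2, 0.2), seed = 1) {
  if (!any(fractions == 1)) stop_invalid("fractions must include 1.0")
  if (any(fractions <= 0 | fractions > 1)) stop_invalid("fractions must lie in (0, 1]")
  idx <- split_indices(length(stimuli), split, seed)
  test_stim <- stimuli[idx$test]
  y_test <- y[idx$test]
  rows <- list()
  for (fr in sort(fractions, decreasing = TRUE)) {
    perfs <- vapply(seq_len(n_seeds), function(s) {
      sub <- if (fr == 1) idx$train else {
        with_seed(seed + 1000L * s + round(1e4 * fr),
                  sample(idx$train, round(fr * length(idx$train))))
      }
      if (length(sub) < 10) stop_invalid("fraction ", fr, " leaves < 10 training samples")
      fit <- model_factory(stimuli[sub], y[sub], seed + s)
      pearson(predict(fit, test_stim), y_test, warn = FALSE)
    }, 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fraction = fr, mean_performance = mean(perfs),
      sd_performance = stats::sd(perfs)
    )
  }
  out <- dplyr::bind_rows(rows)
  full <- out$mean_performance[out$fraction == 1][1]
  out$performance_drop <- ifelse(out$fraction == 1, 0,
                                 (full - out$mean_performance) / abs(full))
  class(out) <- c("efficiency_curve", class(out))
  out
}

#' Summarize convergence (epochs to stabilize) across trained nets
#'
#' @param nets A list of trained `rf_net` objects (or a list of lists,
#'   named by model).
#' @return A tibble with per-model `median`, `q25`, `q75` of
#'   `epochs_to_stop`, plus `n`.
#' @export
convergence_summary <- function(nets) {
  if (inherits(nets[[1]], "rf_net")) nets <- list(model = nets)
  rows <- lapply(names(nets), function(nm) {
    ep <- vapply(nets[[nm]], `[[`, 0L, "epochs_to_stop")
    qs <- stats::quantile(ep, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(model = nm, n = length(ep), q25 = qs[1],
                   median = qs[2], q75 = qs[3])
  })
  dplyr::bind_rows(rows)
}
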