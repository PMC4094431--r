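#' Sample-wise classification accuracy curve and peak
#'
#' For each time point of the classification period, the fraction of trials
#' whose per-sample prediction matches the trial's class label; the reported
#' headline figure is the curve's peak.
#'
#' @param pred character (or logical) matrix, trials x time points, of
#'   per-sample predicted labels.
#' @param labels true class label per trial.
#' @param t optional time base (seconds) for the columns.
#' @return list of class `"accuracy_curve"`: `t`, `acc` (fractions), `peak`
#'   (percent).
#' @export
samplewise_accuracy <- function(pred, labels, t = NULL) {
  pred <- as.matrix(pred)
  if (nrow(pred) != length(labels))
    stop("one label per trial required")
  if (length(unique(labels)) < 2)
    stop("need at least one trial per class")
  correct <- pred == matrix(labels, nrow(pred), ncol(pred))
  acc <- colMeans(correct)
  if (is.null(t)) t <- seq_len(ncol(pred))
  else if (length(t) != ncol(pred)) stop("misaligned time base")
  structure(list(t = t, acc = acc, peak = 100 * max(acc)),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d time points, peak %.1f %%\n",
              length(x$acc), x$peak))
  invisible(x)
}

# TRUE when the output stream contains >= 1 uninterrupted above-threshold
# span of at least dwell_n samples
has_activation <- function(o, threshold, dwell_n) {
  r <- rle(o > threshold)
  any(r$values & r$lengths >= dwell_n)
}

#' Youden index over a threshold-by-dwell-time grid
#'
#' For each grid cell, a movement-imagery trial counts as a true positive
#' when its output stream contains at least one uninterrupted above-threshold
#' span of the dwell length (otherwise a false negative); a non-control trial
#' with such a span is a false positive (otherwise a true negative). The
#' Youden index J = TPR - FPR ranges from -1 (all targets missed, all
#' non-targets hit) to +1; the maximum over the grid is returned, ties going
#' to the first cell in grid order (thresholds fastest).
#'
#' @param outputs numeric matrix, trials x time points, of normalized
#'   classifier outputs over the classification period.
#' @param labels class label per trial.
#' @param positive movement-imagery class label.
#' @param thresholds candidate activation thresholds (normalized output
#'   scale).
#' @param dwells candidate dwell times in seconds.
#' @param fs sampling rate in Hz.
#' @return list: `J` (best index), `threshold`, `dwell`, `grid` (data.frame
#'   of all cells with TP/FP/TN/FN and J).
#' @export
youden_index <- function(outputs, labels, positive,
                         thresholds = seq(-0.75, 0.75, by = 0.25),
                         dwells = seq(0.5, 4, by = 0.5), fs = 256) {
  if (!length(thresholds) || !length(dwells)) stop("empty grid")
  outputs <- as.matrix(outputs)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes required")
  grid <- expand.grid(threshold = thresholds, dwell = dwells,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(apply(grid, 1, function(g) {
    dn <- round(g[["dwell"]] * fs)
    act <- apply(outputs, 1, has_activation, threshold = g[["threshold"]],
                 dwell_n = dn)
    tp <- sum(act & pos); fn <- sum(!act & pos)
    fp <- sum(act & !pos); tn <- sum(!act & !pos)
    c(TP = tp, FN = fn, FP = fp, TN = tn,
      J = tp / (tp + fn) - fp / (fp + tn))
  }))
  grid <- cbind(grid, as.data.frame(res))
  best <- which.max(grid$J)
  list(J = grid$J[best], threshold = grid$threshold[best],
       dwell = grid$dwell[best], grid = grid)
}

# one-sided adjusted-Wald upper bound on chance (p = 0.5) accuracy, percent
adjusted_wald_upper <- function(n, alpha) {
  if (n < 2) stop("need n >= 2")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  z <- qnorm(1 - alpha)
  p <- (n / 2 + z^2 / 2) / (n + z^2)
  100 * (p + z * sqrt(p * (1 - p) / (n + z^2)))
}

#' Chance-level accuracy threshold for cue-paced classification
#'
#' One-sided adjusted-Wald upper confidence bound around the theoretical
#' two-class chance level (50 %) for `N = 2 x` trials-per-class trials.
#' Accuracies above this bound are better than chance at significance
#' `alpha`. At 54 trials per class and `alpha = 0.01` the bound is ~61 %.
#'
#' @param n_trials_per_class artifact-free trials per class.
#' @param alpha one-sided significance level.
#' @return threshold accuracy in percent.
#' @export
chance_threshold <- function(n_trials_per_class, alpha = 0.01) {
  adjusted_wald_upper(2 * n_trials_per_class, alpha)
}

#' Chance-level balanced-accuracy threshold for the self-paced paradigm
#'
#' Conservative adjusted-Wald bound computed on the number of target segments
#' only (the smaller class), as balanced accuracy averages the two rates and
#' the target count dominates its variance.
#'
#' @param n_target_segments number of target segments.
#' @param alpha one-sided significance level.
#' @return threshold balanced accuracy in percent.
#' @export
selfpaced_chance_threshold <- function(n_target_segments, alpha = 0.01) {
  adjusted_wald_upper(n_target_segments, alpha)
}

#' Class-imbalance-corrected (balanced) accuracy
#'
#' Mean of the true-positive rate and the true-negative rate, in percent.
#' Row-normalizing the confusion matrix makes the theoretical chance level
#' 50 % regardless of the target-segment prevalence.
#'
#' @param counts named list or vector with `TP`, `FP`, `TN`, `FN`.
#' @return balanced accuracy in percent.
#' @export
balanced_accuracy <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if ((tp + fn) == 0 || (tn + fp) == 0)
    stop("both outcome classes must be represented")
  100 * (tp / (tp + fn) + tn / (tn + fp)) / 2
}

#' Confusion counts from self-paced segment records
#'
#' @param segrecs data.frame of segment records (from
#'   [run_selfpaced_session()]) with columns `is_target` and `activations`.
#' @return list with `TP`, `FP`, `TN`, `FN` and `target_fraction`.
#' @export
confusion_counts <- function(segrecs) {
  tgt <- segrecs$is_target
  a <- segrecs$activations
  list(TP = sum(a[tgt]), FN = sum(tgt & a == 0),
       FP = sum(a[!tgt]), TN = sum(!tgt & a == 0),
       target_fraction = mean(tgt))
}
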