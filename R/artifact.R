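#' Artifact screening configuration
#'
#' Thresholds for trial-based screening and the AR-residual real-time
#' detector. Amplitude and z-score limits follow common automated EEG
#' screening practice; all are configurable.
#'
#' @param a_max absolute amplitude limit in microvolts.
#' @param z_max z-score limit for the kurtosis and probability statistics
#'   relative to the trial history.
#' @param outlier_k leave-one-out SD multiple for feature-outlier rejection.
#' @param ar_order autoregressive model order for real-time detection.
#' @param residual_q quantile of absolute training residuals defining the
#'   detection threshold (fixes the training false-flag rate by construction).
#' @param hold seconds an artifact flag is held after detection offset.
#' @param min_history minimum number of history trials before the
#'   distribution-based statistics are applied (amplitude-only below).
#' @param min_ar_seconds minimum clean EEG (per channel) required to fit the
#'   AR model.
#' @return list of class `"artifact_config"`.
#' @export
artifact_config <- function(a_max = 100, z_max = 5, outlier_k = 3,
                            ar_order = 11, residual_q = 0.99, hold = 0.5,
                            min_history = 4, min_ar_seconds = 10) {
  structure(list(a_max = a_max, z_max = z_max, outlier_k = outlier_k,
                 ar_order = ar_order, residual_q = residual_q, hold = hold,
                 min_history = min_history, min_ar_seconds = min_ar_seconds),
            class = "artifact_config")
}

artifact_verdict <- function(reasons = character()) {
  reasons <- sort(unique(reasons))
  structure(list(clean = length(reasons) == 0L, reasons = reasons),
            class = "artifact_verdict")
}

#' @export
print.artifact_verdict <- function(x, ...) {
  if (x$clean) cat("<artifact_verdict> clean\n")
  else cat("<artifact_verdict> artifactual:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

# per-channel mean, mean squared deviation, kurtosis (m4/m2^2)
channel_stats <- function(mat) {
  m <- colMeans(mat)
  d <- sweep(mat, 2, m)
  m2 <- colMeans(d^2)
  m4 <- colMeans(d^4)
  list(mean = m, msq = m2, kurt = m4 / pmax(m2^2, .Machine$double.xmin))
}

#' Trial-based statistical artifact screening
#'
#' Flags a band-filtered trial epoch as artifactual by (i) absolute amplitude
#' thresholding and (ii) comparing the per-channel kurtosis and mean Gaussian
#' log-likelihood ("probability") statistics against their distribution over
#' the trial history. A statistic whose z-score against the history exceeds
#' `z_max` on any channel flags the trial. With fewer than `min_history`
#' history trials only the amplitude criterion is applied.
#'
#' @param trial_eeg band-filtered bipolar [eeg_segment()] (or numeric matrix)
#'   of one trial epoch.
#' @param history list of previous trial epochs (same form).
#' @param cfg an [artifact_config()].
#' @return an `"artifact_verdict"`: `clean` flag plus the subset of
#'   `{amplitude, kurtosis, probability}` reasons that fired.
#' @export
screen_trial_stats <- function(trial_eeg, history = list(),
                               cfg = artifact_config()) {
  mat <- if (inherits(trial_eeg, "eeg_segment")) trial_eeg$data else as.matrix(trial_eeg)
  if (nrow(mat) == 0L) stop("empty trial epoch")
  reasons <- character()
  if (max(abs(mat)) > cfg$a_max) reasons <- c(reasons, "amplitude")
  if (length(history) >= cfg$min_history) {
    hmats <- lapply(history, function(h)
      if (inherits(h, "eeg_segment")) h$data else as.matrix(h))
    hstats <- lapply(hmats, channel_stats)
    ts <- channel_stats(mat)
    # pooled Gaussian per channel over all history samples
    ns <- vapply(hmats, nrow, integer(1))
    wm <- rowSums(mapply(function(s, n) s$mean * n, hstats, ns)) / sum(ns)
    wv <- rowSums(mapply(function(s, n) (s$msq + (s$mean - wm)^2) * n,
                         hstats, ns)) / sum(ns)
    wv <- pmax(wv, .Machine$double.xmin)
    loglik <- function(s) -0.5 * log(2 * pi * wv) -
      (s$msq + (s$mean - wm)^2) / (2 * wv)
    kurt_h <- vapply(hstats, function(s) s$kurt, numeric(ncol(mat)))
    prob_h <- vapply(hstats, loglik, numeric(ncol(mat)))
    kurt_h <- matrix(kurt_h, nrow = ncol(mat)); prob_h <- matrix(prob_h, nrow = ncol(mat))
    zscore <- function(stat, hist) {
      mu <- rowMeans(hist); s <- apply(hist, 1, sd)
      d <- stat - mu
      ifelse(s > 0, abs(d) / s, ifelse(abs(d) > 0, Inf, 0))
    }
    if (any(zscore(ts$kurt, kurt_h) > cfg$z_max)) reasons <- c(reasons, "kurtosis")
    if (any(zscore(loglik(ts), prob_h) > cfg$z_max)) reasons <- c(reasons, "probability")
  }
  artifact_verdict(reasons)
}

#' Leave-one-out feature-outlier trial rejection
#'
#' A trial is rejected when any of its six trial-averaged band-power features
#' lies outside mean +/- k SD of the remaining trials of the same class
#' (leave-one-out distribution). Classes with fewer than 6 trials are left
#' unscreened. Verdicts are permutation-invariant and `k = Inf` disables
#' rejection.
#'
#' @param feats numeric matrix, trials x features (trial-averaged).
#' @param labels class label per trial.
#' @param k SD multiple (default from [artifact_config()]).
#' @return list with `kept` and `rejected` integer indices and the logical
#'   `reject_mask`.
#' @export
reject_feature_outliers <- function(feats, labels,
                                    k = artifact_config()$outlier_k) {
  feats <- as.matrix(feats)
  labels <- as.character(labels)
  stopifnot(nrow(feats) == length(labels))
  n <- nrow(feats)
  mask <- rep(FALSE, n)
  if (!is.infinite(k)) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      m <- length(idx)
      if (m < 6) next
      X <- feats[idx, , drop = FALSE]
      S <- colSums(X); S2 <- colSums(X^2)
      for (j in seq_len(m)) {
        x <- X[j, ]
        mu <- (S - x) / (m - 1)
        ss <- pmax(S2 - x^2 - (m - 1) * mu^2, 0)
        sdv <- sqrt(ss / (m - 2))
        if (any(abs(x - mu) > k * sdv)) mask[idx[j]] <- TRUE
      }
    }
  }
  if (all(mask)) stop("all trials rejected as feature outliers: unusable data")
  list(kept = which(!mask), rejected = which(mask), reject_mask = mask)
}

#' Fit the AR(11) model for real-time artifact detection
#'
#' Fits one autoregressive model of order `cfg$ar_order` per bipolar channel
#' (Yule-Walker, guaranteeing a stable model) on the concatenated artifact-free
#' trial epochs, and sets the per-channel detection threshold to the
#' `cfg$residual_q` quantile of the absolute training residuals, so at most
#' `1 - residual_q` of clean training samples exceed it by construction.
#'
#' @param clean_epochs list of bipolar epochs ([eeg_segment()] or matrices)
#'   judged artifact-free, or a single matrix.
#' @param cfg an [artifact_config()].
#' @param fs sampling rate in Hz (for the minimum-data check).
#' @return an `"ar_model"`: `order`, `coeffs` (order x channels),
#'   `residual_threshold` (per channel, microvolts), `channel_labels`.
#' @export
fit_ar <- function(clean_epochs, cfg = artifact_config(), fs = 256) {
  if (is.matrix(clean_epochs)) clean_epochs <- list(clean_epochs)
  mats <- lapply(clean_epochs, function(h)
    if (inherits(h, "eeg_segment")) h$data else as.matrix(h))
  labs <- colnames(mats[[1]])
  x <- do.call(rbind, mats)
  p <- cfg$ar_order
  if (nrow(x) < cfg$min_ar_seconds * fs)
    stop("need at least ", cfg$min_ar_seconds, " s of clean EEG to fit the AR model")
  coeffs <- matrix(NA_real_, p, ncol(x))
  for (ch in seq_len(ncol(x))) {
    fit <- stats::ar.yw(x[, ch], aic = FALSE, order.max = p, demean = TRUE)
    coeffs[, ch] <- fit$ar
    roots <- polyroot(c(1, -fit$ar))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop("unstable AR fit on channel ", ch, "; provide a longer clean window")
  }
  model <- structure(list(order = p, coeffs = coeffs,
                          residual_threshold = rep(NA_real_, ncol(x)),
                          channel_labels = labs, fs = fs),
                     class = "ar_model")
  # training residuals per epoch (drop the first `order` samples of each)
  res <- lapply(mats, function(m) ar_residuals(model, m))
  absres <- do.call(rbind, lapply(res, function(r)
    abs(r[-seq_len(min(p, nrow(r))), , drop = FALSE])))
  thr0 <- apply(absres, 2, quantile, probs = cfg$residual_q, names = FALSE)
  # a sample is flagged when any channel exceeds its threshold; rescale so
  # that the training false-flag rate of that union rule is 1 - residual_q
  # by construction
  u <- apply(sweep(absres, 2, thr0, "/"), 1, max)
  model$residual_threshold <- thr0 * quantile(u, cfg$residual_q,
                                              names = FALSE)
  model
}

# whitening (inverse transfer function) residuals, optionally with carried
# FIR state for streaming
ar_residuals <- function(model, mat, state = NULL, return_state = FALSE) {
  out <- mat
  st <- if (is.null(state)) vector("list", ncol(mat)) else state
  for (ch in seq_len(ncol(mat))) {
    f <- if (is.null(st[[ch]])) new_iir(c(1, -model$coeffs[, ch]), 1) else st[[ch]]
    r <- iir_apply(f, mat[, ch])
    out[, ch] <- r$y
    st[[ch]] <- r$f
  }
  if (return_state) list(residuals = out, state = st) else out
}

#' Real-time AR-residual artifact detection
#'
#' Applies the inverse transfer function of the fitted AR model to each
#' channel and flags any sample whose whitened residual magnitude exceeds the
#' channel threshold. Flags are held for `cfg$hold` seconds past detection
#' offset (matching the on-screen indicator behaviour). Carried state makes
#' block-wise streaming identical to whole-stream processing.
#'
#' @param stream an [eeg_segment()] or matrix of bipolar EEG.
#' @param model an `"ar_model"` from [fit_ar()].
#' @param cfg an [artifact_config()].
#' @param state carried detector state from the previous block, or `NULL`.
#' @return list: `flags` (logical per sample, hold applied), `raw_flags`
#'   (before hold), `residuals`, `state`.
#' @export
detect_artifact_online <- function(stream, model, cfg = artifact_config(),
                                   state = NULL) {
  if (inherits(stream, "eeg_segment")) {
    if (stream$fs != model$fs)
      stop("stream sampling rate ", stream$fs, " does not match model fs ", model$fs)
    mat <- stream$data
  } else mat <- as.matrix(stream)
  fs <- model$fs
  hold_n <- round(cfg$hold * fs)
  fir_state <- if (is.null(state)) NULL else state$fir
  r <- ar_residuals(model, mat, fir_state, return_state = TRUE)
  exceeded <- abs(r$residuals) > matrix(model$residual_threshold,
                                        nrow(mat), ncol(mat), byrow = TRUE)
  raw <- rowSums(exceeded) > 0
  # hold: flag true if any raw flag within the past hold_n samples
  m <- moving_average_state(as.numeric(raw), hold_n + 1L,
                            if (is.null(state)) NULL else state$hold)
  flags <- m$y > 0
  list(flags = flags, raw_flags = raw, residuals = r$residuals,
       state = list(fir = r$state, hold = m$state))
}
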