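#' Fisher discriminability score
#'
#' `(mean_a - mean_b)^2 / (var_a + var_b)`, the one-dimensional Fisher
#' criterion used for band-power feature selection. Zero when both groups have
#' zero variance and equal means.
#'
#' @param x_a,x_b numeric samples of the two groups (>= 2 each).
#' @return non-negative score (may be `Inf` for separated zero-variance
#'   groups).
#' @export
fisher_score <- function(x_a, x_b) {
  if (length(x_a) < 2 || length(x_b) < 2)
    stop("fisher_score needs at least 2 samples per group")
  if (!all(is.finite(x_a)) || !all(is.finite(x_b)))
    stop("non-finite samples")
  num <- (mean(x_a) - mean(x_b))^2
  den <- var(x_a) + var(x_b)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Train a one-feature linear discriminant
#'
#' Closed-form Fisher LDA on a scalar feature with pooled within-class
#' variance (equal priors): `w = (mu_pos - mu_neg) / s2_pooled`,
#' `b = -w (mu_pos + mu_neg)/2`. The pooled variance is the
#' maximum-likelihood estimate (summed squared deviations over the total
#' count), which makes the model depend on the class statistics only:
#' duplicating every trial leaves it unchanged. The raw output `w x + b` is
#' positive on the positive-class side of the midpoint boundary.
#'
#' @param x per-trial scalar features.
#' @param labels class label per trial (exactly two classes).
#' @param positive label of the positive (movement-imagery) class.
#' @param var_floor lower bound on the pooled variance.
#' @return list: `w`, `b`, class means `mu` (named `neg`, `pos`), pooled
#'   variance `s2`.
#' @export
train_lda <- function(x, labels, positive, var_floor = 1e-12) {
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  m1 <- mean(x[pos]); m0 <- mean(x[!pos])
  n1 <- sum(pos); n0 <- sum(!pos)
  s2 <- (sum((x[pos] - m1)^2) + sum((x[!pos] - m0)^2)) / (n1 + n0)
  s2 <- max(s2, var_floor)
  w <- (m1 - m0) / s2
  b <- -w * (m1 + m0) / 2
  list(w = w, b = b, mu = c(neg = m0, pos = m1), s2 = s2)
}

# affine normalization mapping the raw outputs at the training class means to
# -1 (non-control) and +1 (movement imagery)
normalize_output <- function(lda) {
  y1 <- lda$w * lda$mu["pos"] + lda$b
  y0 <- lda$w * lda$mu["neg"] + lda$b
  if (abs(y1 - y0) < 1e-12) return(list(scale = 1, shift = 0, degenerate = TRUE))
  scale <- 2 / (y1 - y0)
  shift <- -(y1 + y0) / (y1 - y0)
  list(scale = unname(scale), shift = unname(shift), degenerate = FALSE)
}

#' Cross-validated training-window selection
#'
#' Splits the classification period into `n_windows` adjacent 0.5 s windows.
#' For each window, leave-one-out: an LDA is trained on the window-averaged
#' feature of the training folds and applied sample-wise over the whole
#' classification period of the held-out trial; averaging correctness over
#' folds gives one 4 s accuracy curve per window. The window whose curve has
#' the highest median accuracy is selected (ties broken toward the earliest
#' window).
#'
#' @param tracks list of per-trial feature tracks (matrices, full trial).
#' @param labels class label per trial.
#' @param col column index of the selected feature.
#' @param positive positive-class label.
#' @param cfg a [classifier_config()].
#' @param fs sampling rate in Hz.
#' @return list: `train_window` (0-based index), `curves`
#'   (n_windows x period samples), `medians`, `degenerate` flag (constant
#'   feature falls back to window 0 with a warning).
#' @export
loocv_window_select <- function(tracks, labels, col, positive,
                                cfg = classifier_config(), fs = 256) {
  labels <- as.character(labels)
  pos <- labels == positive
  n <- length(tracks)
  if (sum(pos) < cfg$min_loocv || sum(!pos) < cfg$min_loocv)
    stop("need at least ", cfg$min_loocv, " trials per class")
  pr <- period_rows(fs, cfg$period)
  X <- vapply(tracks, function(tr) as.matrix(tr)[pr, col], numeric(length(pr)))
  nw <- cfg$n_windows
  wlen <- length(pr) %/% nw
  Wm <- vapply(seq_len(n), function(i)
    colMeans(matrix(X[seq_len(wlen * nw), i], nrow = wlen)), numeric(nw))
  degenerate <- max(Wm) - min(Wm) < 1e-12
  S1 <- rowSums(Wm[, pos, drop = FALSE]); n1 <- sum(pos)
  S0 <- rowSums(Wm[, !pos, drop = FALSE]); n0 <- sum(!pos)
  curves <- matrix(0, nw, length(pr))
  for (w in seq_len(nw)) {
    acc <- numeric(length(pr))
    for (i in seq_len(n)) {
      if (pos[i]) { m1 <- (S1[w] - Wm[w, i]) / (n1 - 1); m0 <- S0[w] / n0 }
      else        { m1 <- S1[w] / n1; m0 <- (S0[w] - Wm[w, i]) / (n0 - 1) }
      o <- (m1 - m0) * (X[, i] - (m1 + m0) / 2)
      acc <- acc + ((o > 0) == pos[i])
    }
    curves[w, ] <- acc / n
  }
  medians <- apply(curves, 1, median)
  if (degenerate) {
    warning("degenerate (constant) feature; falling back to window 0")
    win <- 0L
  } else win <- which.max(medians) - 1L
  list(train_window = win, curves = curves, medians = medians,
       degenerate = degenerate)
}

# trial-averaged features over the classification period: trials x 6
trial_avg_features <- function(trials, cfg = classifier_config(), fs = 256) {
  pr <- period_rows(fs, cfg$period)
  t(vapply(trials, function(tr) colMeans(tr$features[pr, , drop = FALSE]),
           numeric(ncol(trials[[1]]$features))))
}

# full calibration pipeline for one MI class against non-control; returns
# NULL when outlier rejection leaves too few trials for cross-validation
# (the paradigm then simply keeps collecting)
calibrate_pair <- function(trials, mi_class, cfg, cfg_art, cfg_bp, fs = 256) {
  labs <- vapply(trials, `[[`, character(1), "label")
  sel <- labs %in% c(mi_class, cfg$nc_class)
  trials <- trials[sel]; labs <- labs[sel]
  favg <- trial_avg_features(trials, cfg, fs)
  keep <- reject_feature_outliers(favg, labs, cfg_art$outlier_k)
  trials <- trials[keep$kept]; labs <- labs[keep$kept]
  favg <- favg[keep$kept, , drop = FALSE]
  pos <- labs == mi_class
  if (sum(pos) < cfg$min_loocv || sum(!pos) < cfg$min_loocv) return(NULL)
  fid <- feature_ids(cfg_bp)
  fisher <- vapply(seq_len(ncol(favg)), function(k)
    fisher_score(favg[pos, k], favg[!pos, k]), numeric(1))
  names(fisher) <- fid$id
  col <- which.max(fisher)
  tracks <- lapply(trials, `[[`, "features")
  lw <- loocv_window_select(tracks, labs, col, mi_class, cfg, fs)
  wr <- period_rows(fs, cfg$period)
  wlen <- length(wr) %/% cfg$n_windows
  win_rows <- wr[(lw$train_window * wlen + 1):((lw$train_window + 1) * wlen)]
  xw <- vapply(trials, function(tr) mean(tr$features[win_rows, col]), numeric(1))
  lda <- train_lda(xw, labs, mi_class, cfg$var_floor)
  nrm <- normalize_output(lda)
  list(mi_class = mi_class,
       feature = list(derivation = fid$derivation[col], band = fid$band[col],
                      id = fid$id[col], col = col),
       train_window = lw$train_window, w = lda$w, b = lda$b,
       out_scale = nrm$scale, out_shift = nrm$shift,
       fisher = fisher, loocv = lw,
       median_acc = max(lw$medians),
       n_rejected = length(keep$rejected),
       n_per_class = c(mi = sum(pos), nc = sum(!pos)))
}

#' Auto-calibrate the BCI classifier
#'
#' The central fitting function. On initial calibration (no previous model;
#' requires `tpc_initial` artifact-free trials per class for all three
#' classes) the full pipeline — leave-one-out feature-outlier rejection,
#' Fisher-criterion selection of one of the six log band-power features over
#' the classification period, cross-validated training-window selection, LDA
#' training and output normalization to class means -1/+1 — is run for both
#' left-vs-non-control and right-vs-non-control, and the movement-imagery
#' class with the higher median cross-validated accuracy is selected (ties:
#' higher Fisher score of the selected feature, then right). On
#' re-calibration (a previous model exists and `tpc_recal` new artifact-free
#' trials per class are available for the two active classes) the pipeline is
#' re-run for the selected class on all accumulated clean trials. Every
#' calibration also fits the AR artifact-detection model on all artifact-free
#' trials.
#'
#' Calibration is deterministic given the store contents: two identical
#' stores yield identical models.
#'
#' @param store a [trial_store()].
#' @param prev_model previous `"bci_classifier"` or `NULL` for initial
#'   calibration.
#' @param cfg a [classifier_config()].
#' @param cfg_art an [artifact_config()].
#' @param cfg_bp a [bandpower_config()].
#' @param fs sampling rate in Hz.
#' @return a `"bci_classifier"` object, or a list with `status =
#'   "insufficient"` when the trial-count condition is not met (no-op).
#' @export
bci_calibrate <- function(store, prev_model = NULL,
                          cfg = classifier_config(),
                          cfg_art = artifact_config(),
                          cfg_bp = bandpower_config(), fs = 256) {
  counts <- clean_counts(store)
  if (is.null(prev_model)) {
    need <- c(cfg$nc_class, cfg$mi_classes)
    if (min(counts[need]) < cfg$tpc_initial)
      return(list(status = "insufficient", counts = counts))
    cands <- lapply(cfg$mi_classes, function(mi)
      calibrate_pair(store$trials, mi, cfg, cfg_art, cfg_bp, fs))
    if (any(vapply(cands, is.null, logical(1))))
      return(list(status = "insufficient", counts = counts,
                  reason = "too few trials after outlier rejection"))
    med <- vapply(cands, `[[`, numeric(1), "median_acc")
    fis <- vapply(cands, function(cd) unname(cd$fisher[cd$feature$col]), numeric(1))
    pick <- if (abs(diff(med)) > 1e-12) which.max(med)
            else if (abs(diff(fis)) > 1e-12) which.max(fis)
            else which(cfg$mi_classes == "right")
    chosen <- cands[[pick]]
    calib_count <- 1L
    alternatives <- data.frame(class = cfg$mi_classes, median_acc = med,
                               fisher = fis)
  } else {
    active <- c(prev_model$selected_class, cfg$nc_class)
    if (min(store$new_clean[active]) < cfg$tpc_recal)
      return(list(status = "insufficient", counts = counts,
                  new_clean = store$new_clean))
    chosen <- calibrate_pair(store$trials, prev_model$selected_class,
                             cfg, cfg_art, cfg_bp, fs)
    if (is.null(chosen))
      return(list(status = "insufficient", counts = counts,
                  reason = "too few trials after outlier rejection"))
    calib_count <- prev_model$calib_count + 1L
    alternatives <- prev_model$alternatives
  }
  ar <- fit_ar(lapply(store$trials, `[[`, "bipolar"), cfg_art, fs)
  structure(list(status = "calibrated",
                 selected_class = chosen$mi_class,
                 feature = chosen$feature,
                 train_window = chosen$train_window,
                 w = chosen$w, b = chosen$b,
                 out_scale = chosen$out_scale, out_shift = chosen$out_shift,
                 fisher = chosen$fisher, loocv = chosen$loocv,
                 median_acc = chosen$median_acc,
                 n_rejected = chosen$n_rejected,
                 n_per_class = chosen$n_per_class,
                 alternatives = alternatives,
                 ar = ar, calib_count = calib_count,
                 cfg = cfg, fs = fs),
            class = "bci_classifier")
}

#' Select the movement-imagery control class
#'
#' Runs the initial calibration and returns which MI class the system
#' selected for online control (higher median cross-validated accuracy
#' against non-control; ties broken by Fisher score, then right).
#'
#' @inheritParams bci_calibrate
#' @return `"left"` or `"right"`.
#' @export
select_control_class <- function(store, cfg = classifier_config(),
                                 cfg_art = artifact_config(),
                                 cfg_bp = bandpower_config(), fs = 256) {
  m <- bci_calibrate(store, NULL, cfg, cfg_art, cfg_bp, fs)
  if (!inherits(m, "bci_classifier"))
    stop("initial calibration condition not met")
  m$selected_class
}

# normalized discriminant outputs for a feature track (matrix or vector of
# the selected feature)
classifier_output <- function(model, feat) {
  if (is.matrix(feat)) {
    if (!is.null(colnames(feat))) {
      col <- match(model$feature$id, colnames(feat))
      if (is.na(col)) stop("feature ", model$feature$id, " missing from track")
    } else col <- model$feature$col
    feat <- feat[, col]
  }
  model$out_scale * (model$w * feat + model$b) + model$out_shift
}

#' Apply the calibrated classifier
#'
#' Produces the normalized discriminant output (approximately -1 for
#' non-control to +1 for movement imagery; the training-class means map to
#' exactly -1 and +1 before bias adaptation) and, for `type = "label"`, the
#' predicted class (`selected_class` when the output exceeds 0, otherwise
#' non-control).
#'
#' @param object a `"bci_classifier"`.
#' @param newdata feature track matrix (columns named by feature id) or a
#'   numeric vector of the selected feature.
#' @param type `"response"` for numeric outputs, `"label"` for class labels.
#' @param ... unused.
#' @return numeric vector or character vector per sample.
#' @export
predict.bci_classifier <- function(object, newdata,
                                   type = c("response", "label"), ...) {
  type <- match.arg(type)
  o <- classifier_output(object, newdata)
  if (type == "response") o
  else ifelse(o > 0, object$selected_class, object$cfg$nc_class)
}

#' Adapt the classifier bias on a non-control run
#'
#' Shifts the output bias so that the 90th percentile of the outputs over a
#' non-control run equals zero, i.e. the detector stays below the decision
#' boundary for 90 % of relaxed-state samples. Weights are unchanged;
#' adapting twice on the same run is idempotent.
#'
#' @param model a `"bci_classifier"`.
#' @param nc_track feature track (or numeric outputs' feature vector) of at
#'   least 30 s of non-control data.
#' @param min_seconds minimum run length in seconds.
#' @return the adapted model.
#' @export
adapt_bias <- function(model, nc_track, min_seconds = 30) {
  n <- if (is.matrix(nc_track)) nrow(nc_track) else length(nc_track)
  if (n < min_seconds * model$fs)
    stop("bias adaptation requires at least ", min_seconds, " s of non-control data")
  o <- classifier_output(model, nc_track)
  model$out_shift <- model$out_shift - quantile(o, 0.9, names = FALSE)
  model
}

#' @export
print.bci_classifier <- function(x, ...) {
  cat("<bci_classifier> calibration", x$calib_count, "\n")
  cat(sprintf("  class: %s vs %s | feature: %s | window: %d ([%.1f, %.1f) s)\n",
              x$selected_class, x$cfg$nc_class, x$feature$id, x$train_window,
              x$cfg$period[1] + 0.5 * x$train_window,
              x$cfg$period[1] + 0.5 * (x$train_window + 1)))
  cat(sprintf("  median LooCV accuracy: %.1f %% | trials: %d MI / %d NC (%d outliers rejected)\n",
              100 * x$median_acc, x$n_per_class["mi"], x$n_per_class["nc"],
              x$n_rejected))
  invisible(x)
}

#' @export
coef.bci_classifier <- function(object, ...) {
  c(weight = object$w, bias = object$b,
    out_scale = object$out_scale, out_shift = object$out_shift)
}

#' @export
summary.bci_classifier <- function(object, ...) {
  structure(list(model = object), class = "summary.bci_classifier")
}

#' @export
print.summary.bci_classifier <- function(x, ...) {
  m <- x$model
  print(m)
  cat("  Fisher scores:\n")
  print(round(m$fisher, 4))
  cat("  per-window median LooCV accuracy (%):\n")
  print(round(100 * m$loocv$medians, 1))
  if (!is.null(m$alternatives)) {
    cat("  class selection:\n")
    print(m$alternatives)
  }
  invisible(x)
}

#' Plot cross-validated accuracy curves of the calibration
#'
#' One 4 s accuracy curve per candidate training window; the selected window
#' is drawn in black.
#'
#' @param x a `"bci_classifier"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bci_classifier <- function(x, ...) {
  tt <- x$cfg$period[1] + seq_len(ncol(x$loocv$curves)) / x$fs
  matplot(tt, t(x$loocv$curves), type = "l", lty = 1, col = "grey70",
          xlab = "time in trial (s)", ylab = "LooCV accuracy",
          ylim = c(0, 1), ...)
  lines(tt, x$loocv$curves[x$train_window + 1, ], col = "black", lwd = 2)
  abline(h = 0.5, lty = 3)
  legend("bottomright", bty = "n",
         legend = sprintf("window %d selected", x$train_window))
  invisible(x)
}

#' Serialize a classifier model to JSON
#'
#' Stores everything the self-paced paradigm needs to reuse the last
#' co-adaptive model: feature id, training window, discriminant weights,
#' output normalization, and AR detector coefficients.
#'
#' @param model a `"bci_classifier"`.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  obj <- list(selected_class = model$selected_class,
              feature = model$feature[c("derivation", "band", "id", "col")],
              train_window = model$train_window,
              w = model$w, b = model$b,
              out_scale = model$out_scale, out_shift = model$out_shift,
              calib_count = model$calib_count,
              fs = model$fs,
              nc_class = model$cfg$nc_class,
              ar = list(order = model$ar$order,
                        coeffs = model$ar$coeffs,
                        residual_threshold = model$ar$residual_threshold,
                        channel_labels = model$ar$channel_labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier model from JSON
#'
#' @param path file written by [write_model_json()].
#' @param cfg a [classifier_config()] supplying the period/window layout.
#' @return a `"bci_classifier"` (without calibration diagnostics).
#' @export
read_model_json <- function(path, cfg = classifier_config()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ar <- structure(list(order = obj$ar$order,
                       coeffs = matrix(unlist(obj$ar$coeffs),
                                       nrow = obj$ar$order),
                       residual_threshold = obj$ar$residual_threshold,
                       channel_labels = obj$ar$channel_labels,
                       fs = obj$fs),
                  class = "ar_model")
  structure(list(status = "calibrated",
                 selected_class = obj$selected_class,
                 feature = as.list(obj$feature),
                 train_window = obj$train_window,
                 w = obj$w, b = obj$b,
                 out_scale = obj$out_scale, out_shift = obj$out_shift,
                 fisher = NULL, loocv = NULL, median_acc = NA_real_,
                 n_rejected = NA_integer_,
                 n_per_class = c(mi = NA_integer_, nc = NA_integer_),
                 alternatives = NULL,
                 ar = ar, calib_count = obj$calib_count,
                 cfg = cfg, fs = obj$fs),
            class = "bci_classifier")
}
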