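#' Classifier calibration configuration
#'
#' @param period classification period within a trial, seconds (half-open).
#' @param n_windows number of adjacent 0.5 s training windows the period is
#'   split into.
#' @param tpc_initial artifact-free trials per class required for the initial
#'   calibration (all three classes).
#' @param tpc_recal new artifact-free trials per class triggering a
#'   re-calibration (the two active classes).
#' @param var_floor variance floor for the pooled LDA variance.
#' @param min_loocv minimum trials per class for cross-validated window
#'   selection.
#' @param mi_classes the two movement-imagery class labels.
#' @param nc_class the non-control class label.
#' @return list of class `"classifier_config"`.
#' @export
classifier_config <- function(period = c(3, 7), n_windows = 8,
                              tpc_initial = 9, tpc_recal = 5,
                              var_floor = 1e-12, min_loocv = 5,
                              mi_classes = c("left", "right"),
                              nc_class = "nc") {
  structure(list(period = period, n_windows = n_windows,
                 tpc_initial = tpc_initial, tpc_recal = tpc_recal,
                 var_floor = var_floor, min_loocv = min_loocv,
                 mi_classes = mi_classes, nc_class = nc_class),
            class = "classifier_config")
}

period_rows <- function(fs, period = c(3, 7)) {
  (round(period[1] * fs) + 1L):round(period[2] * fs)
}

#' Build one labeled trial from a raw EEG epoch
#'
#' Runs the feature pipeline on a cue-aligned raw epoch and screens it against
#' the trial history ([screen_trial_stats()]).
#'
#' @param seg raw six-electrode [eeg_segment()] covering the trial (from
#'   second 0 of the trial).
#' @param label class label (`"left"`, `"right"`, `"nc"`).
#' @param cfg_bp a [bandpower_config()].
#' @param cfg_art an [artifact_config()].
#' @param history list of previous trials' bipolar epochs (matrices) for
#'   distribution-based screening.
#' @return list of class `"bci_trial"`: `label`, `t0`, `bipolar` (band-filtered
#'   bipolar matrix), `features` (samples x 6), `clean`, `reasons`.
#' @export
make_trial <- function(seg, label, cfg_bp = bandpower_config(),
                       cfg_art = artifact_config(), history = list()) {
  ex <- extract_features(seg, cfg_bp)
  v <- screen_trial_stats(ex$bipolar, history, cfg_art)
  structure(list(label = label, t0 = seg$t0, bipolar = ex$bipolar$data,
                 features = unclass(ex$features)[, , drop = FALSE],
                 clean = v$clean, reasons = v$reasons),
            class = "bci_trial")
}

#' Trial store for calibration bookkeeping
#'
#' Holds screened trials and the per-class counts of *new* artifact-free
#' trials since the last calibration (the calibration currency).
#'
#' @param classes class labels tracked by the store.
#' @return list of class `"trial_store"`.
#' @export
trial_store <- function(classes = c("nc", "left", "right")) {
  structure(list(trials = list(),
                 new_clean = stats::setNames(rep(0L, length(classes)), classes),
                 classes = classes),
            class = "trial_store")
}

#' Add a screened trial to the store
#'
#' Clean trials are admitted and counted toward the next (re-)calibration;
#' artifactual trials are recorded but not admitted.
#'
#' @param store a [trial_store()].
#' @param trial a `"bci_trial"` from [make_trial()].
#' @return the updated store.
#' @export
store_add <- function(store, trial) {
  stopifnot(inherits(store, "trial_store"), inherits(trial, "bci_trial"))
  if (!trial$label %in% store$classes)
    stop("unknown class label: ", trial$label)
  if (trial$clean) {
    store$trials[[length(store$trials) + 1L]] <- trial
    store$new_clean[trial$label] <- store$new_clean[trial$label] + 1L
  }
  store
}

#' Clean trial counts per class
#'
#' @param store a [trial_store()].
#' @return named integer vector of artifact-free trials per class.
#' @export
clean_counts <- function(store) {
  labs <- vapply(store$trials, `[[`, character(1), "label")
  out <- stats::setNames(integer(length(store$classes)), store$classes)
  tab <- table(labs)
  out[names(tab)] <- as.integer(tab)
  out
}

store_reset_counter <- function(store) {
  store$new_clean[] <- 0L
  store
}

store_subset <- function(store, classes) {
  labs <- vapply(store$trials, `[[`, character(1), "label")
  store$trials[labs %in% classes]
}
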