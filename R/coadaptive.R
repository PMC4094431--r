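#' Co-adaptive paradigm configuration
#'
#' Trial timing of the cue-guided paradigm: fixation cross at second 0, cue
#' at second 2, imagery until second 7, then a pause uniform in 2--3 s.
#' Positive-only feedback is shown between seconds 3.75 and 7; the reward
#' (smiley) requires more than 2 s of cumulative correct classification
#' between seconds 3 and 7.
#'
#' @param n_runs number of runs.
#' @param trials_per_run trials per run.
#' @param cross_t,cue_t,imagery_end trial landmarks in seconds.
#' @param pause pause range `c(min, max)` in seconds.
#' @param feedback_window feedback display window in seconds (half-open).
#' @param match_window window over which matched time is accumulated for the
#'   reward, seconds (half-open).
#' @param reward_time cumulative matched seconds required for the reward
#'   (strictly exceeded).
#' @param display_max feedback bar display maximum (normalized output units).
#' @return list of class `"coadaptive_config"`.
#' @export
coadaptive_config <- function(n_runs = 4, trials_per_run = 36,
                              cross_t = 0, cue_t = 2, imagery_end = 7,
                              pause = c(2, 3),
                              feedback_window = c(3.75, 7),
                              match_window = c(3, 7),
                              reward_time = 2, display_max = 1) {
  structure(list(n_runs = n_runs, trials_per_run = trials_per_run,
                 cross_t = cross_t, cue_t = cue_t, imagery_end = imagery_end,
                 pause = pause, feedback_window = feedback_window,
                 match_window = match_window, reward_time = reward_time,
                 display_max = display_max),
            class = "coadaptive_config")
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# permuted balanced blocks: each consecutive block of length(classes) trials
# contains every class exactly once
balanced_blocks <- function(classes, n) {
  k <- length(classes)
  out <- character(0)
  while (length(out) < n) out <- c(out, sample(classes))
  out[seq_len(n)]
}

#' Build the co-adaptive trial schedule
#'
#' 4 runs x 36 trials with per-trial pauses drawn uniformly from the pause
#' range and cue classes in permuted balanced three-class blocks (the plan
#' for the initial calibration phase; the running session switches to
#' balanced two-class blocks once calibrated). Reproducible from the seed.
#'
#' @param seed integer seed.
#' @param cfg a [coadaptive_config()].
#' @param cfg_cls a [classifier_config()] (class labels).
#' @return data.frame with one row per trial: `run`, `trial`, `t_start`
#'   (session seconds), `pause`, `duration`, `class` (initial-phase plan).
#' @export
make_schedule <- function(seed, cfg = coadaptive_config(),
                          cfg_cls = classifier_config()) {
  with_local_seed(seed, {
    n <- cfg$n_runs * cfg$trials_per_run
    pause <- runif(n, cfg$pause[1], cfg$pause[2])
    duration <- cfg$imagery_end + pause
    t_start <- cumsum(c(0, duration[-n]))
    cls <- balanced_blocks(c(cfg_cls$nc_class, cfg_cls$mi_classes), n)
    data.frame(run = rep(seq_len(cfg$n_runs), each = cfg$trials_per_run),
               trial = seq_len(n), t_start = t_start, pause = pause,
               duration = duration, class = cls)
  })
}

#' Positive-only feedback bar length
#'
#' Feedback is shown only inside the feedback window and only when the
#' predicted label matches the cued label; the bar extends in proportion to
#' the magnitude of the (normalized) discriminant output, clipped to the
#' display maximum. Everything else yields an empty bar.
#'
#' @param pred_label,true_label predicted and cued class labels.
#' @param output normalized classifier output.
#' @param t time within the trial, seconds.
#' @param cfg a [coadaptive_config()].
#' @return bar length in `[0, display_max]`.
#' @export
feedback_bar <- function(pred_label, true_label, output, t,
                         cfg = coadaptive_config()) {
  inside <- t >= cfg$feedback_window[1] & t < cfg$feedback_window[2]
  len <- ifelse(inside & pred_label == true_label,
                pmin(abs(output), cfg$display_max), 0)
  unname(len)
}

#' Reward (smiley) rule
#'
#' The reward fires when predicted and cued labels match for a cumulative
#' (not necessarily contiguous) total of more than `reward_time` seconds
#' within the match window.
#'
#' @param match logical per-sample match timeline over the match window.
#' @param fs sampling rate in Hz.
#' @param cfg a [coadaptive_config()].
#' @return logical flag.
#' @export
reward_rule <- function(match, fs = 256, cfg = coadaptive_config()) {
  sum(match) / fs > cfg$reward_time
}

log_event <- function(log, t, kind, label = NA_character_, value = NA_real_) {
  log[[length(log) + 1L]] <- data.frame(t = t, kind = kind, label = label,
                                        value = value)
  log
}

#' Run a full co-adaptive training session against a simulated user
#'
#' Executes the cue-guided state machine: presents cues (three balanced
#' classes before the first calibration, the selected MI class plus
#' non-control after), generates the user's EEG trial by trial, screens each
#' trial, auto-calibrates as soon as nine artifact-free trials per class are
#' available, selects the control class, re-calibrates after every five new
#' artifact-free trials per class, runs the AR artifact detector online,
#' and emits feedback/reward events. The event log replays deterministically
#' from `(seed, user params)`.
#'
#' @param user a [sim_user()].
#' @param seed integer seed.
#' @param cfg a [coadaptive_config()].
#' @param cfg_cls a [classifier_config()].
#' @param cfg_art an [artifact_config()].
#' @param cfg_bp a [bandpower_config()].
#' @return list: `log` (event data.frame), `model` (final
#'   `"bci_classifier"`), `trials` (per-trial data.frame), `outputs` (list of
#'   per-sample normalized outputs over the classification period, online
#'   feedback trials only), `schedule`, `store`,
#'   `first_calibration_t` (seconds).
#' @export
run_coadaptive_session <- function(user, seed,
                                   cfg = coadaptive_config(),
                                   cfg_cls = classifier_config(),
                                   cfg_art = artifact_config(),
                                   cfg_bp = bandpower_config()) {
  fs <- cfg_bp$fs
  sched <- make_schedule(seed, cfg, cfg_cls)
  set.seed(seed)
  store <- trial_store(c(cfg_cls$nc_class, cfg_cls$mi_classes))
  model <- NULL
  history <- list()
  log <- list()
  queue <- character(0)
  first_calib_t <- NA_real_
  pr <- period_rows(fs, cfg_cls$period)
  n_epoch <- round(cfg$imagery_end * fs)
  trial_rows <- list()
  outputs <- list()
  gen_state <- NULL
  for (i in seq_len(nrow(sched))) {
    t0 <- sched$t_start[i]
    online <- !is.null(model)
    if (!online) {
      label <- sched$class[i]
    } else {
      if (!length(queue))
        queue <- sample(c(cfg_cls$nc_class, model$selected_class))
      label <- queue[1]; queue <- queue[-1]
    }
    log <- log_event(log, t0 + cfg$cue_t, "cue", label)
    timeline <- data.frame(t = c(0, cfg$cue_t, cfg$imagery_end),
                           class = c("nc", label, "nc"))
    classes <- respond(user, timeline, n_epoch, fs)
    gen <- generate_eeg(user, classes, cfg_bp, gen_state, t0 = t0)
    gen_state <- gen$state
    inj <- inject_artifacts(gen$segment, user)
    trial <- make_trial(inj$segment, label, cfg_bp, cfg_art, history)
    history[[length(history) + 1L]] <- trial$bipolar
    # real-time AR artifact display (yellow dot events, 0.5 s hold)
    if (online) {
      det <- detect_artifact_online(trial$bipolar, model$ar, cfg_art)
      r <- rle(det$flags)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      on <- which(r$values)
      if (length(on))
        log[[length(log) + 1L]] <-
          data.frame(t = t0 + (starts[on] - 1) / fs, kind = "artifact_flag",
                     label = NA_character_,
                     value = (ends[on] - starts[on] + 1) / fs)
    }
    if (!trial$clean)
      log <- log_event(log, t0, "trial_artifact",
                       paste(trial$reasons, collapse = "+"))
    fed <- FALSE
    if (online && label %in% c(model$selected_class, cfg_cls$nc_class)) {
      fed <- TRUE
      o <- classifier_output(model, trial$features[pr, , drop = FALSE])
      pred <- ifelse(o > 0, model$selected_class, cfg_cls$nc_class)
      match <- pred == label
      tt <- cfg_cls$period[1] + seq_along(o) / fs
      bars <- feedback_bar(pred, label, o, tt, cfg)
      # log feedback decimated to 16 Hz to keep the event log compact
      dec <- seq(1, length(bars), by = fs / 16)
      log[[length(log) + 1L]] <-
        data.frame(t = t0 + tt[dec], kind = "feedback", label = pred[dec],
                   value = bars[dec])
      if (reward_rule(match, fs, cfg)) {
        log <- log_event(log, t0 + cfg$imagery_end, "reward", label)
      }
      outputs[[length(outputs) + 1L]] <-
        structure(o, label = label, trial = i, clean = trial$clean)
    }
    store <- store_add(store, trial)
    trial_rows[[i]] <- data.frame(trial = i, run = sched$run[i], t_start = t0,
                                  class = label, clean = trial$clean,
                                  phase = if (online) "online" else "initial",
                                  feedback = fed)
    # calibration scheduling
    m <- bci_calibrate(store, model, cfg_cls, cfg_art, cfg_bp, fs)
    if (inherits(m, "bci_classifier")) {
      t_cal <- t0 + sched$duration[i]
      if (is.null(model)) {
        first_calib_t <- t_cal
        log <- log_event(log, t_cal, "class_selection", m$selected_class)
        queue <- character(0)
      }
      log <- log_event(log, t_cal, "calibration", m$feature$id,
                       m$calib_count)
      model <- m
      store <- store_reset_counter(store)
    }
  }
  log <- do.call(rbind, log)
  log <- log[order(log$t), ]
  rownames(log) <- NULL
  list(log = log, model = model,
       trials = do.call(rbind, trial_rows), outputs = outputs,
       schedule = sched, store = store, first_calibration_t = first_calib_t)
}

#' Evaluate a co-adaptive session
#'
#' Computes the sample-wise accuracy curve and peak over the online-phase
#' feedback trials, the Youden index over the threshold-by-dwell grid, and
#' the chance-level threshold for the realized trial counts.
#'
#' @param session result of [run_coadaptive_session()].
#' @param alpha significance level for the chance threshold.
#' @return list: `peak_acc` (percent), `accuracy` (curve), `youden`,
#'   `chance` (percent), `n_per_class`, `significant`.
#' @export
evaluate_coadaptive <- function(session, alpha = 0.01) {
  if (!length(session$outputs)) stop("session has no online feedback trials")
  model <- session$model
  labels <- vapply(session$outputs, attr, character(1), "label")
  O <- do.call(rbind, lapply(session$outputs, as.numeric))
  pred <- ifelse(O > 0, model$selected_class, model$cfg$nc_class)
  fs <- model$fs
  tt <- model$cfg$period[1] + seq_len(ncol(O)) / fs
  acc <- samplewise_accuracy(pred, labels, tt)
  yj <- youden_index(O, labels, model$selected_class, fs = fs)
  tpc <- min(table(labels))
  chance <- chance_threshold(tpc, alpha)
  list(peak_acc = acc$peak, accuracy = acc, youden = yj, chance = chance,
       n_per_class = table(labels), significant = acc$peak > chance)
}
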