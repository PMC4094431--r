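#' Self-paced paradigm configuration
#'
#' Rotating-arrow brain-switch: six segments, 4 s of arrow travel per
#' segment, a static activation threshold of 0.5 on the normalized
#' classifier output, a 1 s dwell time per activation, and a 3 s refractory
#' stop after scored target segments. The first run (60 s of non-control)
#' only adapts the classifier bias; the two 420 s runs are scored.
#'
#' @param n_segments menu segments in the circular arrangement.
#' @param seconds_per_segment arrow travel time over one segment.
#' @param activation_threshold static threshold on the normalized output.
#' @param dwell uninterrupted above-threshold seconds per activation.
#' @param refractory pause after a scored target segment, seconds.
#' @param run_lengths run lengths in seconds (bias-adaptation run first).
#' @param target_offsets clockwise offsets (segments) the next target is
#'   drawn from, uniformly.
#' @param sham_mean,sham_sd,sham_max sham feedback distribution for
#'   non-target segments: Gaussian arrow lengths clipped below the
#'   threshold.
#' @return list of class `"selfpaced_config"`.
#' @export
selfpaced_config <- function(n_segments = 6, seconds_per_segment = 4,
                             activation_threshold = 0.5, dwell = 1,
                             refractory = 3, run_lengths = c(60, 420, 420),
                             target_offsets = 2:5,
                             sham_mean = 0.25, sham_sd = 0.08,
                             sham_max = 0.45) {
  if (activation_threshold <= 0 || activation_threshold >= 1)
    stop("activation threshold must lie in (0, 1)")
  if (any(c(n_segments, seconds_per_segment, dwell, refractory,
            run_lengths) <= 0))
    stop("all durations must be positive")
  structure(list(n_segments = n_segments,
                 seconds_per_segment = seconds_per_segment,
                 activation_threshold = activation_threshold, dwell = dwell,
                 refractory = refractory, run_lengths = run_lengths,
                 target_offsets = target_offsets, sham_mean = sham_mean,
                 sham_sd = sham_sd, sham_max = sham_max),
            class = "selfpaced_config")
}

#' Draw the next target segment
#'
#' The next target lies uniformly two to five segments clockwise after the
#' last target (or the arrow position at run start). Uses the current RNG
#' state, so it is reproducible under [set.seed()].
#'
#' @param current current (0-based) segment index of the last target or
#'   arrow position.
#' @param cfg a [selfpaced_config()].
#' @return 0-based target segment index.
#' @export
next_target <- function(current, cfg = selfpaced_config()) {
  offset <- cfg$target_offsets[sample.int(length(cfg$target_offsets), 1)]
  (current + offset) %% cfg$n_segments
}

#' Displayed arrow length and state for one sample
#'
#' In target segments the arrow shows the real output (proportional to the
#' positive part of the normalized classifier output) and turns red above
#' the activation threshold. In non-target segments sham feedback is shown:
#' Gaussian lengths around a sub-threshold mean, clipped so the displayed
#' arrow never reaches the activation state regardless of the user's actual
#' output (false positives are logged but never displayed).
#'
#' @param output normalized classifier output (vectorized).
#' @param is_target logical: is the arrow pointing at the target segment.
#' @param cfg a [selfpaced_config()].
#' @return data.frame with `length` and `state`
#'   (`"red"`/`"blue"`/`"sham"`).
#' @export
step_ui <- function(output, is_target, cfg = selfpaced_config()) {
  n <- length(output)
  if (is_target) {
    len <- pmin(pmax(output, 0), 1)
    state <- ifelse(len > cfg$activation_threshold, "red", "blue")
  } else {
    len <- pmin(pmax(rnorm(n, cfg$sham_mean, cfg$sham_sd), 0), cfg$sham_max)
    state <- rep("sham", n)
  }
  data.frame(length = len, state = state)
}

#' Detect dwell-time activations in an output stream
#'
#' One activation per completed uninterrupted dwell period above the
#' threshold; a single long span yields consecutive activations (a full 4 s
#' span at 1 s dwell gives 4), so `floor(span / dwell)` events per span. The
#' dwell clock resets at the start of the stream (segment boundary).
#'
#' @param outputs normalized classifier outputs at `fs` Hz.
#' @param cfg a [selfpaced_config()].
#' @param fs sampling rate in Hz.
#' @return list: `count`, `times` (seconds of each completed dwell period,
#'   relative to stream start).
#' @export
detect_activation <- function(outputs, cfg = selfpaced_config(), fs = 256) {
  dn <- round(cfg$dwell * fs)
  r <- rle(outputs > cfg$activation_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  times <- numeric(0)
  for (j in which(r$values)) {
    k <- r$lengths[j] %/% dn
    if (k > 0) times <- c(times, (starts[j] - 1L + dn * seq_len(k)) / fs)
  }
  list(count = length(times), times = times)
}

#' Score one segment
#'
#' Target segments: every activation is a true positive and scores one point
#' (at most four within a segment); a target without activation is one false
#' negative. Non-target segments: activations are false positives (never
#' displayed); none means one true negative.
#'
#' @param n_activations activation count in the segment.
#' @param is_target logical.
#' @return one-row data.frame: `is_target`, `activations`, `points`, `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
score_segment <- function(n_activations, is_target) {
  if (is_target) {
    data.frame(is_target = TRUE, activations = n_activations,
               points = min(n_activations, 4L),
               TP = n_activations, FP = 0L, TN = 0L,
               FN = as.integer(n_activations == 0))
  } else {
    data.frame(is_target = FALSE, activations = n_activations, points = 0L,
               TP = 0L, FP = n_activations,
               TN = as.integer(n_activations == 0), FN = 0L)
  }
}

# streaming feature extraction closure carrying preprocessing and band-power
# filter state across blocks
feature_stream <- function(cfg_bp = bandpower_config()) {
  pre_state <- NULL
  bp_state <- NULL
  function(seg) {
    pp <- preprocess(seg, pre_state)
    pre_state <<- attr(pp, "filter_state")
    bip <- bipolar_derive(pp, cfg_bp)
    tr <- log_bandpower(bip, cfg_bp, bp_state)
    bp_state <<- attr(tr, "filter_state")
    tr
  }
}

#' Run a self-paced training session against a simulated user
#'
#' Run 1 (60 s, non-control) adapts the classifier bias
#' ([adapt_bias()]); the remaining runs execute the rotating-arrow state
#' machine: the arrow advances one segment every 4 s, targets are scheduled
#' 2--5 segments clockwise after the last, the user (simulated) performs the
#' trained movement imagery in target segments and relaxes otherwise, real
#' feedback is displayed in target segments and sham feedback elsewhere,
#' dwell-time activations are detected on the true outputs everywhere, and a
#' 3 s refractory stop follows every scored target segment. The first second
#' of each run is pipeline warm-up and precedes the first segment.
#'
#' @param user a [sim_user()].
#' @param model the last co-adaptive `"bci_classifier"`.
#' @param seed integer seed.
#' @param cfg a [selfpaced_config()].
#' @param cfg_bp a [bandpower_config()].
#' @return list: `segments` (data.frame of segment records), `log` (event
#'   data.frame), `model` (bias-adapted), `counts` (confusion counts),
#'   `balanced_acc` (percent), `n_target`.
#' @export
run_selfpaced_session <- function(user, model, seed,
                                  cfg = selfpaced_config(),
                                  cfg_bp = bandpower_config()) {
  if (is.null(model) || !inherits(model, "bci_classifier"))
    stop("a calibrated classifier model is required")
  fs <- cfg_bp$fs
  set.seed(seed)
  log <- list()
  seg_len <- round(cfg$seconds_per_segment * fs)
  # --- run 1: bias adaptation on non-control data --------------------------
  fsreader <- feature_stream(cfg_bp)
  n1 <- round(cfg$run_lengths[1] * fs)
  gen <- generate_eeg(user, rep("nc", n1), cfg_bp)
  inj <- inject_artifacts(gen$segment, user)
  track <- fsreader(inj$segment)
  warm <- attr(track, "warmup_samples")
  old_shift <- model$out_shift
  model <- adapt_bias(model, unclass(track)[-seq_len(warm), , drop = FALSE])
  log <- log_event(log, cfg$run_lengths[1], "bias_adaptation",
                   value = model$out_shift - old_shift)
  # --- scored runs ----------------------------------------------------------
  segrecs <- list()
  t_session <- cfg$run_lengths[1]
  for (run in seq_along(cfg$run_lengths)[-1]) {
    run_len <- cfg$run_lengths[run]
    fsreader <- feature_stream(cfg_bp)
    gen_state <- NULL
    # 1 s warm-up lead-in before the first segment
    gen <- generate_eeg(user, rep("nc", fs), cfg_bp, gen_state)
    gen_state <- gen$state
    fsreader(gen$segment)
    t <- 1
    arrow <- 0L
    target <- next_target(arrow, cfg)
    idx <- 0L
    while (t + cfg$seconds_per_segment <= run_len) {
      idx <- idx + 1L
      is_target <- arrow == target
      timeline <- if (is_target)
        data.frame(t = c(0, 0.0001), class = c("nc", model$selected_class))
      else data.frame(t = 0, class = "nc")
      classes <- respond(user, timeline, seg_len, fs)
      gen <- generate_eeg(user, classes, cfg_bp, gen_state)
      gen_state <- gen$state
      inj <- inject_artifacts(gen$segment, user)
      track <- fsreader(inj$segment)
      o <- classifier_output(model, unclass(track))
      act <- detect_activation(o, cfg, fs)
      ui <- step_ui(o, is_target, cfg)
      rec <- score_segment(act$count, is_target)
      rec <- cbind(data.frame(run = run, segment = idx, arrow = arrow,
                              t_start = t_session + t), rec,
                   data.frame(max_display = max(ui$length)))
      segrecs[[length(segrecs) + 1L]] <- rec
      log <- log_event(log, t_session + t,
                       if (is_target) "target_segment" else "segment",
                       value = act$count)
      t <- t + cfg$seconds_per_segment
      if (is_target) {
        if (rec$points >= 1) {
          log <- log_event(log, t_session + t, "score", value = rec$points)
          # refractory stop: arrow halted, user relaxes, time excluded
          nref <- round(cfg$refractory * fs)
          gen <- generate_eeg(user, rep("nc", nref), cfg_bp, gen_state)
          gen_state <- gen$state
          fsreader(gen$segment)
          t <- t + cfg$refractory
        }
        target <- next_target(target, cfg)
      }
      arrow <- (arrow + 1L) %% cfg$n_segments
    }
    t_session <- t_session + run_len
  }
  segments <- do.call(rbind, segrecs)
  rownames(segments) <- NULL
  counts <- confusion_counts(segments)
  log <- do.call(rbind, log)
  log <- log[order(log$t), ]
  rownames(log) <- NULL
  list(segments = segments, log = log, model = model,
       counts = counts,
       balanced_acc = balanced_accuracy(counts),
       n_target = sum(segments$is_target))
}
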