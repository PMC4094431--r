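#' Simulated BCI user
#'
#' Seeded generative model of a participant's six-electrode sensorimotor EEG:
#' 1/f-colored background noise plus a white floor per electrode, band-limited
#' mu and beta rhythms (amplitude-modulated narrowband Gaussian noise) on the
#' anterior electrode of each bipolar pair, class-conditional ERD (fractional
#' band-power attenuation with contralateral mapping: right-hand MI attenuates
#' C3, left-hand MI attenuates C4), a motor-imagery onset latency, and
#' Poisson-timed broadband transient artifacts.
#'
#' Presets: `"strong"` (deep contralateral mu/beta ERD, no artifacts),
#' `"weak"` (shallow ERD, occasional artifacts), `"null"` (no ERD),
#' `"artifacty"` (shallow ERD, frequent large artifacts).
#'
#' @param preset one of `"strong"`, `"weak"`, `"null"`, `"artifacty"`, or
#'   `NULL` to use the explicit arguments.
#' @param erd_depth named list per MI class of named fractional power
#'   attenuations in `[0, 1)` keyed by feature id (e.g.
#'   `list(right = c("C3-mu" = 0.5))`). Unspecified entries are 0.
#' @param rhythm_amp named RMS amplitudes (microvolts) of the baseline
#'   rhythms per feature id.
#' @param pink_sd,white_sd background-noise RMS per electrode (microvolts):
#'   1/f component and white floor (the floor keeps AR fitting well-posed).
#' @param latency response latency in seconds between an instruction change
#'   and the corresponding change in the user's mental state.
#' @param artifact_rate transient artifacts per minute.
#' @param artifact_amp artifact peak amplitude in microvolts.
#' @return list of class `"sim_user"`.
#' @export
sim_user <- function(preset = NULL,
                     erd_depth = list(),
                     rhythm_amp = c("C3-mu" = 10, "Cz-mu" = 10, "C4-mu" = 10,
                                    "C3-beta" = 8, "Cz-beta" = 8, "C4-beta" = 8),
                     pink_sd = 8, white_sd = 2, latency = 0.5,
                     artifact_rate = 0, artifact_amp = 500) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strong", "weak", "null", "artifacty"))
    erd_depth <- switch(preset,
      strong = list(right = c("C3-mu" = 0.5, "C3-beta" = 0.3),
                    left  = c("C4-mu" = 0.3)),
      weak = list(right = c("C3-mu" = 0.2), left = c("C4-mu" = 0.1)),
      null = list(),
      artifacty = list(right = c("C3-mu" = 0.2), left = c("C4-mu" = 0.1)))
    artifact_rate <- switch(preset, strong = 0, weak = 1, null = 0,
                            artifacty = 6)
  }
  for (cl in names(erd_depth)) {
    d <- erd_depth[[cl]]
    if (any(d < 0 | d >= 1)) stop("ERD depths must lie in [0, 1)")
  }
  if (any(rhythm_amp <= 0)) stop("rhythm amplitudes must be positive")
  structure(list(erd_depth = erd_depth, rhythm_amp = rhythm_amp,
                 pink_sd = pink_sd, white_sd = white_sd, latency = latency,
                 artifact_rate = artifact_rate, artifact_amp = artifact_amp,
                 preset = preset),
            class = "sim_user")
}

# classic 3-pole/3-zero "pinking" IIR approximating a 1/f amplitude spectrum
pinking_filter <- function() {
  new_iir(c(0.049922035, -0.095993537, 0.050612699, -0.004408786),
          c(1, -2.494956002, 2.017265875, -0.522189400))
}

# generator filter states + unit-RMS scale factors (deterministic, no draws)
user_state <- function(params, cfg_bp = bandpower_config()) {
  elec <- unique(unlist(cfg_bp$derivations))
  pf <- pinking_filter()
  pink_scale <- 1 / sqrt(filter_noise_gain(pf))
  fid <- feature_ids(cfg_bp)
  band_filters <- lapply(seq_len(nrow(fid)), function(k) {
    b <- cfg_bp$bands[[fid$band[k]]]
    design_bandpass(b[1], b[2], cfg_bp$fs, order = 2)
  })
  band_scale <- vapply(band_filters, function(f) 1 / sqrt(filter_noise_gain(f)),
                       numeric(1))
  # depth lookup: classes x features, power attenuation
  classes <- c("nc", names(params$erd_depth))
  depth <- matrix(0, length(classes), nrow(fid),
                  dimnames = list(classes, fid$id))
  for (cl in names(params$erd_depth)) {
    d <- params$erd_depth[[cl]]
    bad <- setdiff(names(d), fid$id)
    if (length(bad)) stop("unknown feature id(s): ", paste(bad, collapse = ", "))
    depth[cl, names(d)] <- d
  }
  list(pink = stats::setNames(replicate(length(elec), pinking_filter(),
                                        simplify = FALSE), elec),
       pink_scale = pink_scale,
       band = band_filters, band_scale = band_scale,
       depth = depth, elec = elec, fid = fid)
}

#' Generate synthetic EEG for a per-sample class timeline
#'
#' @param params a [sim_user()].
#' @param classes character vector: the user's mental class at every sample
#'   (`"nc"`, `"left"`, `"right"`); apply [respond()] first to account for
#'   response latency.
#' @param cfg_bp a [bandpower_config()].
#' @param state carried generator state from a previous block (for streaming
#'   continuity), or `NULL`.
#' @param t0 segment start time in seconds.
#' @return list: `segment` (six-electrode [eeg_segment()]), `state`.
#' @export
generate_eeg <- function(params, classes, cfg_bp = bandpower_config(),
                         state = NULL, t0 = 0) {
  if (is.null(state)) state <- user_state(params, cfg_bp)
  n <- length(classes)
  known <- c("nc", "left", "right")
  if (!all(classes %in% known))
    stop("unknown class label(s): ",
         paste(setdiff(unique(classes), known), collapse = ", "))
  cls_row <- match(classes, rownames(state$depth))
  cls_row[is.na(cls_row)] <- 1L  # classes with no ERD entry behave as baseline
  X <- matrix(0, n, length(state$elec), dimnames = list(NULL, state$elec))
  for (e in state$elec) {
    r <- iir_apply(state$pink[[e]], rnorm(n))
    state$pink[[e]] <- r$f
    X[, e] <- r$y * state$pink_scale * params$pink_sd + rnorm(n) * params$white_sd
  }
  for (k in seq_len(nrow(state$fid))) {
    r <- iir_apply(state$band[[k]], rnorm(n))
    state$band[[k]] <- r$f
    env <- sqrt(1 - state$depth[cls_row, k])
    amp <- params$rhythm_amp[state$fid$id[k]]
    anterior <- cfg_bp$derivations[[state$fid$derivation[k]]][1]
    X[, anterior] <- X[, anterior] + amp * state$band_scale[k] * r$y * env
  }
  list(segment = eeg_segment(X, cfg_bp$fs, state$elec, t0), state = state)
}

#' Inject transient artifacts
#'
#' Adds Poisson-timed broadband transients (raised-cosine pulses of 0.2--0.5 s
#' at `artifact_amp` microvolts) on random electrodes, and returns the
#' ground-truth event list for detector evaluation.
#'
#' @param seg an [eeg_segment()].
#' @param params a [sim_user()].
#' @return list: `segment` (with artifacts added), `events` (data.frame with
#'   `t_on`, `duration`, `channel`, `amplitude`; times relative to segment
#'   start).
#' @export
inject_artifacts <- function(seg, params) {
  n <- nrow(seg$data); fs <- seg$fs
  dur_s <- n / fs
  n_ev <- if (params$artifact_rate > 0)
    rpois(1, params$artifact_rate * dur_s / 60) else 0L
  events <- data.frame(t_on = numeric(0), duration = numeric(0),
                       channel = character(0), amplitude = numeric(0))
  if (n_ev > 0) {
    for (i in seq_len(n_ev)) {
      d <- runif(1, 0.2, 0.5)
      on <- runif(1, 0, max(dur_s - d, 0))
      ch <- sample(seg$channel_labels, 1)
      i0 <- round(on * fs) + 1L
      len <- max(round(d * fs), 2L)
      idx <- i0:min(i0 + len - 1L, n)
      pulse <- params$artifact_amp *
        0.5 * (1 - cos(2 * pi * seq_along(idx) / len))
      seg$data[idx, ch] <- seg$data[idx, ch] + pulse
      events <- rbind(events, data.frame(t_on = on, duration = d,
                                         channel = ch,
                                         amplitude = params$artifact_amp))
    }
  }
  list(segment = seg, events = events)
}

#' Per-sample mental class from an instruction timeline
#'
#' Converts a step-function instruction timeline into the user's per-sample
#' mental class, delaying every transition after time zero by the user's
#' response latency (reaction time).
#'
#' @param params a [sim_user()].
#' @param timeline data.frame with columns `t` (seconds, first row must be 0)
#'   and `class`; each row's class holds from its `t` until the next row.
#' @param n number of samples to produce.
#' @param fs sampling rate in Hz.
#' @return character vector of length `n`.
#' @export
respond <- function(params, timeline, n, fs = 256) {
  stopifnot(nrow(timeline) >= 1, timeline$t[1] == 0)
  out <- rep(timeline$class[1], n)
  if (nrow(timeline) > 1) {
    for (r in 2:nrow(timeline)) {
      i0 <- round((timeline$t[r] + params$latency) * fs) + 1L
      if (i0 <= n) out[i0:n] <- timeline$class[r]
    }
  }
  out
}
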