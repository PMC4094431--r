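# shared fixture builders (all fixtures are generated in code)

montage6 <- c("FC3", "CP3", "FCz", "CPz", "FC4", "CP4")

sine_segment <- function(freq, amp, seconds = 5, fs = 256,
                         labels = c("C3", "Cz", "C4")) {
  t <- seq_len(seconds * fs) / fs
  eeg_segment(matrix(amp * sin(2 * pi * freq * t), length(t), length(labels)),
              fs, labels)
}

# round-robin cue presentation: returns a filled trial_store plus history
sim_trial_store <- function(user, n_per_class, seed,
                            classes = c("nc", "left", "right"),
                            cfg_bp = bandpower_config(),
                            cfg_art = artifact_config()) {
  set.seed(seed)
  fs <- cfg_bp$fs
  store <- trial_store(classes)
  history <- list()
  gen_state <- NULL
  for (i in seq_len(n_per_class * length(classes))) {
    label <- classes[(i - 1) %% length(classes) + 1]
    tl <- data.frame(t = c(0, 2, 7), class = c("nc", label, "nc"))
    cl <- respond(user, tl, 7 * fs, fs)
    gen <- generate_eeg(user, cl, cfg_bp, gen_state)
    gen_state <- gen$state
    inj <- inject_artifacts(gen$segment, user)
    trial <- make_trial(inj$segment, label, cfg_bp, cfg_art, history)
    history[[length(history) + 1]] <- trial$bipolar
    store <- store_add(store, trial)
  }
  store
}

# cheap calibrated model without a full closed-loop session
calibrated_model <- function(user = sim_user("strong"), seed = 101,
                             n_per_class = 12) {
  store <- sim_trial_store(user, n_per_class, seed)
  m <- bci_calibrate(store)
  stopifnot(inherits(m, "bci_classifier"))
  m
}

# synthetic feature tracks with a class offset planted in chosen sample rows
planted_tracks <- function(n_per_class, rows_offset, offset = 3, fs = 256,
                           n_features = 6, col = 1, noise = 1, seed = 1) {
  set.seed(seed)
  n_rows <- 7 * fs
  labels <- rep(c("mi", "nc"), each = n_per_class)
  tracks <- lapply(labels, function(lb) {
    m <- matrix(rnorm(n_rows * n_features, sd = noise), n_rows, n_features)
    if (lb == "mi") m[rows_offset, col] <- m[rows_offset, col] + offset
    colnames(m) <- feature_ids()$id
    m
  })
  list(tracks = tracks, labels = labels)
}
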