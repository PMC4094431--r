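pad_str <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

num8 <- function(x) pad_str(formatC(x, format = "g", digits = 7), 8)

#' Write an EEG segment to an EDF file
#'
#' Minimal EDF (continuous recording) writer: ASCII header plus 16-bit
#' little-endian data records with per-channel physical scaling. The last
#' record is zero-padded to a whole record. Amplitudes round-trip within the
#' 16-bit quantization of the physical range.
#'
#' @param seg an [eeg_segment()] (microvolts).
#' @param path output file.
#' @param record_seconds data-record duration (must give an integer number
#'   of samples).
#' @export
write_edf <- function(seg, path, record_seconds = 1) {
  stopifnot(inherits(seg, "eeg_segment"))
  spr <- seg$fs * record_seconds
  if (spr != round(spr)) stop("record duration must give integer samples")
  spr <- as.integer(spr)
  ns <- ncol(seg$data)
  n <- nrow(seg$data)
  ndr <- as.integer(ceiling(n / spr))
  x <- rbind(seg$data, matrix(0, ndr * spr - n, ns))
  pm <- max(ceiling(max(abs(x))), 1)
  dmin <- -32768L; dmax <- 32767L
  dig <- round((x + pm) / (2 * pm) * (dmax - dmin) + dmin)
  dig[] <- pmin(pmax(dig, dmin), dmax)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad_str("0", 8)); wr(pad_str("X", 80)); wr(pad_str("Startdate X", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(pad_str(256 + ns * 256, 8)); wr(pad_str("", 44))
  wr(pad_str(ndr, 8)); wr(num8(record_seconds)); wr(pad_str(ns, 4))
  for (lab in seg$channel_labels) wr(pad_str(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(pad_str("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(pad_str("uV", 8))
  for (i in seq_len(ns)) wr(num8(-pm))
  for (i in seq_len(ns)) wr(num8(pm))
  for (i in seq_len(ns)) wr(pad_str(dmin, 8))
  for (i in seq_len(ns)) wr(pad_str(dmax, 8))
  for (i in seq_len(ns)) wr(pad_str("HP:0.5Hz LP:100Hz N:50Hz", 80))
  for (i in seq_len(ns)) wr(pad_str(spr, 8))
  for (i in seq_len(ns)) wr(pad_str("", 32))
  for (r in seq_len(ndr)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns))
      writeBin(as.integer(dig[rows, ch]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG segment
#'
#' Reads continuous-recording EDF files (as produced by [write_edf()]);
#' channel labels of the form `"EEG <name>"` are shortened to the 10/20
#' name. Amplitudes are rescaled to physical units (microvolts).
#'
#' @param path EDF file.
#' @return an [eeg_segment()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w) stop("malformed EDF: truncated header at byte ",
                              seek(con))
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  ndr <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count")
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  labs <- sub("^EEG ", "", labs)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(NA_real_, ndr * spr[1], ns)
  for (r in seq_len(ndr)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      if (length(d) < spr[ch]) stop("malformed EDF: truncated record ", r)
      phys <- (d - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
      out[((r - 1) * spr[1] + 1):(r * spr[1]), ch] <- phys
    }
  }
  eeg_segment(out, fs, labs, t0 = 0)
}

session_log_cols <- c("t", "kind", "label", "value")

#' Write a session event log
#'
#' CSV (times as 6-decimal fixed point seconds) or JSON, with the stable
#' column order `t, kind, label, value`.
#'
#' @param log event data.frame (as produced by the session runners).
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @export
write_session_log <- function(log, path) {
  log <- log[, session_log_cols]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(log, path, auto_unbox = FALSE, digits = NA,
                         na = "null")
  } else {
    log$t <- sprintf("%.6f", log$t)
    write.csv(log, path, row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(path)
}

#' Read a session event log
#'
#' @param path file written by [write_session_log()].
#' @return event data.frame with columns `t, kind, label, value`.
#' @export
read_session_log <- function(path) {
  log <- if (grepl("\\.json$", path))
    jsonlite::fromJSON(path)
  else read.csv(path, colClasses = c(t = "character", kind = "character",
                                     label = "character", value = "numeric"))
  unknown <- setdiff(names(log), session_log_cols)
  if (length(unknown))
    stop("unknown session-log column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(session_log_cols, names(log))
  if (length(missing))
    stop("missing session-log column(s): ", paste(missing, collapse = ", "))
  log$t <- as.numeric(log$t)
  log[, session_log_cols]
}

#' Experiment configuration
#'
#' Bundles all sub-configurations, the seed and the simulated-user preset of
#' one reproducible experiment; round-trips losslessly through YAML or JSON
#' ([write_config()] / [read_config()]).
#'
#' @param seed integer seed.
#' @param preset simulated-user preset name (see [sim_user()]).
#' @param out_dir output directory for the CLI.
#' @param bandpower,artifact,classifier,coadaptive,selfpaced
#'   sub-configurations.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(seed = 1, preset = "strong", out_dir = ".",
                              bandpower = bandpower_config(),
                              artifact = artifact_config(),
                              classifier = classifier_config(),
                              coadaptive = coadaptive_config(),
                              selfpaced = selfpaced_config()) {
  structure(list(seed = seed, preset = preset, out_dir = out_dir,
                 bandpower = bandpower, artifact = artifact,
                 classifier = classifier, coadaptive = coadaptive,
                 selfpaced = selfpaced),
            class = "experiment_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Write an experiment configuration
#'
#' @param cfg an [experiment_config()].
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @export
write_config <- function(cfg, path) {
  obj <- strip_classes(cfg)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an experiment configuration
#'
#' @param path file written by [write_config()].
#' @return an [experiment_config()].
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_num <- function(x) if (is.list(x)) unlist(x) else x
  bp <- obj$bandpower
  experiment_config(
    seed = obj$seed, preset = obj$preset, out_dir = obj$out_dir,
    bandpower = bandpower_config(bands = lapply(bp$bands, as_num),
                                 avg_window = bp$avg_window,
                                 derivations = lapply(bp$derivations, as_num),
                                 fs = bp$fs),
    artifact = do.call(artifact_config, obj$artifact),
    classifier = {
      cl <- obj$classifier
      classifier_config(period = as_num(cl$period), n_windows = cl$n_windows,
                        tpc_initial = cl$tpc_initial,
                        tpc_recal = cl$tpc_recal, var_floor = cl$var_floor,
                        min_loocv = cl$min_loocv,
                        mi_classes = as_num(cl$mi_classes),
                        nc_class = cl$nc_class)
    },
    coadaptive = {
      co <- obj$coadaptive
      coadaptive_config(n_runs = co$n_runs,
                        trials_per_run = co$trials_per_run,
                        cross_t = co$cross_t, cue_t = co$cue_t,
                        imagery_end = co$imagery_end, pause = as_num(co$pause),
                        feedback_window = as_num(co$feedback_window),
                        match_window = as_num(co$match_window),
                        reward_time = co$reward_time,
                        display_max = co$display_max)
    },
    selfpaced = {
      sp <- obj$selfpaced
      selfpaced_config(n_segments = sp$n_segments,
                       seconds_per_segment = sp$seconds_per_segment,
                       activation_threshold = sp$activation_threshold,
                       dwell = sp$dwell, refractory = sp$refractory,
                       run_lengths = as_num(sp$run_lengths),
                       target_offsets = as_num(sp$target_offsets),
                       sham_mean = sp$sham_mean, sham_sd = sp$sham_sd,
                       sham_max = sp$sham_max)
    })
}
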