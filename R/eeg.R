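#' Multichannel EEG segment
#'
#' Fixed-rate block of EEG samples with 10/20 channel labels and a start time
#' relative to session start. Amplitudes are in microvolts.
#'
#' @param data numeric matrix, samples x channels (microvolts).
#' @param fs sampling rate in Hz (the pipeline operates at 256 Hz).
#' @param channel_labels character vector of unique 10/20 electrode names,
#'   one per column of `data`.
#' @param t0 start time in seconds since session start.
#' @return An object of class `"eeg_segment"`.
#' @export
eeg_segment <- function(data, fs = 256, channel_labels, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("EEG data must be numeric")
  if (fs <= 0) stop("fs must be positive")
  if (length(channel_labels) != ncol(data))
    stop("need one channel label per column")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  colnames(data) <- channel_labels
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels), t0 = t0),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d samples x %d channels @ %g Hz (%.2f s), t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs, x$t0))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Band-power feature configuration
#'
#' Defines the two analysis bands (mu 9--13 Hz, beta 16--26 Hz), the causal
#' averaging window for band power, and the three bipolar derivations
#' (anterior minus posterior electrode) over the sensorimotor strip. The six
#' features are ordered C3-mu, Cz-mu, C4-mu, C3-beta, Cz-beta, C4-beta.
#'
#' @param bands named list of `c(low, high)` band edges in Hz.
#' @param avg_window causal moving-average window in seconds.
#' @param derivations named list mapping derivation name to
#'   `c(anterior, posterior)` electrode labels.
#' @param fs sampling rate in Hz.
#' @return An object of class `"bandpower_config"`.
#' @export
bandpower_config <- function(bands = list(mu = c(9, 13), beta = c(16, 26)),
                             avg_window = 1.0,
                             derivations = list(C3 = c("FC3", "CP3"),
                                                Cz = c("FCz", "CPz"),
                                                C4 = c("FC4", "CP4")),
                             fs = 256) {
  for (b in bands) if (b[1] >= b[2]) stop("band low edge must be below high edge")
  if (avg_window <= 0) stop("avg_window must be positive")
  cfg <- structure(list(bands = bands, avg_window = avg_window,
                        derivations = derivations, fs = fs),
                   class = "bandpower_config")
  cfg
}

#' Feature identifiers of a band-power configuration
#'
#' @param cfg a [bandpower_config()].
#' @return data.frame with columns `derivation`, `band`, `id` (6 rows in the
#'   fixed feature order: all derivations for the first band, then the second).
#' @export
feature_ids <- function(cfg = bandpower_config()) {
  d <- names(cfg$derivations)
  b <- names(cfg$bands)
  out <- expand.grid(derivation = d, band = b, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$id <- paste(out$derivation, out$band, sep = "-")
  out
}

## --- stateful IIR plumbing -------------------------------------------------

new_iir <- function(b, a) list(b = as.numeric(b), a = as.numeric(a), zi = NULL)

iir_apply <- function(f, x) {
  r <- iir_filter_state(f$b, f$a, x, f$zi)
  f$zi <- r$zf
  list(y = r$y, f = f)
}

.design_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .design_cache, inherits = FALSE))
    assign(key, force(expr), .design_cache)
  get(key, .design_cache, inherits = FALSE)
}

design_bandpass <- function(low, high, fs, order = 2) {
  bt <- cached(sprintf("bp_%g_%g_%g_%d", low, high, fs, order),
               signal::butter(order, c(low, high) / (fs / 2), type = "pass"))
  new_iir(bt$b, bt$a)
}

design_notch <- function(freq, fs, width = 2, order = 1) {
  bt <- cached(sprintf("notch_%g_%g_%g_%d", freq, fs, width, order),
               signal::butter(order, c(freq - width, freq + width) / (fs / 2),
                              type = "stop"))
  new_iir(bt$b, bt$a)
}

# |H(f)|^2 averaged over white input: fraction of white-noise power passed.
filter_noise_gain <- function(flt, n = 4096) {
  key <- paste0("gain_", paste(signif(c(flt$b, 0.5, flt$a), 12), collapse = "_"))
  cached(key, {
    w <- pi * (seq_len(n) - 0.5) / n
    num <- exp(-1i * outer(w, seq_along(flt$b) - 1)) %*% flt$b
    den <- exp(-1i * outer(w, seq_along(flt$a) - 1)) %*% flt$a
    mean(Mod(num / den)^2)
  })
}

## --- preprocessing ----------------------------------------------------------

#' Causal EEG preprocessing: 0.5--100 Hz band-pass and 50 Hz notch
#'
#' Applies a causal Butterworth band-pass (0.5--100 Hz) and a narrow 50 Hz
#' notch to every channel, matching online operation (no zero-phase
#' filtering). The first second after a cold start is a filter warm-up
#' transient and is marked via the `"warmup_samples"` attribute.
#'
#' Filter state can be carried across consecutive blocks so that streaming
#' block-wise processing equals whole-stream processing: pass the
#' `"filter_state"` attribute of the previous output as `state`.
#'
#' @param seg an [eeg_segment()] at 256 Hz.
#' @param state carried filter state from a previous block, or `NULL` for a
#'   cold start.
#' @return the filtered [eeg_segment()], with attributes `"filter_state"` and
#'   `"warmup_samples"`.
#' @export
preprocess <- function(seg, state = NULL) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (seg$fs != 256) stop("pipeline requires fs = 256 Hz, got ", seg$fs)
  nch <- ncol(seg$data)
  if (is.null(state)) {
    state <- lapply(seq_len(nch), function(i)
      list(bp = design_bandpass(0.5, 100, seg$fs, order = 2),
           notch = design_notch(50, seg$fs)))
    warm <- seg$fs  # 1 s cold-start transient
  } else warm <- 0L
  out <- seg$data
  for (i in seq_len(nch)) {
    r1 <- iir_apply(state[[i]]$bp, seg$data[, i]); state[[i]]$bp <- r1$f
    r2 <- iir_apply(state[[i]]$notch, r1$y);       state[[i]]$notch <- r2$f
    out[, i] <- r2$y
  }
  res <- eeg_segment(out, seg$fs, seg$channel_labels, seg$t0)
  attr(res, "filter_state") <- state
  attr(res, "warmup_samples") <- warm
  res
}

#' Bipolar derivation
#'
#' Reduces the six-electrode montage to the three bipolar channels C3, Cz and
#' C4, each the anterior minus the posterior electrode of its pair (e.g.
#' C3 = FC3 - CP3). Bipolar derivations suppress common far-field activity.
#'
#' @param seg an [eeg_segment()] containing all electrodes named in `cfg`.
#' @param cfg a [bandpower_config()].
#' @return an [eeg_segment()] with one channel per derivation.
#' @export
bipolar_derive <- function(seg, cfg = bandpower_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  need <- unique(unlist(cfg$derivations))
  missing <- setdiff(need, seg$channel_labels)
  if (length(missing))
    stop("missing electrode(s): ", paste(missing, collapse = ", "))
  out <- vapply(cfg$derivations, function(p)
    seg$data[, p[1]] - seg$data[, p[2]], numeric(nrow(seg$data)))
  eeg_segment(as.matrix(out), seg$fs, names(cfg$derivations), seg$t0)
}

#' Logarithmic band-power features
#'
#' For each bipolar channel and band: causal band-pass, square, causal
#' rectangular moving average over `cfg$avg_window` seconds, natural
#' logarithm. Yields six features per sample in the fixed order C3-mu, Cz-mu,
#' C4-mu, C3-beta, Cz-beta, C4-beta, in log(microvolt^2).
#'
#' As with [preprocess()], filter and averaging state can be carried across
#' blocks via the `"filter_state"` attribute.
#'
#' @param seg a bipolar [eeg_segment()] (3 channels).
#' @param cfg a [bandpower_config()].
#' @param state carried state from a previous block, or `NULL`.
#' @return a `"feature_track"`: numeric matrix samples x 6 with attributes
#'   `fs`, `feature_ids` (data.frame), `"filter_state"`, `"warmup_samples"`.
#' @export
log_bandpower <- function(seg, cfg = bandpower_config(), state = NULL) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!all(is.finite(seg$data))) stop("non-finite values in EEG input")
  if (ncol(seg$data) != length(cfg$derivations))
    stop("expected one channel per derivation")
  fid <- feature_ids(cfg)
  width <- round(cfg$avg_window * seg$fs)
  if (nrow(seg$data) < 1) stop("empty segment")
  if (is.null(state)) {
    state <- lapply(seq_len(nrow(fid)), function(k) {
      band <- cfg$bands[[fid$band[k]]]
      list(bp = design_bandpass(band[1], band[2], seg$fs, order = 2),
           ma = NULL)
    })
    warm <- width  # moving-average warm-up
  } else warm <- 0L
  out <- matrix(NA_real_, nrow(seg$data), nrow(fid))
  for (k in seq_len(nrow(fid))) {
    ch <- match(fid$derivation[k], seg$channel_labels)
    r <- iir_apply(state[[k]]$bp, seg$data[, ch]); state[[k]]$bp <- r$f
    m <- moving_average_state(r$y^2, width, state[[k]]$ma)
    state[[k]]$ma <- m$state
    out[, k] <- log(pmax(m$y, .Machine$double.xmin))
  }
  colnames(out) <- fid$id
  structure(out, fs = seg$fs, feature_ids = fid, t0 = seg$t0,
            filter_state = state, warmup_samples = warm,
            class = c("feature_track", "matrix", "array"))
}

#' Full per-trial feature extraction
#'
#' Convenience wrapper: [preprocess()], [bipolar_derive()], [log_bandpower()]
#' on one raw 6-electrode epoch (cold start; the first second is warm-up).
#'
#' @param seg raw [eeg_segment()] with the six montage electrodes.
#' @param cfg a [bandpower_config()].
#' @return list with elements `features` (feature track), `bipolar` (the
#'   band-filtered bipolar segment used for artifact screening).
#' @export
extract_features <- function(seg, cfg = bandpower_config()) {
  pp <- preprocess(seg)
  bip <- bipolar_derive(pp, cfg)
  list(features = log_bandpower(bip, cfg), bipolar = bip)
}
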