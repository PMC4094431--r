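fs <- 256

test_that("preprocessing removes DC, passes 10 Hz, and notches 50 Hz", {
  n <- 8 * fs
  labs <- montage6
  dc <- eeg_segment(matrix(50, n, 6), fs, labs)
  out <- preprocess(dc)
  expect_lt(max(abs(out$data[(4 * fs):n, ])), 0.01)

  t <- seq_len(n) / fs
  steady <- (4 * fs):n
  s10 <- eeg_segment(matrix(10 * sin(2 * pi * 10 * t), n, 6), fs, labs)
  gain10 <- sd(preprocess(s10)$data[steady, 1]) / sd(s10$data[steady, 1])
  expect_equal(gain10, 1, tolerance = 0.05)

  s50 <- eeg_segment(matrix(10 * sin(2 * pi * 50 * t), n, 6), fs, labs)
  gain50 <- sd(preprocess(s50)$data[steady, 1]) / sd(s50$data[steady, 1])
  expect_lt(20 * log10(gain50), -20)
})

test_that("preprocessing rejects non-256 Hz input", {
  seg <- eeg_segment(matrix(0, 100, 6), 128, montage6)
  expect_error(preprocess(seg), "256")
})

test_that("bipolar derivation is anterior minus posterior", {
  n <- fs
  zero <- matrix(0, n, 6, dimnames = list(NULL, montage6))
  same <- zero; same[, "FC3"] <- 1; same[, "CP3"] <- 1
  out <- bipolar_derive(eeg_segment(same, fs, montage6))
  expect_true(all(out$data[, "C3"] == 0))

  one <- zero; one[, "FC3"] <- 1
  out <- bipolar_derive(eeg_segment(one, fs, montage6))
  expect_true(all(out$data[, "C3"] == 1))

  set.seed(1)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, montage6))
  out <- bipolar_derive(eeg_segment(X, fs, montage6))
  expect_equal(out$data[, "C3"], X[, "FC3"] - X[, "CP3"])
  expect_equal(out$data[, "Cz"], X[, "FCz"] - X[, "CPz"])
  expect_equal(out$data[, "C4"], X[, "FC4"] - X[, "CP4"])

  expect_error(bipolar_derive(eeg_segment(X[, 1:5], fs, montage6[1:5])),
               "CP4")
})

test_that("log band-power is calibrated: unit in-band power gives log(1) = 0", {
  seg <- sine_segment(10, sqrt(2), seconds = 8)  # power = 1 uV^2 at 10 Hz
  tr <- log_bandpower(seg)
  expect_equal(mean(tr[(4 * fs):(8 * fs), "C3-mu"]), 0, tolerance = 0.1)
})

test_that("doubling the amplitude raises the feature by log(4)", {
  a <- log_bandpower(sine_segment(11, 2, seconds = 6))
  b <- log_bandpower(sine_segment(11, 4, seconds = 6))
  steady <- (3 * fs):(6 * fs)
  expect_equal(mean(b[steady, "C3-mu"] - a[steady, "C3-mu"]), log(4),
               tolerance = 0.01)
})

test_that("white-noise band power matches the frequency-response oracle", {
  set.seed(3)
  sigma <- 5
  n <- 60 * fs
  seg <- eeg_segment(matrix(rnorm(n * 3, sd = sigma), n, 3), fs,
                     c("C3", "Cz", "C4"))
  tr <- log_bandpower(seg)
  # oracle: white-noise power passed by the band filter, |H|^2 via freqz;
  # measurement averaged over the three independent channels
  bt <- signal::butter(2, c(9, 13) / (fs / 2), type = "pass")
  h <- signal::freqz(bt$b, bt$a, n = 4096)
  expected <- sigma^2 * mean(Mod(h$h)^2)
  measured <- mean(exp(tr[(5 * fs):n, c("C3-mu", "Cz-mu", "C4-mu")]))
  expect_equal(measured, expected, tolerance = 0.1)
  # beta band as well
  bt2 <- signal::butter(2, c(16, 26) / (fs / 2), type = "pass")
  h2 <- signal::freqz(bt2$b, bt2$a, n = 4096)
  expected2 <- sigma^2 * mean(Mod(h2$h)^2)
  measured2 <- mean(exp(tr[(5 * fs):n, c("C3-beta", "Cz-beta", "C4-beta")]))
  expect_equal(measured2, expected2, tolerance = 0.1)
})

test_that("features are monotone in input amplitude for fixed waveform", {
  set.seed(4)
  base <- matrix(rnorm(6 * fs * 3), 6 * fs, 3)
  labs <- c("C3", "Cz", "C4")
  steady <- (3 * fs):(6 * fs)
  m <- sapply(c(1, 2, 4, 8), function(a) {
    tr <- log_bandpower(eeg_segment(a * base, fs, labs))
    mean(tr[steady, "C3-mu"])
  })
  expect_true(all(diff(m) > 0))
})

test_that("block-wise streaming equals whole-stream processing", {
  set.seed(5)
  n <- 4 * fs
  X <- matrix(rnorm(n * 6, sd = 10), n, 6, dimnames = list(NULL, montage6))
  whole <- preprocess(eeg_segment(X, fs, montage6))
  track_whole <- log_bandpower(bipolar_derive(whole))

  pre_state <- NULL; bp_state <- NULL
  pieces <- list()
  for (b in 1:4) {
    rows <- ((b - 1) * fs + 1):(b * fs)
    pp <- preprocess(eeg_segment(X[rows, ], fs, montage6), pre_state)
    pre_state <- attr(pp, "filter_state")
    tr <- log_bandpower(bipolar_derive(pp), state = bp_state)
    bp_state <- attr(tr, "filter_state")
    pieces[[b]] <- unclass(tr)
  }
  expect_equal(do.call(rbind, pieces), unclass(track_whole)[, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature extraction rejects non-finite input", {
  X <- matrix(0, fs, 3); X[5, 2] <- NA
  expect_error(log_bandpower(eeg_segment(X, fs, c("C3", "Cz", "C4"))),
               "finite")
})
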