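fs <- 256

gauss_epoch <- function(n = 7 * fs, sd = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmin(pmax(matrix(rnorm(n * 3, sd = sd), n, 3), -30), 30)
}

test_that("statistical screening flags amplitude, kurtosis and heavy tails", {
  set.seed(10)
  history <- lapply(1:20, function(i) gauss_epoch())
  clean <- gauss_epoch()
  v <- screen_trial_stats(clean, history)
  expect_true(v$clean)
  expect_length(v$reasons, 0)

  spike <- clean; spike[100, 2] <- 500
  v <- screen_trial_stats(spike, history)
  expect_true("amplitude" %in% v$reasons)
  expect_false(v$clean)

  # heavy-tailed epoch among Gaussian history: kurtosis z-score oracle
  set.seed(11)
  heavy <- matrix(rnorm(7 * fs * 3) * (1 + 6 * (runif(7 * fs * 3) < 0.02)),
                  7 * fs, 3)
  kurt <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  kh <- sapply(history, function(h) apply(h, 2, kurt))
  z <- (apply(heavy, 2, kurt) - rowMeans(kh)) / apply(kh, 1, sd)
  expect_gt(max(z), 5)  # oracle confirms the construction
  v <- screen_trial_stats(heavy, history)
  expect_true("kurtosis" %in% v$reasons)
})

test_that("screening falls back to amplitude-only with a short history", {
  set.seed(12)
  heavy <- matrix(rnorm(fs * 3) * 10, fs, 3)
  heavy <- pmin(pmax(heavy, -90), 90)
  v <- screen_trial_stats(heavy, history = list())
  expect_true(v$clean)
  expect_error(screen_trial_stats(matrix(0, 0, 3)), "empty")
})

test_that("leave-one-out feature-outlier rejection matches its z oracle", {
  # identical trials: zero variance handled as no-outlier
  feats <- matrix(1, 10, 6)
  r <- reject_feature_outliers(feats, rep(c("a", "b"), each = 5))
  expect_length(r$rejected, 0)

  # 19 trials at 0, one at +10 SD: exactly that one rejected
  feats <- matrix(0, 20, 6)
  feats[7, 3] <- 10
  labels <- rep("a", 20)
  r <- reject_feature_outliers(feats, labels, k = 3)
  expect_equal(r$rejected, 7L)

  # noisy variant checked against the leave-one-out z oracle
  set.seed(13)
  noisy <- matrix(rnorm(20 * 6), 20, 6)
  noisy[7, 3] <- 10 * sd(noisy[-7, 3])
  rn <- reject_feature_outliers(noisy, labels, k = 3)
  z <- apply(noisy, 2, function(f) sapply(seq_along(f), function(i)
    abs(f[i] - mean(f[-i])) / sd(f[-i])))
  expect_setequal(rn$rejected, which(apply(z > 3, 1, any)))
  expect_true(7L %in% rn$rejected)

  # k = Inf disables rejection
  r <- reject_feature_outliers(feats, labels, k = Inf)
  expect_length(r$rejected, 0)

  # permutation invariance of the verdict set
  perm <- sample(20)
  rp <- reject_feature_outliers(noisy[perm, ], labels[perm], k = 3)
  expect_setequal(perm[rp$rejected], rn$rejected)
})

test_that("AR(11) coefficients are recovered from a known stable process", {
  set.seed(14)
  true_ar <- c(0.6, -0.3, 0.15, 0.1, -0.05, 0.04, -0.03, 0.02, 0.02,
               -0.01, 0.01)
  n <- 60 * fs
  x <- as.numeric(stats::arima.sim(list(ar = true_ar), n, sd = 1))
  X <- cbind(x, x2 = as.numeric(stats::arima.sim(list(ar = true_ar), n)),
             x3 = as.numeric(stats::arima.sim(list(ar = true_ar), n)))
  colnames(X) <- c("C3", "Cz", "C4")
  m <- fit_ar(X)
  expect_s3_class(m, "ar_model")
  expect_equal(m$order, 11)
  expect_lt(max(abs(m$coeffs - true_ar)), 0.1)
})

test_that("white noise yields near-zero AR coefficients and a calibrated threshold", {
  set.seed(15)
  X <- matrix(rnorm(60 * fs * 3), ncol = 3,
              dimnames = list(NULL, c("C3", "Cz", "C4")))
  m <- fit_ar(X)
  expect_lt(max(abs(m$coeffs)), 0.05)
  # <= 1 % of training samples are flagged, by construction of the threshold
  res <- erdbci:::ar_residuals(m, X)[-(1:11), ]
  exceeded <- abs(res) > matrix(m$residual_threshold, nrow(res), 3,
                                byrow = TRUE)
  expect_lte(mean(rowSums(exceeded) > 0), 0.0101)
  expect_error(fit_ar(X[1:100, ]), "10 s")
})

test_that("online detection flags transients fast and holds 0.5 s", {
  set.seed(16)
  true_ar <- c(0.5, -0.25, 0.1)
  sim <- function(n) as.numeric(stats::arima.sim(list(ar = true_ar), n))
  Xtrain <- cbind(sim(30 * fs), sim(30 * fs), sim(30 * fs))
  colnames(Xtrain) <- c("C3", "Cz", "C4")
  m <- fit_ar(Xtrain)

  # stream from the model's own process: flagged fraction <= 2 %
  Xs <- cbind(sim(20 * fs), sim(20 * fs), sim(20 * fs))
  det <- detect_artifact_online(Xs, m)
  expect_lte(mean(det$raw_flags), 0.02)

  # 300 uV step transient: flag within 50 ms of onset
  Xt <- Xs
  onset <- 10 * fs
  Xt[onset:(onset + fs), 1] <- Xt[onset:(onset + fs), 1] + 300
  det <- detect_artifact_online(Xt, m)
  first <- which(det$raw_flags & seq_along(det$raw_flags) >= onset)[1]
  expect_lte((first - onset) / fs, 0.05)

  # hold: flag stays raised until offset + 0.5 s (step-induced flag run)
  off <- max(which(det$raw_flags[seq_len(11 * fs)]))
  expect_true(all(det$flags[off:(off + round(0.5 * fs))]))

  # streaming equals whole-stream
  st <- NULL; parts <- list()
  for (b in 1:4) {
    rows <- ((b - 1) * 5 * fs + 1):(b * 5 * fs)
    d <- detect_artifact_online(Xt[rows, ], m, state = st)
    st <- d$state
    parts[[b]] <- d$flags
  }
  expect_equal(unlist(parts), det$flags)
})
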