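fs <- 256

test_that("fisher score matches the closed formula", {
  expect_equal(fisher_score(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(20)
  a <- rnorm(50); b <- rnorm(50, 1)
  expect_equal(fisher_score(a + 0, b), (mean(a) - mean(b))^2 / (var(a) + var(b)),
               tolerance = 1e-12)
  # means 0 and 1, unit variances -> 0.5
  a <- c(-1, 1); b <- c(0, 2)  # means 0,1; var 2,2 -> 1/4
  expect_equal(fisher_score(a, b), 0.25)
  expect_error(fisher_score(1, c(1, 2)), "2 samples")
})

test_that("LDA training matches the closed form and is duplication-invariant", {
  set.seed(21)
  x <- c(rnorm(40, -1), rnorm(40, 1))
  labels <- rep(c("nc", "mi"), each = 40)
  m <- train_lda(x, labels, positive = "mi")
  # boundary near 0 in the symmetric case
  expect_equal(-m$b / m$w, 0, tolerance = 0.1)
  # closed-form oracle: pooled-covariance discriminant (ML pooling)
  mu1 <- mean(x[labels == "mi"]); mu0 <- mean(x[labels == "nc"])
  s2 <- (sum((x[labels == "mi"] - mu1)^2) +
           sum((x[labels == "nc"] - mu0)^2)) / 80
  expect_equal(m$w, (mu1 - mu0) / s2, tolerance = 1e-12)
  # duplicating every trial leaves the model unchanged
  m2 <- train_lda(c(x, x), c(labels, labels), positive = "mi")
  expect_equal(m2$w, m$w, tolerance = 1e-9)
  expect_equal(m2$b, m$b, tolerance = 1e-9)
  expect_error(train_lda(x, rep("mi", 80), "mi"), "both classes")
})

test_that("window selection finds the window where classes separate", {
  pr <- erdbci:::period_rows(fs)
  # separability planted only from 5 s on (windows 4-7): the earliest
  # separating window is selected
  late <- pr[(4 * 128 + 1):length(pr)]
  p <- planted_tracks(8, rows_offset = late, offset = 3, noise = 0.1,
                      seed = 22)
  r <- loocv_window_select(p$tracks, p$labels, col = 1, positive = "mi")
  expect_equal(r$train_window, 4L)
  expect_gt(r$medians[5], max(r$medians[1:4]))

  # separable everywhere: median accuracy 1, earliest window by tie-break
  p <- planted_tracks(6, rows_offset = pr, offset = 50, noise = 0.1, seed = 23)
  r <- loocv_window_select(p$tracks, p$labels, col = 1, positive = "mi")
  expect_equal(r$train_window, 0L)
  expect_equal(max(r$medians), 1.0)

  # no class difference: chance-level accuracy
  p <- planted_tracks(10, rows_offset = pr, offset = 0, seed = 24)
  r <- loocv_window_select(p$tracks, p$labels, col = 1, positive = "mi")
  expect_equal(median(r$medians), 0.5, tolerance = 0.15)

  # degenerate constant feature falls back to window 0 with a warning
  const <- lapply(p$tracks, function(m) { m[] <- 1; m })
  expect_warning(
    rd <- loocv_window_select(const, p$labels, col = 1, positive = "mi"),
    "degenerate")
  expect_equal(rd$train_window, 0L)
})

test_that("window selection equals a brute-force LooCV oracle on a small instance", {
  set.seed(25)
  pr <- erdbci:::period_rows(fs)
  p <- planted_tracks(5, rows_offset = pr[1:512], offset = 1.2, seed = 25)
  r <- loocv_window_select(p$tracks, p$labels, col = 1, positive = "mi")
  # oracle: direct re-implementation, all folds and windows explicitly
  n <- length(p$tracks)
  med <- sapply(0:7, function(w) {
    rows <- pr[(w * 128 + 1):((w + 1) * 128)]
    acc <- rep(0, length(pr))
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      xw <- sapply(p$tracks[tr], function(m) mean(m[rows, 1]))
      l <- train_lda(xw, p$labels[tr], "mi")
      o <- l$w * p$tracks[[i]][pr, 1] + l$b
      acc <- acc + ((o > 0) == (p$labels[i] == "mi"))
    }
    median(acc / n)
  })
  expect_equal(r$medians, med, tolerance = 1e-12)
  expect_equal(r$train_window, which.max(med) - 1L)
})

test_that("auto-calibration triggers at exactly nine clean trials per class", {
  u <- sim_user("strong")
  store <- sim_trial_store(u, 9, seed = 26)
  counts <- clean_counts(store)
  m <- bci_calibrate(store)
  if (min(counts) >= 9) {
    expect_s3_class(m, "bci_classifier")
  }
  # drop one class below 9: insufficient
  small <- store
  labs <- vapply(small$trials, `[[`, character(1), "label")
  drop <- which(labs == "left")[1]
  small$trials <- small$trials[-drop]
  m2 <- bci_calibrate(small)
  if (clean_counts(small)["left"] < 9) {
    expect_false(inherits(m2, "bci_classifier"))
    expect_equal(m2$status, "insufficient")
  }
})

test_that("re-calibration requires five new clean trials per class", {
  u <- sim_user("strong")
  store <- sim_trial_store(u, 10, seed = 27)
  m <- bci_calibrate(store)
  expect_s3_class(m, "bci_classifier")
  store <- erdbci:::store_reset_counter(store)
  # add 4 new clean trials per active class: no re-calibration
  add <- sim_trial_store(u, 4, seed = 28, classes = c("nc", m$selected_class))
  for (tr in add$trials) store <- store_add(store, tr)
  if (min(store$new_clean[c("nc", m$selected_class)]) < 5) {
    expect_equal(bci_calibrate(store, m)$status, "insufficient")
  }
  # the fifth triggers it
  add5 <- sim_trial_store(u, 2, seed = 29, classes = c("nc", m$selected_class))
  for (tr in add5$trials) store <- store_add(store, tr)
  m2 <- bci_calibrate(store, m)
  expect_s3_class(m2, "bci_classifier")
  expect_equal(m2$calib_count, m$calib_count + 1L)
})

test_that("calibration is a deterministic function of the store", {
  u <- sim_user("strong")
  s1 <- sim_trial_store(u, 9, seed = 30)
  s2 <- sim_trial_store(u, 9, seed = 30)
  m1 <- bci_calibrate(s1)
  m2 <- bci_calibrate(s2)
  expect_equal(coef(m1), coef(m2))
  expect_equal(m1$feature$id, m2$feature$id)
  expect_equal(m1$train_window, m2$train_window)
})

test_that("normalized outputs map training class means to -1, 0, +1", {
  m <- calibrated_model(seed = 31)
  # reconstruct the training window means from the stored discriminant:
  # raw output at class means is +/- (by the normalization contract)
  mu_mid <- -m$b / m$w
  half <- 1 / (m$out_scale * m$w)
  mu_nc <- mu_mid - half
  mu_mi <- mu_mid + half
  expect_equal(predict(m, mu_nc), -1, tolerance = 1e-9)
  expect_equal(predict(m, mu_mi), +1, tolerance = 1e-9)
  expect_equal(predict(m, mu_mid), 0, tolerance = 1e-9)
  expect_equal(predict(m, mu_mi, type = "label"), m$selected_class)
  expect_equal(predict(m, mu_nc, type = "label"), "nc")
})

test_that("bias adaptation anchors the 90th percentile at zero and is idempotent", {
  m <- calibrated_model(seed = 32)
  set.seed(33)
  f <- rnorm(40 * fs, mean = -m$b / m$w, sd = 1 / abs(m$out_scale * m$w))
  m1 <- adapt_bias(m, f)
  o <- predict(m1, f)
  expect_equal(quantile(o, 0.9, names = FALSE), 0, tolerance = 1e-9)
  expect_lte(mean(o > 0.5), 0.1)
  # affine oracle: +0.5 drift in output space shifts the bias down by 0.5
  f_drift <- f + 0.5 / (m1$out_scale * m1$w)
  m2 <- adapt_bias(m1, f_drift)
  expect_equal(m2$out_shift, m1$out_shift - 0.5, tolerance = 1e-9)
  # idempotence on the same run
  m3 <- adapt_bias(m1, f)
  expect_equal(m3$out_shift, m1$out_shift, tolerance = 1e-9)
  expect_error(adapt_bias(m, f[1:(20 * fs)]), "30 s")
})

test_that("class selection recovers a one-sided responder", {
  hits <- 0
  for (s in 1:6) {
    u <- sim_user(erd_depth = list(right = c("C3-mu" = 0.5)))
    store <- sim_trial_store(u, 10, seed = 300 + s)
    m <- bci_calibrate(store)
    if (inherits(m, "bci_classifier") && m$selected_class == "right")
      hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("model JSON round-trips the decision function", {
  m <- calibrated_model(seed = 34)
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  x <- seq(-5, 5, length.out = 11)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
  expect_equal(m2$ar$coeffs, m$ar$coeffs, tolerance = 1e-12)
  expect_equal(m2$selected_class, m$selected_class)
})
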