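fs <- 256

test_that("sample-wise accuracy and its peak behave", {
  pred <- rbind(rep("a", 10), rep("b", 10))
  acc <- samplewise_accuracy(pred, c("a", "b"))
  expect_true(all(acc$acc == 1))
  expect_equal(acc$peak, 100)

  pred <- rbind(rep("a", 10), rep("a", 10))
  acc <- samplewise_accuracy(pred, c("a", "b"))
  expect_true(all(acc$acc == 0.5))
  # peak >= mean always
  set.seed(50)
  pred <- matrix(sample(c("a", "b"), 200, TRUE), 20, 10)
  acc <- samplewise_accuracy(pred, rep(c("a", "b"), 10))
  expect_gte(acc$peak, 100 * mean(acc$acc))
  expect_error(samplewise_accuracy(pred, c("a", "b")), "one label per trial")
})

test_that("the Youden index matches a brute-force grid oracle", {
  # perfect separation
  O <- rbind(matrix(1, 5, 2 * fs), matrix(-1, 5, 2 * fs))
  labels <- rep(c("mi", "nc"), each = 5)
  r <- youden_index(O, labels, "mi")
  expect_equal(r$J, 1)
  # identical outputs across classes: J = 0 everywhere
  O0 <- rbind(matrix(1, 5, 2 * fs), matrix(1, 5, 2 * fs))
  r0 <- youden_index(O0, labels, "mi")
  expect_true(all(abs(r0$grid$J) < 1e-12))
  # random small instance vs independent enumeration
  set.seed(51)
  O <- matrix(rnorm(10 * 2 * fs, sd = 0.8), 10)
  O[1:5, ] <- O[1:5, ] + 0.5
  thr <- seq(-0.5, 0.5, by = 0.5); dw <- c(0.5, 1, 2)
  r <- youden_index(O, labels, "mi", thresholds = thr, dwells = dw)
  best <- -Inf
  for (d in dw) for (th in thr) {
    act <- apply(O, 1, function(o) {
      rr <- rle(o > th); any(rr$values & rr$lengths >= round(d * fs))
    })
    J <- mean(act[1:5]) - mean(act[6:10])
    best <- max(best, J)
  }
  expect_equal(r$J, best, tolerance = 1e-12)
})

test_that("Youden index and balanced accuracy are duplication-invariant", {
  set.seed(52)
  O <- matrix(rnorm(8 * fs), 8)
  labels <- rep(c("mi", "nc"), 4)
  r1 <- youden_index(O, labels, "mi", thresholds = c(-0.2, 0.2),
                     dwells = c(0.5, 1), fs = 32)
  r2 <- youden_index(rbind(O, O), c(labels, labels), "mi",
                     thresholds = c(-0.2, 0.2), dwells = c(0.5, 1), fs = 32)
  expect_equal(r1$J, r2$J)
  cc <- list(TP = 10, FN = 5, FP = 3, TN = 20)
  cc2 <- lapply(cc, `*`, 2)
  expect_equal(balanced_accuracy(cc), balanced_accuracy(cc2))
})

test_that("the chance threshold reproduces the printed 61 % and its Monte-Carlo null", {
  th <- chance_threshold(54, alpha = 0.01)
  expect_equal(th, 61.0, tolerance = 0.2)
  # consistency: N -> infinity approaches 50 %
  expect_lt(chance_threshold(1e6), 50.1)
  # strictly decreasing in N, increasing as alpha shrinks
  ns <- c(10, 20, 54, 100, 400)
  expect_true(all(diff(sapply(ns, chance_threshold)) < 0))
  expect_gt(chance_threshold(54, 0.001), chance_threshold(54, 0.05))
  # Monte-Carlo binomial null at N = 108
  set.seed(53)
  emp <- quantile(rbinom(10000, 108, 0.5) / 108, 0.99, names = FALSE) * 100
  expect_equal(th, emp, tolerance = 1.0)
  expect_error(chance_threshold(54, alpha = 0.7), "alpha")
})

test_that("balanced accuracy corrects the 31.2 % target imbalance to 50 %", {
  expect_equal(balanced_accuracy(list(TP = 7, FN = 7, FP = 9, TN = 9)), 50)
  expect_equal(balanced_accuracy(list(TP = 10, FN = 0, FP = 0, TN = 30)), 100)
  expect_error(balanced_accuracy(list(TP = 0, FN = 0, FP = 1, TN = 1)),
               "classes")
  # null detector at 31.2 % prevalence: expectation 50 %
  set.seed(54)
  reps <- replicate(400, {
    tgt <- runif(1000) < 0.312
    act <- rpois(1000, 0.4)  # activations independent of target status
    balanced_accuracy(confusion_counts(
      data.frame(is_target = tgt, activations = act)))
  })
  expect_equal(mean(reps), 50, tolerance = 0.5)
})

test_that("the self-paced chance threshold is conservative and consistent", {
  expect_true(all(diff(sapply(c(10, 30, 54, 200), selfpaced_chance_threshold)) < 0))
  expect_lt(selfpaced_chance_threshold(1e6), 50.2)
  # conservative against a Monte-Carlo null of segment outcomes
  set.seed(55)
  n_seg <- 160; p_tgt <- 0.312
  nulls <- replicate(2000, {
    tgt <- runif(n_seg) < p_tgt
    act <- as.integer(runif(n_seg) < 0.3)
    balanced_accuracy(confusion_counts(
      data.frame(is_target = tgt, activations = act)))
  })
  emp99 <- quantile(nulls, 0.99, names = FALSE)
  th <- selfpaced_chance_threshold(round(n_seg * p_tgt))
  expect_equal(th, emp99, tolerance = 1.5)
})
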