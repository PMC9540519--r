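test_that("scoring reproduces hand-computed rates and a confusion-matrix oracle", {
  # a 12-trial block with 5 correct is 41.7%
  pred <- c(rep("positive", 5), rep("negative", 7))
  truth <- c(rep("positive", 12))
  expect_equal(round(score(pred, truth)$accuracy, 1), 41.7)
  # TP=20 TN=16 FP=14 FN=10 -> 60.0 / 66.7 / 53.3
  pred2 <- c(rep("positive", 20), rep("negative", 10),
             rep("negative", 16), rep("positive", 14))
  truth2 <- c(rep("positive", 30), rep("negative", 30))
  ev <- score(pred2, truth2)
  expect_equal(round(ev$accuracy, 1), 60.0)
  expect_equal(round(ev$sensitivity, 1), 66.7)
  expect_equal(round(ev$specificity, 1), 53.3)
  expect_equal(c(ev$tp, ev$tn, ev$fp, ev$fn), c(20, 16, 14, 10))
  # confusion oracle + permutation equivariance
  perm <- sample(60)
  ev2 <- score(pred2[perm], truth2[perm])
  expect_equal(ev2$accuracy, ev$accuracy)
  tab <- table(pred2, truth2)
  expect_equal(ev$accuracy, 100 * sum(diag(tab)) / sum(tab))
  # all correct
  ev3 <- score(truth2, truth2)
  expect_equal(c(ev3$accuracy, ev3$sensitivity, ev3$specificity),
               c(100, 100, 100))
  expect_error(score(pred, truth2), "length mismatch")
})

test_that("exact binomial thresholds match a brute-force tail sum for many n", {
  brute <- function(n, conf) {
    for (k in 0:n) if (sum(dbinom(k:n, n, 0.5)) < 1 - conf) return(k)
    n + 1
  }
  for (n in c(1:30, 57, 60, 120, 180, 443, 997))
    for (conf in c(0.95, 0.99, 0.999))
      expect_equal(attr(chance_threshold(n, conf), "k"), brute(n, conf),
                   info = paste(n, conf))
})

test_that("chance thresholds reproduce the published figure-caption values", {
  expect_equal(as.integer(chance_threshold(120, 0.95)), 58L)
  expect_equal(as.integer(chance_threshold(180, 0.95)), 57L)
  expect_equal(attr(chance_threshold(60, 0.95), "exact"), 61.6667,
               tolerance = 1e-4)
  # consistency limit: the threshold approaches 50% for huge n
  expect_equal(attr(chance_threshold(1e6, 0.95), "exact"), 50, tolerance = 0.3)
  # one-sided normal approximation for comparison
  expect_equal(attr(chance_threshold_normal(60, 0.95), "exact"),
               50 + 100 * qnorm(0.95) * 0.5 / sqrt(60), tolerance = 1e-10)
})

test_that("cross-validation stratifies folds, selects in-fold, and detects strong effects", {
  trials <- offset_trials(n = 30, shift = 1.5, seed = 6)
  cv <- cross_validate(trials, "mean", folds = 5, iterations = 2, seed = 1)
  expect_s3_class(cv, "bci_cv")
  expect_gte(cv$mean_accuracy, 90)
  expect_length(cv$per_iteration, 2)
  expect_error(cross_validate(trials[1:8], "mean", folds = 10),
               "stratification")
})

test_that("in-fold selection has no optimistic bias at null, unlike leaky selection", {
  fm <- iid_features(n = 60, seed = 31)
  y <- attr(fm, "labels")
  # leaky protocol: select channels once on ALL data, then cross-validate
  sub_all <- select_channels(fm, y)
  set.seed(1)
  fold <- integer(60)
  for (cl in unique(y)) {
    i <- which(y == cl); fold[i] <- sample(rep_len(1:10, length(i)))
  }
  leaky <- correct_infold <- 0
  for (f in 1:10) {
    tr <- fold != f; te <- fold == f
    m <- train_lda(fm[tr, sub_all$columns, drop = FALSE], y[tr])
    leaky <- leaky + sum(predict(m, fm[te, sub_all$columns, drop = FALSE])$label == y[te])
    sub_f <- select_channels(fm[tr, , drop = FALSE], y[tr])
    m2 <- train_lda(fm[tr, sub_f$columns, drop = FALSE], y[tr])
    correct_infold <- correct_infold +
      sum(predict(m2, fm[te, sub_f$columns, drop = FALSE])$label == y[te])
  }
  # selection leakage inflates null accuracy well above chance;
  # the in-fold protocol stays at or below the upper chance band
  expect_gt(100 * leaky / 60, 60)
  expect_lte(100 * correct_infold / 60, attr(chance_threshold(60, 0.95), "exact"))
})

test_that("selection frequencies count events conservatively per chromophore", {
  sub <- list(hbo = c(1L, 2L, 3L, 4L, 5L), hbr = c(6L, 7L, 8L, 9L, 10L))
  tally <- selection_frequency(sub)
  expect_equal(tally$hbo[1:5], rep(1L, 5))
  expect_equal(sum(tally$hbo), 5)
  expect_equal(tally$hbr[6:10], rep(1L, 5))
  many <- selection_frequency(list(sub, sub, list(hbo = 1:5, hbr = 1:5)))
  expect_equal(sum(many$hbo), 15)  # 5 x number of events
  expect_equal(sum(many$hbr), 15)
})

test_that("selection audit logs round-trip through JSONL files", {
  s <- small_session()
  fit <- bci_fit(small_session(seed = 8)$trials, feature_type = "mean")
  log <- run_online_session(fit, s$raw, small_config())
  path <- tempfile(fileext = ".jsonl")
  write_selection_log(log, path)
  events <- read_selection_log(path)
  expect_length(events, small_config()$blocks)
  tally_file <- selection_frequency(path)
  tally_log <- selection_frequency(log)
  expect_equal(tally_file, tally_log)
  expect_equal(sum(tally_file$hbo), 5 * length(events))
  unlink(path)
})
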