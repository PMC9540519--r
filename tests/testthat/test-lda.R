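test_that("LDA solves the hand-computed one-dimensional case exactly", {
  # neg {-1,-3}, pos {1,3}: means +/-2, pooled variance 2,
  # w = (2 - (-2))/2 = 2, bias = 0, so the discriminant is 2x
  X <- matrix(c(1, 3, -1, -3))
  y <- c("positive", "positive", "negative", "negative")
  m <- train_lda(X, y, gamma = 0)
  expect_equal(m$w, 2, tolerance = 1e-12)
  expect_equal(m$bias, 0, tolerance = 1e-12)
  p <- predict(m, matrix(c(0, 1, -1)))
  expect_equal(p$posterior, plogis(c(0, 2, -2)), tolerance = 1e-12)
  expect_equal(p$label, c("positive", "positive", "negative"))  # tie -> positive
})

test_that("the weight vector satisfies the model invariant", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60, 1), 15), matrix(rnorm(60, -1), 15))
  y <- rep(c("positive", "negative"), each = 15)
  m <- train_lda(X, y)
  expect_equal(as.numeric(solve(m$cov) %*% (m$mu_pos - m$mu_neg)), m$w,
               tolerance = 1e-9)
  expect_true(all(is.finite(coef(m))))
  expect_equal(unname(m$priors), c(0.5, 0.5))
})

test_that("well-separated clouds are perfectly classified, symmetric ones split at the midpoint", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 8), 20))
  y <- rep(c("negative", "positive"), each = 20)
  m <- train_lda(X, y)
  expect_equal(predict(m, X)$label, y)  # 100% training accuracy
  # far inside the positive class the posterior saturates
  expect_gt(predict(m, c(8, 8))$posterior, 0.99)
  # symmetric classes: boundary at the midpoint
  Xs <- rbind(matrix(rnorm(60, 2), 15), matrix(rnorm(60, -2), 15))
  ms <- train_lda(Xs, rep(c("positive", "negative"), each = 15), gamma = 0)
  mid <- (ms$mu_pos + ms$mu_neg) / 2
  expect_equal(predict(ms, mid)$posterior, 0.5, tolerance = 1e-9)
})

test_that("the posterior is strictly increasing along the weight direction", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 1.5), 20), matrix(rnorm(40, -1.5), 20))
  m <- train_lda(X, rep(c("positive", "negative"), each = 20))
  ray <- t(sapply(seq(-3, 3, 0.5), function(a) a * m$w / sqrt(sum(m$w^2))))
  post <- predict(m, ray)$posterior
  expect_true(all(diff(post) > 0))
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  X <- rbind(matrix(rnorm(100, 1), 25), matrix(rnorm(100, 0), 25))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("positive", "negative"), each = 25)
  mine <- train_lda(X, y, gamma = 0)
  ref <- MASS::lda(X, grouping = y)
  rp <- predict(ref, X)
  mp <- predict(mine, X)
  expect_equal(mp$label, as.character(rp$class))
  expect_equal(mp$posterior, unname(rp$posterior[, "positive"]),
               tolerance = 1e-8)
})

test_that("the model is shift-invariant and scale-equivariant", {
  set.seed(5)
  X <- rbind(matrix(rnorm(60, 1), 15), matrix(rnorm(60, -1), 15))
  y <- rep(c("positive", "negative"), each = 15)
  m0 <- train_lda(X, y, gamma = 0)
  mshift <- train_lda(X + 7, y, gamma = 0)
  expect_equal(mshift$w, m0$w, tolerance = 1e-9)
  expect_equal(predict(mshift, X[3, ] + 7)$posterior,
               predict(m0, X[3, ])$posterior, tolerance = 1e-9)
  mscale <- train_lda(X * 10, y, gamma = 0)
  expect_equal(mscale$w, m0$w / 10, tolerance = 1e-9)
  expect_equal(predict(mscale, X[3, ] * 10)$posterior,
               predict(m0, X[3, ])$posterior, tolerance = 1e-9)
})

test_that("shrinkage rescues singular covariances; true singularity errors", {
  set.seed(6)
  x <- rnorm(10)
  X <- cbind(x, x, x)  # rank-1 within-class structure
  X[1:5, ] <- X[1:5, ] + 1
  y <- rep(c("positive", "negative"), each = 5)
  m <- train_lda(X, y)  # Ledoit-Wolf shrinkage handles it
  expect_true(all(is.finite(m$w)))
  expect_gt(m$gamma, 0)
  expect_error(train_lda(matrix(0, 10, 2), y), "singular")
  expect_error(train_lda(X, rep("positive", 10)), "both classes")
  expect_error(predict(m, c(1, 2)), "dimension mismatch")
})

test_that("posterior probabilities are approximately calibrated on conformant data", {
  set.seed(7)
  n <- 400
  mu <- c(1, 0.5)
  Xtr <- rbind(matrix(rnorm(2 * n, 0), n), sweep(matrix(rnorm(2 * n), n), 2, -mu))
  ytr <- rep(c("negative", "positive"), each = n)
  m <- train_lda(Xtr, ytr, gamma = 0)
  Xte <- rbind(matrix(rnorm(2 * n, 0), n), sweep(matrix(rnorm(2 * n), n), 2, -mu))
  yte <- rep(c("negative", "positive"), each = n)
  p <- predict(m, Xte)
  correct <- as.numeric(p$label == yte)
  conf <- pmax(p$posterior, 1 - p$posterior)
  for (lo in c(0.5, 0.65, 0.8)) {
    i <- conf >= lo & conf < lo + 0.15
    if (sum(i) >= 50)
      expect_equal(mean(correct[i]), mean(conf[i]), tolerance = 0.1)
  }
})

test_that("models survive a JSON round trip", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 1), 15), matrix(rnorm(60, -1), 15))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("positive", "negative"), each = 15)
  m <- train_lda(X, y)
  path <- tempfile(fileext = ".json")
  write_lda(m, path)
  back <- read_lda(path)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_equal(back$gamma, m$gamma)
  unlink(path)
})
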