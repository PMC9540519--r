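test_that("Fisher criterion matches the hand-computed scalar case", {
  # class A: {0, 1}; class B: {10, 11}: within-scatter 0.5 + 0.5 = 1,
  # between-scatter 2*(5.5-10.5)^2 ... = 100, J = 100 (up to the tiny ridge)
  X <- matrix(c(0, 1, 10, 11))
  y <- c("a", "a", "b", "b")
  expect_equal(fisher_score(X, y), 100, tolerance = 1e-4)
  # identical class distributions give J ~ 0
  Z <- matrix(rnorm(10), 5)
  expect_equal(fisher_score(rbind(Z, Z), rep(c("a", "b"), each = 5)), 0,
               tolerance = 1e-9)
  expect_error(fisher_score(X, rep("a", 4)), "two classes")
  expect_error(fisher_score(X, c("a", "b", "b", "b")), ">= 2 trials")
})

test_that("Fisher criterion is invariant under invertible affine maps as ridge vanishes", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40)
  X[1:20, 1] <- X[1:20, 1] + 1.5
  y <- rep(c("positive", "negative"), each = 20)
  A <- matrix(rnorm(16), 4) + diag(4)
  b <- rnorm(4)
  J1 <- fisher_score(X, y, ridge = 1e-12)
  J2 <- fisher_score(sweep(X %*% A, 2, -b), y, ridge = 1e-12)
  expect_equal(J1, J2, tolerance = 1e-6)
  expect_gte(J1, 0)
})

test_that("floating search equals exhaustive search on small random instances", {
  set.seed(101)
  for (i in 1:20) {
    d <- sample(6:10, 1)
    n <- sample(c(24, 40), 1)
    y <- rep(c("positive", "negative"), each = n / 2)
    X <- matrix(rnorm(n * d), n)
    X[y == "positive", ] <- X[y == "positive", ] +
      matrix(rnorm(d, 0, 0.7), n / 2, d, byrow = TRUE)
    s_float <- sffs_select(X, y, target = 5)
    s_exh <- affectbci:::exhaustive_select(X, y, target = 5)
    expect_identical(as.integer(s_float), as.integer(s_exh))
    expect_equal(attr(s_float, "score"), attr(s_exh, "score"), tolerance = 1e-9)
  }
})

test_that("floating search beats or ties plain greedy forward selection", {
  set.seed(8)
  for (i in 1:5) {
    n <- 40; d <- 12
    y <- rep(c("positive", "negative"), each = n / 2)
    X <- matrix(rnorm(n * d), n)
    X[y == "positive", 1:4] <- X[y == "positive", 1:4] + 0.8
    greedy <- integer(0)
    for (k in 1:5) {
      cand <- setdiff(1:d, greedy)
      js <- vapply(cand, function(f)
        fisher_score(X[, c(greedy, f), drop = FALSE], y), 0)
      greedy <- c(greedy, cand[which.max(js)])
    }
    s <- sffs_select(X, y, target = 5)
    expect_gte(attr(s, "score") + 1e-9,
               fisher_score(X[, greedy, drop = FALSE], y))
  }
})

test_that("ties break toward the lowest channel id and errors are informative", {
  set.seed(9)
  x <- rnorm(20) + rep(c(1, 0), each = 10)
  y <- rep(c("positive", "negative"), each = 10)
  X <- cbind(x, x, rnorm(20), rnorm(20), rnorm(20), rnorm(20))
  s <- sffs_select(X, y, target = 1)
  expect_equal(as.integer(s), 1L)  # duplicated informative column: lowest id
  expect_error(sffs_select(X[, 1:3], y, target = 5), "fewer candidate")
  expect_error(sffs_select(X, rep("positive", 20), target = 2), "two classes")
})

test_that("per-chromophore selection yields 10 features and ignores the other chromophore", {
  fm <- iid_features(n = 60, shift = 3, shift_channels = c(2, 6, 11, 17, 20),
                     seed = 4)
  sub <- select_channels(fm)
  expect_s3_class(sub, "bci_channel_subset")
  expect_length(sub$hbo, 5)
  expect_length(sub$hbr, 5)
  expect_length(sub$columns, 10)
  expect_false(any(duplicated(sub$hbo)))
  # HbO selection is untouched by arbitrary changes to the Hb columns
  fm2 <- fm
  fm2[, 23:44] <- matrix(rnorm(60 * 22, sd = 3), 60)
  expect_identical(select_channels(fm2)$hbo, sub$hbo)
  # most planted HbO channels are found at high effect (the criterion-optimal
  # subset can legitimately trade one planted channel for a noise-canceller)
  expect_gte(length(intersect(sub$hbo, c(2L, 6L, 11L, 17L, 20L))), 4)
})

test_that("on null data the selected sets vary across realizations", {
  sets <- vapply(1:12, function(i)
    paste(select_channels(iid_features(n = 30, seed = 100 + i))$hbo,
          collapse = ","), "")
  expect_gt(length(unique(sets)), 6)
})

test_that("the scatter-based subset criterion equals the reference Fisher score", {
  set.seed(12)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rep(c("positive", "negative"), each = 15)
  S <- affectbci:::scatter_matrices(X, y)
  for (i in 1:10) {
    idx <- sort(sample(8, sample(2:5, 1)))
    expect_equal(affectbci:::J_subset(S, idx),
                 fisher_score(X[, idx, drop = FALSE], y), tolerance = 1e-10)
  }
})
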