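test_that("the designed low-pass filter meets DC gain, stopband and stability requirements", {
  f <- design_filter()
  expect_equal(sum(f$b) / sum(f$a), 1, tolerance = 1e-6)  # 0 dB at DC
  expect_gte(f$achieved$stopband_atten_db, 50)
  expect_true(f$achieved$stable)
  # independent check of the realized response on a fresh grid
  freqs <- seq(0.5, 5, by = 0.005)
  H <- vapply(freqs, function(fr) {
    z <- exp(-1i * 2 * pi * fr / f$fs * (0:3))
    Mod(sum(f$b * z) / sum(f$a * z))
  }, 0)
  expect_true(all(-20 * log10(H) >= 50 - 1e-6))
})

test_that("order 3 cannot meet the passband bound, and strict mode reports it", {
  f <- design_filter()
  expect_gt(f$achieved$passband_dev_db, 0.1)  # physical limit at this order
  expect_error(design_filter(strict = TRUE), "passband deviation")
  # a higher order meets both clauses
  f4 <- design_filter(order = 4)
  expect_lte(f4$achieved$passband_dev_db, 0.1)
  expect_silent(design_filter(order = 4, strict = TRUE))
  expect_error(design_filter(passband_hz = 0.6), "Nyquist")
})

test_that("causal filtering is linear and matches an independent IIR implementation", {
  f <- design_filter()
  set.seed(1)
  x <- rnorm(500)
  y1 <- iir_filter(x, f)$y
  expect_equal(iir_filter(3 * x, f)$y, 3 * y1, tolerance = 1e-12)
  # oracle: the signal package's own filter routine
  y2 <- as.numeric(signal::filter(signal::Arma(f$b, f$a), x))
  expect_equal(y1, y2, tolerance = 1e-10)
})

test_that("a 1 Hz sinusoid is attenuated by at least 50 dB in steady state", {
  f <- design_filter()
  tt <- (0:1199) / 10
  y <- iir_filter(sin(2 * pi * 1 * tt), f)$y
  expect_lte(max(abs(y[600:1200])), 10^(-50 / 20) * 1.01)
})

test_that("chunked streaming reproduces batch filtering bit for bit", {
  f <- design_filter()
  set.seed(2)
  x <- matrix(rnorm(900 * 3), ncol = 3)
  whole <- iir_filter(x, f)$y
  st <- NULL
  got <- x * NA
  pos <- 0
  for (take in c(20, 7, 113, 20, 20, 1, 219, 500)) {
    take <- min(take, nrow(x) - pos)
    r <- iir_filter(x[pos + seq_len(take), , drop = FALSE], f, st)
    got[pos + seq_len(take), ] <- r$y
    st <- r$state
    pos <- pos + take
  }
  expect_identical(got, whole)
})

test_that("stream and batch modes agree on a whole recording", {
  s <- small_session()
  f <- design_filter()
  expect_identical(apply_filter(s$raw, f, mode = "stream")$data,
                   apply_filter(s$raw, f, mode = "batch")$data)
})

test_that("baseline correction zeroes the baseline window, block by block, idempotently", {
  s <- small_session()
  rec <- apply_filter(s$raw, design_filter())
  cor1 <- baseline_correct(rec)
  bl <- cor1$markers[cor1$markers$kind == "baseline", ]
  for (i in seq_len(nrow(bl))) {
    win <- bl$onset[i] + seq_len(bl$duration[i])
    expect_equal(max(abs(colMeans(cor1$data[win, , 1]))), 0, tolerance = 1e-10)
    expect_equal(max(abs(colMeans(cor1$data[win, , 2]))), 0, tolerance = 1e-10)
  }
  # offset invariance: adding a constant to one block changes nothing
  shifted <- rec
  b2 <- affectbci:::block_starts(rec)[2]
  shifted$data[(b2 + 1):dim(rec$data)[1], , ] <-
    shifted$data[(b2 + 1):dim(rec$data)[1], , ] + 5
  expect_equal(baseline_correct(shifted)$data, cor1$data, tolerance = 1e-10)
  # idempotence
  expect_equal(baseline_correct(cor1)$data, cor1$data, tolerance = 1e-12)
  # blocks are corrected independently
  expect_false(isTRUE(all.equal(
    cor1$data[b2 + 1:100, 1, 1],
    rec$data[b2 + 1:100, 1, 1] - mean(rec$data[1:300, 1, 1]))))
  nomk <- rec; nomk$markers <- NULL
  expect_error(baseline_correct(nomk), "no markers")
})

test_that("MBLL conversion inverts its forward model and has the right signs", {
  expect_equal(mbll_convert(matrix(0, 5, 2)),
               matrix(0, 5, 2, dimnames = list(NULL, c("hbo", "hbr"))))
  set.seed(3)
  conc <- cbind(hbo = rnorm(20), hbr = rnorm(20))
  od <- mbll_forward(conc)
  back <- mbll_convert(od)
  expect_equal(unname(back), unname(conc), tolerance = 1e-10)
  # a pure HbO increase produces a larger OD change at 830 nm, where the
  # oxygenated extinction coefficient dominates
  od1 <- mbll_forward(cbind(hbo = 1, hbr = 0))
  expect_gt(od1[1, "od830"], od1[1, "od690"])
  expect_error(mbll_convert(od, wavelengths = c(690, 690)), "singular")
  expect_error(mbll_convert(od, wavelengths = c(700, 830)), "700")
  expect_error(mbll_convert(matrix(0, 5, 3)), "two wavelength")
})

test_that("preprocess() composes filter and baseline correction", {
  s <- small_session()
  pre <- preprocess(s$raw)
  expect_true(isTRUE(attr(pre, "preprocessed")))
  manual <- baseline_correct(apply_filter(s$raw, design_filter()))
  expect_identical(pre$data, manual$data)
})
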