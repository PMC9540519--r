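#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a gamma-density main lobe minus a scaled
#' gamma-density undershoot, normalized so the default response peaks at 1.
#' Defaults place the peak at 6 s post-stimulus, inside the physiological
#' 5-8 s window for the evoked cortical response.
#'
#' @param t Time since stimulus onset, seconds (`t >= 0`).
#' @param params List of shape parameters: `peak_shape`, `peak_rate`
#'   (main lobe gamma), `under_shape`, `under_rate`, `under_ratio`
#'   (undershoot gamma and its relative amplitude).
#' @return Unitless amplitude, zero at `t = 0`, single main peak.
#' @examples
#' tt <- seq(0, 30, 0.01)
#' tt[which.max(canonical_hrf(tt))]  # ~6 s
#' @export
canonical_hrf <- function(t, params = hrf_params()) {
  p <- params
  vals <- unlist(p[c("peak_shape", "peak_rate", "under_shape", "under_rate",
                     "under_ratio")])
  if (any(!is.finite(vals)) || any(vals[1:4] <= 0))
    stop("canonical_hrf: non-finite or non-positive shape parameters")
  if (any(t < 0)) stop("canonical_hrf: t must be >= 0")
  raw <- function(x) stats::dgamma(x, p$peak_shape, p$peak_rate) -
    p$under_ratio * stats::dgamma(x, p$under_shape, p$under_rate)
  grid <- seq(0, 40, by = 0.01)
  raw(t) / max(raw(grid))
}

#' @rdname canonical_hrf
#' @param peak_shape,peak_rate,under_shape,under_rate,under_ratio See above.
#' @export
hrf_params <- function(peak_shape = 7, peak_rate = 1, under_shape = 16,
                       under_rate = 1, under_ratio = 1 / 6) {
  list(peak_shape = peak_shape, peak_rate = peak_rate,
       under_shape = under_shape, under_rate = under_rate,
       under_ratio = under_ratio)
}

#' Simulation parameters for a synthetic session
#'
#' Defines the statistical structure the pipeline assumes: valence-dependent
#' spatial amplitude maps applied to a canonical HRF in the oxygenated
#' hemoglobin signal (with an anti-correlated, ratio-scaled deoxygenated
#' counterpart), plus additive physiological noise -- narrowband cardiac
#' (0.8-1.2 Hz) and respiratory (0.2-0.4 Hz) oscillations, a ~0.1 Hz
#' Mayer-wave component, linear drift, per-channel DC offset and white noise.
#'
#' The planted class effect is parameterized by `effect_size`: the
#' separation between the two class amplitude maps on each planted channel
#' (at the HRF peak), in units of the raw per-sample noise standard
#' deviation. The noise SD is measured by a short deterministic simulation
#' at construction (stored as `sigma_raw`, alongside `sigma_feat`, the
#' noise SD of the preprocessed per-trial window mean, and `hrf_win_mean`,
#' the window mean of a unit filtered response, which together give the
#' effect in feature units). `effect_size = 0` gives a null dataset with no
#' class structure.
#'
#' @param effect_size Planted class separation (see above).
#' @param planted_channels Channels carrying the differential effect
#'   (default: the five left-lateral prefrontal channels, emulating the
#'   lateral-PFC concentration of discriminative channels).
#' @param hrf HRF shape parameters, see [hrf_params()].
#' @param hbr_ratio Deoxygenated-to-oxygenated response amplitude ratio
#'   (must be negative; conventional anti-correlation).
#' @param cardiac_amp,cardiac_band Cardiac oscillation amplitude (uM*mm) and
#'   frequency band (Hz).
#' @param resp_amp,resp_band Respiratory amplitude and band.
#' @param mayer_amp,mayer_hz Mayer-wave amplitude and center frequency.
#' @param drift_sd SD of the per-channel linear drift slope, uM*mm per second.
#' @param coherence_s Phase-coherence time of the narrowband components,
#'   seconds (their phase diffuses stochastically on this timescale, so
#'   trials 40 s apart see effectively independent oscillation phases).
#' @param white_sd White measurement noise SD, uM*mm.
#' @param offset_sd SD of the per-channel DC offset, uM*mm.
#' @param hbr_noise_scale Noise amplitude scale for the deoxygenated channel
#'   relative to oxygenated.
#' @param amp_pos,amp_neg Optional explicit 22-channel amplitude maps
#'   (uM*mm at HRF peak); when omitted they are built from `effect_size`.
#' @param config Protocol used for calibration (defaults to the standard one).
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(effect_size = 1,
                             planted_channels = lateral_channels(side = "L"),
                             hrf = hrf_params(), hbr_ratio = -1 / 3,
                             cardiac_amp = 0.4, cardiac_band = c(0.8, 1.2),
                             resp_amp = 0.3, resp_band = c(0.2, 0.4),
                             mayer_amp = 0.3, mayer_hz = 0.1,
                             drift_sd = 5e-5, white_sd = 0.2,
                             coherence_s = 20,
                             offset_sd = 1, hbr_noise_scale = 1 / 3,
                             amp_pos = NULL, amp_neg = NULL,
                             config = session_config()) {
  if (hbr_ratio >= 0) stop("synthetic_params: hbr_ratio must be negative")
  nyq <- config$fs / 2
  centers <- c(mean(cardiac_band), mean(resp_band), mayer_hz)
  if (any(centers >= nyq))
    stop("synthetic_params: noise band center at or above Nyquist (", nyq, " Hz)")
  tt <- seq(0, 30, 0.01)
  pk <- tt[which.max(canonical_hrf(tt, hrf))]
  p <- list(effect_size = effect_size, planted_channels = planted_channels,
            hrf = hrf, hrf_peak_s = pk, hbr_ratio = hbr_ratio,
            cardiac_amp = cardiac_amp, cardiac_band = cardiac_band,
            resp_amp = resp_amp, resp_band = resp_band,
            mayer_amp = mayer_amp, mayer_hz = mayer_hz,
            drift_sd = drift_sd, white_sd = white_sd,
            coherence_s = coherence_s, offset_sd = offset_sd,
            hbr_noise_scale = hbr_noise_scale, config = config)
  cal <- calibrate_effect(p)
  p$sigma_raw <- cal$sigma_raw
  p$sigma_feat <- cal$sigma_feat
  p$hrf_win_mean <- cal$hrf_win_mean
  n_ch <- 22L
  if (is.null(amp_pos) || is.null(amp_neg)) {
    delta <- if (effect_size > 0) effect_size * cal$sigma_raw else 0
    amp_pos <- amp_neg <- rep(0, n_ch)
    amp_pos[planted_channels] <- +delta / 2
    amp_neg[planted_channels] <- -delta / 2
  }
  p$amp_pos <- amp_pos
  p$amp_neg <- amp_neg
  class(p) <- "synthetic_params"
  p
}

#' @export
print.synthetic_params <- function(x, ...) {
  cat(sprintf("synthetic_params: effect size %.2f on channels {%s}, HRF peak %.1f s\n",
              x$effect_size, paste(x$planted_channels, collapse = ","), x$hrf_peak_s))
  invisible(x)
}

# Deterministic calibration: noise SD of the preprocessed per-trial window
# mean, and the window mean of a unit-amplitude filtered HRF response.
calibrate_effect <- function(p) {
  cfg <- p$config
  fs <- cfg$fs
  filt <- design_filter(fs = fs)
  n_block <- as.integer((cfg$baseline_s +
    cfg$trials_per_block * (cfg$task_s + cfg$rest_s)) * fs)
  nb <- as.integer(cfg$baseline_s * fs)
  nt <- as.integer(cfg$task_s * fs)
  stride <- as.integer((cfg$task_s + cfg$rest_s) * fs)
  onsets <- nb + (seq_len(cfg$trials_per_block) - 1L) * stride
  noise <- with_seed(104729, noise_matrix(n_block, fs, p, n_series = 24))
  filtered <- iir_filter(noise, filt)$y
  filtered <- sweep(filtered, 2, colMeans(filtered[seq_len(nb), , drop = FALSE]))
  means <- sapply(seq_len(ncol(filtered)), function(j)
    vapply(onsets, function(on) mean(filtered[(on + 1):(on + nt), j]), 0))
  sigma_feat <- stats::sd(as.numeric(means))

  # unit HRF response placed mid-block, filtered causally
  x <- numeric(n_block)
  on <- onsets[3]
  tsup <- seq_len(min(400L, n_block - on))
  x[on + tsup] <- canonical_hrf((tsup - 1) / fs, p$hrf)
  xf <- iir_filter(x, filt)$y
  hrf_win_mean <- mean(xf[(on + 1):(on + nt)])
  list(sigma_raw = stats::sd(as.numeric(noise)), sigma_feat = sigma_feat,
       hrf_win_mean = hrf_win_mean)
}

#' Pseudo-randomized counter-balanced trial order
#'
#' Each block contains `positives_per_block` positive and the remaining
#' negative trials in randomized order, with no run of more than three
#' identical labels anywhere in the session (runs are checked across block
#' boundaries). Reproducible under `seed`.
#'
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @return Character vector of `"positive"`/`"negative"`, one per trial.
#' @export
make_trial_order <- function(config = session_config(), seed = 1) {
  with_seed(seed, trial_order_impl(config))
}

trial_order_impl <- function(config, max_run = 3, max_tries = 10000) {
  block <- c(rep("positive", config$positives_per_block),
             rep("negative", config$trials_per_block - config$positives_per_block))
  if (max(config$positives_per_block,
          config$trials_per_block - config$positives_per_block) >
      max_run * (min(config$positives_per_block,
                     config$trials_per_block - config$positives_per_block) + 1))
    stop("make_trial_order: label counts cannot satisfy the run-length constraint")
  out <- character(0)
  for (b in seq_len(config$blocks)) {
    for (try in seq_len(max_tries)) {
      cand <- sample(block)
      r <- rle(c(tail(out, max_run), cand))
      if (max(r$lengths) <= max_run) { out <- c(out, cand); break }
      if (try == max_tries)
        stop("make_trial_order: could not schedule block ", b,
             " under the run-length constraint")
    }
  }
  out
}

#' Synthetic physiological noise
#'
#' Sum of amplitude-modulated narrowband oscillations (cardiac,
#' respiratory, Mayer), linear drift and white noise, with independent
#' random phases per channel. Narrowband components use slow sinusoidal
#' frequency jitter confined to the stated band.
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate, Hz.
#' @param params A [synthetic_params()] object.
#' @param seed Integer seed.
#' @param n_series Number of independent channel series.
#' @param scale Overall amplitude scale (used for the deoxygenated signal).
#' @return Matrix, `n_samples` x `n_series`, uM*mm.
#' @export
generate_noise <- function(n_samples, fs, params = synthetic_params(),
                           seed = 1, n_series = 22, scale = 1) {
  if (any(c(mean(params$cardiac_band), mean(params$resp_band), params$mayer_hz) >= fs / 2))
    stop("generate_noise: noise band center at or above Nyquist")
  with_seed(seed, noise_matrix(n_samples, fs, params, n_series, scale))
}

noise_matrix <- function(n_samples, fs, p, n_series = 22, scale = 1) {
  t <- (seq_len(n_samples) - 1) / fs
  # narrowband oscillation with slow sinusoidal frequency jitter inside the
  # band plus stochastic phase diffusion (coherence time ~coh_s seconds, as
  # physiological rhythms are not phase-coherent over a whole session)
  coh_s <- p$coherence_s %||% 20
  narrowband <- function(amp, band) {
    if (amp == 0) return(numeric(n_samples))
    f0 <- mean(band); hb <- diff(range(band)) / 2
    fm <- runif(1, 0.005, 0.02)
    finst <- f0 + hb * sin(2 * pi * fm * t + runif(1, 0, 2 * pi))
    diffusion <- cumsum(rnorm(n_samples, 0, sqrt(2 / (coh_s * fs))))
    phase <- 2 * pi * cumsum(finst) / fs + diffusion + runif(1, 0, 2 * pi)
    am <- 1 + 0.3 * sin(2 * pi * runif(1, 0.01, 0.03) * t + runif(1, 0, 2 * pi))
    amp * am * sin(phase)
  }
  out <- matrix(0, n_samples, n_series)
  for (j in seq_len(n_series)) {
    x <- narrowband(p$cardiac_amp, p$cardiac_band) +
      narrowband(p$resp_amp, p$resp_band) +
      narrowband(p$mayer_amp, c(p$mayer_hz, p$mayer_hz))
    slope <- if (p$drift_sd > 0) rnorm(1, 0, p$drift_sd) else 0
    wn <- if (p$white_sd > 0) rnorm(n_samples, 0, p$white_sd) else 0
    out[, j] <- x + slope * t + wn
  }
  out * scale
}

#' Generate a full synthetic fNIRS session
#'
#' Builds the standard session schedule (baseline, task, rest markers),
#' plants class-map x HRF responses in the oxygenated signal (and the
#' ratio-scaled anti-correlated deoxygenated counterpart) during task
#' epochs, and adds physiological noise, drift and per-channel offsets.
#'
#' @param config A [session_config()].
#' @param params A [synthetic_params()].
#' @param seed Integer seed; the whole session is deterministic given
#'   (`config`, `params`, `seed`).
#' @return List with `recording` (a raw, unpreprocessed [nirs_recording()])
#'   and `truth` (class `bci_ground_truth`: labels, markers, the noiseless
#'   response array, amplitude maps, effect size).
#' @examples
#' s <- generate_session(seed = 1)
#' dim(s$recording$data)  # 25500 x 22 x 2
#' @export
generate_session <- function(config = session_config(),
                             params = synthetic_params(), seed = 1) {
  montage <- build_standard_montage()
  n_ch <- nrow(montage$channels)
  if (length(params$amp_pos) != n_ch || length(params$amp_neg) != n_ch)
    stop("generate_session: amplitude maps must have one value per channel")
  fs <- config$fs
  n <- as.integer(session_duration_s(config) * fs)
  with_seed(seed, {
    labels <- trial_order_impl(config)
    markers <- session_markers(config, labels)
    noiseless <- array(0, c(n, n_ch, 2), dimnames = list(NULL, NULL, c("hbo", "hbr")))
    tm <- markers[markers$kind == "task", ]
    support <- min(400L, n)
    hrfv <- canonical_hrf((seq_len(support) - 1) / fs, params$hrf)
    for (i in seq_len(nrow(tm))) {
      amp <- if (tm$valence[i] == "positive") params$amp_pos else params$amp_neg
      idx <- tm$onset[i] + seq_len(min(support, n - tm$onset[i]))
      h <- hrfv[seq_along(idx)]
      noiseless[idx, , "hbo"] <- noiseless[idx, , "hbo"] + outer(h, amp)
      noiseless[idx, , "hbr"] <- noiseless[idx, , "hbr"] +
        params$hbr_ratio * outer(h, amp)
    }
    data <- noiseless
    data[, , "hbo"] <- data[, , "hbo"] + noise_matrix(n, fs, params, n_ch) +
      matrix(rnorm(n_ch, 0, params$offset_sd), n, n_ch, byrow = TRUE)
    data[, , "hbr"] <- data[, , "hbr"] +
      noise_matrix(n, fs, params, n_ch, scale = params$hbr_noise_scale) +
      matrix(rnorm(n_ch, 0, params$offset_sd * params$hbr_noise_scale),
             n, n_ch, byrow = TRUE)
    rec <- nirs_recording(data, fs = fs, montage = montage, markers = markers)
    truth <- structure(list(labels = labels, markers = markers,
                            noiseless = noiseless,
                            effect_size = params$effect_size,
                            planted_channels = params$planted_channels,
                            amp_pos = params$amp_pos, amp_neg = params$amp_neg,
                            sigma_feat = params$sigma_feat),
                       class = "bci_ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' @export
print.bci_ground_truth <- function(x, ...) {
  cat(sprintf("bci_ground_truth: %d trials (%d positive), effect size %.2f\n",
              length(x$labels), sum(x$labels == "positive"), x$effect_size))
  invisible(x)
}
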