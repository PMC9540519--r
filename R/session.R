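#' Neurofeedback bar height from a prediction
#'
#' The bar height is the positive-class posterior itself: 0.5 is the
#' neutral midpoint where each trial starts, 1 a full (positive) bar, 0 an
#' empty (negative) bar.
#'
#' @param pred A prediction data frame (from [predict.bci_lda()] /
#'   [predict.bci_fit()]) or a numeric posterior.
#' @return Height(s) in `[0, 1]`.
#' @export
feedback_height <- function(pred) {
  p <- if (is.data.frame(pred)) pred$posterior else pred
  pmin(1, pmax(0, p))
}

#' Cumulative online prediction over a trial
#'
#' Classifies a 20-s trial as it streams in: the k-th output is computed
#' from the first `k * segment_s` seconds, with features over the
#' cumulative window (moving-slope sub-windows are truncated to the
#' available data while it is shorter than one sub-window). The final
#' output uses the full window and equals the batch prediction of the
#' whole trial.
#'
#' @param fit A [bci_fit()] (the current pipeline state).
#' @param trial_data Preprocessed samples x channels x 2 array for one
#'   trial (or a `trial_window`).
#' @param segment_s Segment length, seconds.
#' @return Data frame with one row per segment: `segment`, `seconds`,
#'   `label`, `posterior`, `discriminant`, `height`.
#' @export
classify_cumulative <- function(fit, trial_data, segment_s = 2) {
  if (inherits(trial_data, "trial_window")) trial_data <- trial_data$data
  n <- dim(trial_data)[1]
  step <- as.integer(round(segment_s * fit$fs))
  if (step < 1 || n < step) stop("classify_cumulative: stream underrun (trial has ",
                                 n, " samples, segment needs ", step, ")")
  flat <- cbind(trial_data[, , 1], trial_data[, , 2])
  ends <- seq(step, n, by = step)
  if (tail(ends, 1) != n) ends <- c(ends, n)
  out <- lapply(seq_along(ends), function(k) {
    feats <- features_of_matrix(flat[seq_len(ends[k]), , drop = FALSE],
                                fit$feature_type, fit$fs)
    p <- predict(fit$lda, feats[fit$subset$columns])
    cbind(segment = k, seconds = ends[k] / fit$fs, p)
  })
  out <- do.call(rbind, out)
  out$height <- feedback_height(out)
  out
}

#' Run a closed-loop online session
#'
#' Replays a recorded (or synthetic) session through the online loop: per
#' block, the causal filter state is re-initialized, the 30-s baseline is
#' streamed and its mean becomes the block's baseline correction, every
#' trial is classified cumulatively on 2-s segments (emitting neurofeedback
#' heights), and after each completed block the pipeline is retrained on
#' all accumulated data ([update.bci_fit()]). After the session the
#' returned state has absorbed all of the session's trials.
#'
#' The model used for any prediction was trained only on trials from
#' blocks completed before that prediction (plus prior sessions) -- the
#' current block's labels are used only after the block ends.
#'
#' @param fit A [bci_fit()] trained on prior-session data.
#' @param recording A raw (unpreprocessed) [nirs_recording()] with session
#'   markers.
#' @param config A [session_config()].
#' @param filt The causal filter, [design_filter()].
#' @return An object of class `bci_online_log`: `predictions` (per
#'   segment), `final` (one row per trial: predicted label, truth,
#'   posterior), `retrain` (per-block snapshots: training size, selected
#'   channels, weight checksum), and `fit` (the post-session state).
#' @export
run_online_session <- function(fit, recording, config = session_config(),
                               filt = design_filter(fs = recording$fs)) {
  if (!length(fit$trials)) stop("run_online_session: prior data is empty")
  m <- recording$markers
  if (is.null(m)) stop("run_online_session: recording has no markers")
  fs <- recording$fs
  step <- as.integer(round(config$segment_s * fs))
  n_ch <- dim(recording$data)[2]
  preds <- list(); finals <- list(); retrain <- list()
  for (b in sort(unique(m$block))) {
    mb <- m[m$block == b, , drop = FALSE]
    state <- NULL           # filter state resets at block boundaries
    base_mu <- NULL
    block_trials <- list()
    for (i in seq_len(nrow(mb))) {
      seg <- mb[i, ]
      idx <- seg$onset + seq_len(seg$duration)
      flat <- cbind(recording$data[idx, , 1], recording$data[idx, , 2])
      corrected <- matrix(NA_real_, seg$duration, 2 * n_ch)
      pos <- 0L
      while (pos < seg$duration) {
        take <- min(step, seg$duration - pos)
        r <- iir_filter(flat[pos + seq_len(take), , drop = FALSE], filt, state)
        state <- r$state
        chunk <- r$y
        if (!is.null(base_mu)) chunk <- sweep(chunk, 2, base_mu)
        corrected[pos + seq_len(take), ] <- chunk
        pos <- pos + take
        if (seg$kind == "task") {
          feats <- features_of_matrix(corrected[seq_len(pos), , drop = FALSE],
                                      fit$feature_type, fs)
          p <- predict(fit$lda, feats[fit$subset$columns])
          preds[[length(preds) + 1L]] <-
            cbind(block = b, trial = seg$trial,
                  segment = as.integer(ceiling(pos / step)),
                  seconds = pos / fs, p, height = feedback_height(p),
                  truth = seg$valence)
        }
      }
      if (seg$kind == "baseline") base_mu <- colMeans(corrected)
      if (seg$kind == "task") {
        arr <- array(NA_real_, c(seg$duration, n_ch, 2),
                     dimnames = list(NULL, NULL, c("hbo", "hbr")))
        arr[, , 1] <- corrected[, seq_len(n_ch)]
        arr[, , 2] <- corrected[, n_ch + seq_len(n_ch)]
        tw <- structure(list(data = arr, label = seg$valence,
                             block = b, trial = seg$trial),
                        class = "trial_window")
        block_trials[[length(block_trials) + 1L]] <- tw
        last <- preds[[length(preds)]]
        finals[[length(finals) + 1L]] <- data.frame(
          block = b, trial = seg$trial,
          label = last$label[nrow(last)], posterior = last$posterior[nrow(last)],
          truth = seg$valence)
      }
    }
    fit <- update(fit, block_trials)
    retrain[[length(retrain) + 1L]] <- list(
      block = b, n_train = length(fit$trials),
      hbo = fit$subset$hbo, hbr = fit$subset$hbr,
      w_checksum = sum(fit$lda$w) + fit$lda$bias)
  }
  structure(list(predictions = do.call(rbind, preds),
                 final = do.call(rbind, finals),
                 retrain = retrain, fit = fit,
                 feature_type = fit$feature_type),
            class = "bci_online_log")
}

#' @export
print.bci_online_log <- function(x, ...) {
  cat(sprintf("bci_online_log: %d trials, %d retraining events, %s feature\n",
              nrow(x$final), length(x$retrain), x$feature_type))
  acc <- 100 * mean(x$final$label == x$final$truth)
  cat(sprintf("  final-prediction accuracy %.1f%%\n", acc))
  invisible(x)
}

#' Selected-channel audit trail
#'
#' Writes one JSON line per retraining event (block, training size,
#' selected channels per chromophore); the accumulated files feed
#' [selection_frequency()].
#'
#' @param log A `bci_online_log`.
#' @param path JSONL output path (appended to).
#' @return `path`, invisibly.
#' @export
write_selection_log <- function(log, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (ev in log$retrain)
    writeLines(jsonlite::toJSON(ev[c("block", "n_train", "hbo", "hbr")],
                                auto_unbox = TRUE), con)
  invisible(path)
}

#' @rdname write_selection_log
#' @export
read_selection_log <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l))
}
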