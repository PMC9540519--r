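#' Score predictions against ground truth
#'
#' Accuracy is the percentage of correct classifications out of all
#' classifications made; sensitivity the recall on positive-valence trials
#' and specificity the recall on negative-valence trials. The report also
#' carries the exact binomial chance thresholds for its `n` at the 95, 99
#' and 99.9% confidence levels, and a per-block breakdown when block
#' indices are available.
#'
#' @param x Predicted labels (character), or a `bci_online_log`.
#' @param truth True labels (required for the character method).
#' @param block Optional block index per trial, for the breakdown.
#' @param ... Unused.
#' @return An object of class `bci_eval` with fields `n`, `tp`, `tn`,
#'   `fp`, `fn`, `accuracy`, `sensitivity`, `specificity` (percent, full
#'   precision; the print method shows one decimal) and `chance`
#'   (named percent thresholds).
#' @examples
#' score(rep(c("positive", "negative"), c(5, 7)),
#'       rep(c("positive", "negative"), each = 6))
#' @export
score <- function(x, ...) UseMethod("score")

#' @rdname score
#' @export
score.default <- function(x, truth, block = NULL, ...) {
  if (length(x) != length(truth))
    stop("score: prediction/label length mismatch (", length(x), " vs ",
         length(truth), ")")
  tp <- sum(x == "positive" & truth == "positive")
  tn <- sum(x == "negative" & truth == "negative")
  fp <- sum(x == "positive" & truth == "negative")
  fn <- sum(x == "negative" & truth == "positive")
  n <- length(truth)
  out <- list(n = n, tp = tp, tn = tn, fp = fp, fn = fn,
              accuracy = 100 * (tp + tn) / n,
              sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
              chance = c(`95%` = chance_threshold(n, 0.95),
                         `99%` = chance_threshold(n, 0.99),
                         `99.9%` = chance_threshold(n, 0.999)))
  if (!is.null(block)) {
    out$per_block <- do.call(rbind, lapply(sort(unique(block)), function(b) {
      i <- block == b
      data.frame(block = b, n = sum(i),
                 accuracy = 100 * mean(x[i] == truth[i]))
    }))
  }
  class(out) <- "bci_eval"
  out
}

#' @rdname score
#' @export
score.bci_online_log <- function(x, ...) {
  score(x$final$label, x$final$truth, block = x$final$block)
}

#' @export
print.bci_eval <- function(x, ...) {
  cat(sprintf("n = %d: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              x$n, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("chance thresholds (exact binomial): 95%%: %d%%, 99%%: %d%%, 99.9%%: %d%%\n",
              x$chance[1], x$chance[2], x$chance[3]))
  if (!is.null(x$per_block)) {
    cat("per block:", paste(sprintf("B%d %.1f%%", x$per_block$block,
                                    x$per_block$accuracy), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Chance-level accuracy threshold for a two-class classifier
#'
#' The smallest k with `P(X >= k) < alpha` under `Binomial(n, 0.5)`,
#' expressed as a percentage of n and rounded to the nearest integer
#' percent (the unrounded value and k are attached as attributes). This is
#' the exact binomial inverse tail; `chance_threshold_normal()` gives the
#' one-sided normal approximation for comparison.
#'
#' @param n Number of classifications.
#' @param confidence One of 0.95, 0.99, 0.999 (any value in (0,1) works).
#' @return Integer percent threshold with attributes `exact` (unrounded
#'   percent) and `k` (trial count).
#' @examples
#' chance_threshold(120)  # 58
#' chance_threshold(180)  # 57
#' @export
chance_threshold <- function(n, confidence = 0.95) {
  stopifnot(n >= 1, confidence > 0, confidence < 1)
  alpha <- 1 - confidence
  # smallest k with upper tail below alpha
  k <- stats::qbinom(alpha, n, 0.5, lower.tail = FALSE) + 1
  while (k > 0 && stats::pbinom(k - 2, n, 0.5, lower.tail = FALSE) < alpha)
    k <- k - 1
  pct <- 100 * k / n
  structure(as.integer(round(pct)), exact = pct, k = k)
}

#' @rdname chance_threshold
#' @export
chance_threshold_normal <- function(n, confidence = 0.95) {
  pct <- 100 * (0.5 + stats::qnorm(confidence) * 0.5 / sqrt(n))
  structure(as.integer(round(pct)), exact = pct)
}

#' Repeated stratified k-fold cross-validation with in-fold selection
#'
#' The offline evaluation protocol: per fold, channel selection
#' ([select_channels()]) runs on the training rows only -- the held-out
#' fold is excluded from feature selection and used solely to score the
#' trained LDA. Folds are stratified by class; partitions are reshuffled
#' each iteration.
#'
#' @param trials List of labeled `trial_window` objects.
#' @param feature_type One of [feature_types()].
#' @param folds,iterations Protocol size (default 10 x 10).
#' @param seed Integer seed for the partitions.
#' @param fs Sampling rate, Hz.
#' @param channels_per_chromophore Channels selected per chromophore.
#' @return An object of class `bci_cv`: `mean_accuracy`, `sd_accuracy`
#'   (across iterations, percent), `per_iteration`, and the protocol
#'   parameters.
#' @export
cross_validate <- function(trials, feature_type = "mean", folds = 10,
                           iterations = 10, seed = 1, fs = 10,
                           channels_per_chromophore = 5) {
  labels <- trial_labels(trials)
  classes <- unique(labels)
  if (length(classes) != 2) stop("cross_validate: need two classes")
  if (any(table(labels) < folds))
    stop("cross_validate: fewer trials than folds in a class; ",
         "stratification infeasible")
  fm <- build_feature_matrix(trials, feature_type, fs)
  n <- length(labels)
  acc <- with_seed(seed, vapply(seq_len(iterations), function(it) {
    fold <- integer(n)
    for (cl in classes) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- fold == f
      sub <- select_channels(fm[tr, , drop = FALSE], labels[tr],
                             target = channels_per_chromophore)
      lda <- train_lda(fm[tr, sub$columns, drop = FALSE], labels[tr])
      p <- predict(lda, fm[te, sub$columns, drop = FALSE])
      correct <- correct + sum(p$label == labels[te])
    }
    100 * correct / n
  }, 0))
  structure(list(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                 per_iteration = acc, folds = folds, iterations = iterations,
                 feature_type = feature_type, n = n),
            class = "bci_cv")
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("%dx%d-fold CV (%s feature, n = %d): %.1f%% +/- %.1f%%\n",
              x$iterations, x$folds, x$feature_type, x$n,
              x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Channel selection frequency across retraining events
#'
#' Tallies how often each channel was selected, split by chromophore, from
#' one or more selection audit sources.
#'
#' @param x A `bci_online_log`, a `bci_channel_subset`, a JSONL audit file
#'   path (see [write_selection_log()]), or a list of any of these.
#' @param n_channels Number of montage channels.
#' @return Data frame with `channel`, `hbo`, `hbr` counts; counts sum to
#'   `channels-per-event x number of events` per chromophore.
#' @export
selection_frequency <- function(x, n_channels = 22) {
  events <- collect_selection_events(x)
  if (!length(events)) stop("selection_frequency: no selection events")
  out <- data.frame(channel = seq_len(n_channels),
                    hbo = 0L, hbr = 0L)
  for (ev in events) {
    out$hbo[ev$hbo] <- out$hbo[ev$hbo] + 1L
    out$hbr[ev$hbr] <- out$hbr[ev$hbr] + 1L
  }
  out
}

collect_selection_events <- function(x) {
  if (inherits(x, "bci_online_log")) return(x$retrain)
  if (inherits(x, "bci_channel_subset")) return(list(x))
  if (is.character(x)) return(do.call(c, lapply(x, read_selection_log)))
  if (is.list(x)) {
    if (!is.null(x$hbo) && !is.null(x$hbr)) return(list(x))
    return(do.call(c, lapply(x, collect_selection_events)))
  }
  stop("selection_frequency: unrecognized input")
}
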