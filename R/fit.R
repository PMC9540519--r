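#' Fit the affective BCI pipeline
#'
#' The core fitting function: from labeled, preprocessed trial windows it
#' (optionally) picks the most discriminative temporal feature type by
#' cross-validation, selects the five best channels per chromophore by
#' floating search under the Fisher criterion, and trains a shrinkage LDA
#' on the resulting 10 features. The returned object carries the
#' accumulated training trials, so the block-wise adaptive retraining of an
#' online session is simply [update()] with the newly completed block.
#'
#' @param trials List of labeled `trial_window` objects (see
#'   [slice_trials()]).
#' @param feature_type One of [feature_types()], or `NULL` to choose by
#'   repeated cross-validation of first-session data (frozen thereafter:
#'   `update()` never revisits it).
#' @param fs Sampling rate, Hz.
#' @param channels_per_chromophore Channels selected per chromophore.
#' @param select_seed Seed for the feature-type selection CV partitions.
#' @param select_iterations CV iterations for feature-type selection.
#' @return An object of class `bci_fit`: `feature_type`, `subset`
#'   (a `bci_channel_subset`), `lda` (a `bci_lda`), the accumulated
#'   `trials` and `labels`, and bookkeeping fields.
#' @examples
#' \donttest{
#' s <- generate_session(params = synthetic_params(effect_size = 2), seed = 1)
#' trials <- slice_trials(preprocess(s$recording))
#' fit <- bci_fit(trials, feature_type = "mean")
#' fit
#' }
#' @export
bci_fit <- function(trials, feature_type = NULL, fs = 10,
                    channels_per_chromophore = 5, select_seed = 1,
                    select_iterations = 10) {
  labels <- trial_labels(trials)
  if (is.null(feature_type)) {
    feature_type <- as.character(
      select_feature_type(trials, iterations = select_iterations,
                          seed = select_seed, fs = fs))
  }
  fm <- build_feature_matrix(trials, feature_type, fs)
  subset <- select_channels(fm, labels, target = channels_per_chromophore)
  lda <- train_lda(fm[, subset$columns, drop = FALSE], labels)
  structure(list(feature_type = feature_type, subset = subset, lda = lda,
                 trials = trials, labels = labels, fs = fs,
                 channels_per_chromophore = channels_per_chromophore,
                 call = match.call()),
            class = "bci_fit")
}

#' @export
print.bci_fit <- function(x, ...) {
  cat(sprintf("bci_fit: %s feature, %d training trials (%d positive)\n",
              x$feature_type, length(x$trials), sum(x$labels == "positive")))
  print(x$subset)
  invisible(x)
}

#' @export
summary.bci_fit <- function(object, ...) {
  fm <- build_feature_matrix(object$trials, object$feature_type, object$fs)
  train_pred <- predict(object$lda, fm[, object$subset$columns, drop = FALSE])
  res <- list(fit = object,
              train_accuracy = 100 * mean(train_pred$label == object$labels),
              gamma = object$lda$gamma)
  class(res) <- "summary.bci_fit"
  res
}

#' @export
print.summary.bci_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  LDA shrinkage %.3f; training accuracy %.1f%% (resubstitution)\n",
              x$gamma, x$train_accuracy))
  invisible(x)
}

#' @export
coef.bci_fit <- function(object, ...) coef(object$lda)

#' Predict valence for new trial windows
#'
#' @param object A [bci_fit()] model.
#' @param newdata A `trial_window`, a list of them, or a samples x
#'   channels x 2 array.
#' @param ... Unused.
#' @return Data frame with one row per trial: `label`, `posterior`,
#'   `discriminant`.
#' @export
predict.bci_fit <- function(object, newdata, ...) {
  trials <- as_trial_list(newdata)
  fm <- build_feature_matrix(trials, object$feature_type, object$fs)
  predict(object$lda, fm[, object$subset$columns, drop = FALSE])
}

as_trial_list <- function(newdata) {
  if (inherits(newdata, "trial_window")) return(list(newdata))
  if (is.array(newdata) && length(dim(newdata)) == 3) {
    dimnames(newdata)[[3]] <- c("hbo", "hbr")
    return(list(structure(list(data = newdata, label = NA_character_,
                               block = NA_integer_, trial = NA_integer_),
                          class = "trial_window")))
  }
  if (is.list(newdata)) return(newdata)
  stop("predict.bci_fit: cannot interpret newdata as trial windows")
}

#' Retrain the pipeline on additional labeled trials
#'
#' Implements block-wise adaptive retraining: the accumulated training set
#' grows by the new trials, channel selection is re-run on the full
#' accumulated set, and the LDA is retrained. The feature type chosen from
#' the first session is kept frozen. The input object is not modified.
#'
#' @param object A [bci_fit()].
#' @param new_trials List of labeled `trial_window` objects (e.g. one
#'   completed block).
#' @param ... Unused.
#' @return A new `bci_fit`.
#' @export
update.bci_fit <- function(object, new_trials, ...) {
  bci_fit(c(object$trials, as_trial_list(new_trials)),
          feature_type = object$feature_type, fs = object$fs,
          channels_per_chromophore = object$channels_per_chromophore)
}

#' @rdname update.bci_fit
#' @param state A `bci_fit` (the current pipeline state).
#' @param block_trials The completed block's labeled trials.
#' @export
retrain_after_block <- function(state, block_trials) {
  update(state, block_trials)
}

#' Plot class-average responses of the selected channels
#'
#' Trial-averaged oxygenated-hemoglobin time courses of the selected
#' channels, by valence class, from the accumulated training trials.
#'
#' @param x A [bci_fit()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bci_fit <- function(x, chromophore = c("hbo", "hbr"), ...) {
  chromophore <- match.arg(chromophore)
  chans <- x$subset[[chromophore]]
  tt <- (seq_len(dim(x$trials[[1]]$data)[1]) - 1) / x$fs
  avg <- function(lab) {
    arr <- sapply(x$trials[trial_labels(x$trials) == lab],
                  function(tr) rowMeans(tr$data[, chans, chromophore, drop = FALSE]))
    rowMeans(arr)
  }
  graphics::matplot(tt, cbind(avg("positive"), avg("negative")), type = "l",
                    lty = 1, col = c("forestgreen", "firebrick"),
                    xlab = "time in trial (s)",
                    ylab = paste("mean", toupper(chromophore), "(uM*mm)"), ...)
  graphics::legend("topleft", c("positive", "negative"), lty = 1,
                   col = c("forestgreen", "firebrick"), bty = "n")
  invisible(x)
}
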