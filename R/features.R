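#' The seven temporal feature types
#'
#' Per-trial features computed over the 20-s response window of each
#' channel/chromophore series: mean, least-squares slope, moving slope
#' (mean of least-squares slopes over 4-s sub-windows whose consecutive
#' placements overlap by 0.5 s, i.e. a 3.5-s advance), sample variance
#' (n-1 divisor), root mean square, sample skewness (third standardized
#' moment) and excess kurtosis (fourth standardized moment minus 3).
#' Skewness and kurtosis of a zero-variance window are defined as 0.
#'
#' @return Character vector of the seven feature type ids, in the canonical
#'   (tie-breaking) order.
#' @export
feature_types <- function() {
  c("mean", "slope", "moving_slope", "variance", "rms", "skewness", "kurtosis")
}

#' Compute one temporal feature of a window
#'
#' @param x Numeric vector (one channel/chromophore series of a trial
#'   window); must be free of non-finite values.
#' @param ftype One of [feature_types()].
#' @param fs Sampling rate, Hz (slopes are per second).
#' @param window_s,overlap_s Moving-slope sub-window length and overlap,
#'   seconds. A window shorter than `window_s` is reduced to a single
#'   sub-window spanning the available data.
#' @return Scalar feature value.
#' @examples
#' compute_feature(seq(0, 1.99, 0.01) * 3, "slope", fs = 100)  # 3
#' @export
compute_feature <- function(x, ftype = feature_types(), fs = 10,
                            window_s = 4, overlap_s = 0.5) {
  ftype <- match.arg(ftype)
  if (any(!is.finite(x))) stop("compute_feature: non-finite values in window")
  n <- length(x)
  if (n < 2) stop("compute_feature: window too short")
  tt <- (seq_len(n) - 1) / fs
  ls_slope <- function(y, t) {
    tc <- t - mean(t)
    sum(tc * y) / sum(tc^2)
  }
  switch(ftype,
    mean = mean(x),
    slope = ls_slope(x, tt),
    moving_slope = {
      w <- as.integer(round(window_s * fs))
      adv <- as.integer(round((window_s - overlap_s) * fs))
      if (n < w) {
        ls_slope(x, tt)
      } else {
        starts <- seq(1L, n - w + 1L, by = adv)
        mean(vapply(starts, function(s)
          ls_slope(x[s:(s + w - 1L)], tt[s:(s + w - 1L)]), 0))
      }
    },
    variance = stats::var(x),
    rms = sqrt(mean(x^2)),
    skewness = {
      m2 <- mean((x - mean(x))^2)
      if (m2 == 0) 0 else mean((x - mean(x))^3) / m2^1.5
    },
    kurtosis = {
      m2 <- mean((x - mean(x))^2)
      if (m2 == 0) 0 else mean((x - mean(x))^4) / m2^2 - 3
    })
}

# vectorized feature computation over the columns of a samples x series matrix
features_of_matrix <- function(mat, ftype, fs = 10, window_s = 4, overlap_s = 0.5) {
  n <- nrow(mat)
  tt <- (seq_len(n) - 1) / fs
  tc <- tt - mean(tt)
  switch(ftype,
    mean = colMeans(mat),
    slope = as.numeric(crossprod(tc, mat)) / sum(tc^2),
    moving_slope = {
      w <- as.integer(round(window_s * fs))
      adv <- as.integer(round((window_s - overlap_s) * fs))
      if (n < w) {
        as.numeric(crossprod(tc, mat)) / sum(tc^2)
      } else {
        starts <- seq(1L, n - w + 1L, by = adv)
        tw <- (seq_len(w) - 1) / fs
        twc <- tw - mean(tw)
        sl <- sapply(starts, function(s)
          as.numeric(crossprod(twc, mat[s:(s + w - 1L), , drop = FALSE])) / sum(twc^2))
        if (is.null(dim(sl))) sl else rowMeans(sl)
      }
    },
    variance = apply(mat, 2, stats::var),
    rms = sqrt(colMeans(mat^2)),
    skewness = {
      ctr <- sweep(mat, 2, colMeans(mat))
      m2 <- colMeans(ctr^2); m3 <- colMeans(ctr^3)
      ifelse(m2 == 0, 0, m3 / m2^1.5)
    },
    kurtosis = {
      ctr <- sweep(mat, 2, colMeans(mat))
      m2 <- colMeans(ctr^2); m4 <- colMeans(ctr^4)
      ifelse(m2 == 0, 0, m4 / m2^2 - 3)
    })
}

#' Assemble the trials x features matrix for one feature type
#'
#' Column order is fixed and documented: channels 1..22 of the oxygenated
#' chromophore, then channels 1..22 of the deoxygenated chromophore (44
#' columns for the standard montage). Per-column provenance (channel,
#' chromophore, feature type) and per-row labels are attached as
#' attributes.
#'
#' @param trials List of `trial_window` objects (from [slice_trials()]),
#'   all of the same shape.
#' @param ftype One of [feature_types()].
#' @param fs Sampling rate, Hz.
#' @return A numeric matrix of class `bci_features` with attributes
#'   `provenance` (data frame: `channel`, `chromophore`, `feature`) and
#'   `labels` (character).
#' @export
build_feature_matrix <- function(trials, ftype = feature_types(), fs = 10) {
  ftype <- match.arg(ftype)
  if (!length(trials)) stop("build_feature_matrix: no trials")
  shapes <- vapply(trials, function(tr) paste(dim(tr$data), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("build_feature_matrix: trials have mixed shapes: ",
         paste(unique(shapes), collapse = ", "))
  n_ch <- dim(trials[[1]]$data)[2]
  vals <- t(vapply(trials, function(tr) {
    flat <- cbind(tr$data[, , "hbo"], tr$data[, , "hbr"])
    features_of_matrix(flat, ftype, fs)
  }, numeric(2 * n_ch)))
  if (any(!is.finite(vals)))
    stop("build_feature_matrix: non-finite feature values")
  prov <- data.frame(channel = rep(seq_len(n_ch), 2),
                     chromophore = rep(c("hbo", "hbr"), each = n_ch),
                     feature = ftype)
  colnames(vals) <- paste0("ch", sprintf("%02d", prov$channel), "_",
                           prov$chromophore)
  structure(vals, provenance = prov, labels = trial_labels(trials),
            feature_type = ftype, class = c("bci_features", class(vals)))
}

#' @export
`[.bci_features` <- function(x, i, j, ..., drop = FALSE) {
  mat <- x
  oldClass(mat) <- NULL
  if (missing(i)) i <- seq_len(nrow(mat))
  if (missing(j)) j <- seq_len(ncol(mat))
  prov <- attr(x, "provenance")
  structure(mat[i, j, drop = FALSE],
            provenance = prov[j, , drop = FALSE],
            labels = attr(x, "labels")[i],
            feature_type = attr(x, "feature_type"),
            class = c("bci_features", "matrix", "array"))
}

#' Pick the most discriminative feature type from first-session data
#'
#' Evaluates each of the seven feature types by repeated stratified k-fold
#' cross-validation of the full pipeline (channel selection inside folds,
#' then LDA) and returns the type with the highest mean accuracy. Ties are
#' broken by the documented [feature_types()] order.
#'
#' @param trials List of labeled trial windows (the first session).
#' @param folds,iterations Cross-validation protocol (default 10 x 10).
#' @param seed Integer seed for the fold partitions.
#' @param fs Sampling rate, Hz.
#' @return The winning feature type id; the per-type mean accuracies are
#'   attached as attribute `accuracy`.
#' @export
select_feature_type <- function(trials, folds = 10, iterations = 10,
                                seed = 1, fs = 10) {
  acc <- vapply(feature_types(), function(ft)
    cross_validate(trials, feature_type = ft, folds = folds,
                   iterations = iterations, seed = seed, fs = fs)$mean_accuracy,
    0)
  winner <- feature_types()[which.max(acc)]  # which.max takes first on ties
  structure(winner, accuracy = acc)
}
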