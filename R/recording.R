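#' Session protocol configuration
#'
#' The standard protocol is 5 blocks, each a 30-s baseline followed by 12
#' trials of a 20-s emotion-induction response period and a 20-s rest, i.e.
#' 60 task trials per session (30 positive, 30 negative), sampled at 10 Hz,
#' with online predictions on cumulative 2-s segments.
#'
#' @param blocks Blocks per session.
#' @param trials_per_block Trials within one block.
#' @param positives_per_block Positive-valence trials per block (the rest
#'   are negative).
#' @param baseline_s,task_s,rest_s Segment durations in seconds.
#' @param fs Sampling rate in Hz.
#' @param segment_s Online prediction segment length in seconds.
#' @return A `session_config` list.
#' @examples
#' cfg <- session_config()
#' cfg$blocks * cfg$trials_per_block  # 60 trials
#' @export
session_config <- function(blocks = 5, trials_per_block = 12,
                           positives_per_block = trials_per_block / 2,
                           baseline_s = 30, task_s = 20, rest_s = 20,
                           fs = 10, segment_s = 2) {
  cfg <- list(blocks = as.integer(blocks),
              trials_per_block = as.integer(trials_per_block),
              positives_per_block = as.integer(positives_per_block),
              baseline_s = baseline_s, task_s = task_s, rest_s = rest_s,
              fs = fs, segment_s = segment_s)
  if (cfg$blocks < 1 || cfg$trials_per_block < 1)
    stop("session_config: blocks and trials_per_block must be positive")
  if (cfg$positives_per_block < 0 || cfg$positives_per_block > cfg$trials_per_block)
    stop("session_config: positives_per_block out of range")
  if (any(unlist(cfg[c("baseline_s", "task_s", "rest_s", "fs", "segment_s")]) <= 0))
    stop("session_config: durations and sampling rate must be positive")
  class(cfg) <- "session_config"
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "session_config: %d blocks x [%gs baseline + %d x (%gs task + %gs rest)] at %g Hz (%d trials)\n",
    x$blocks, x$baseline_s, x$trials_per_block, x$task_s, x$rest_s, x$fs,
    x$blocks * x$trials_per_block))
  invisible(x)
}

#' @rdname session_config
#' @param path YAML file path.
#' @export
read_session_config <- function(path) {
  do.call(session_config, yaml::read_yaml(path))
}

#' @rdname session_config
#' @param config A `session_config`.
#' @export
write_session_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# total scheduled session duration, seconds
session_duration_s <- function(config) {
  config$blocks *
    (config$baseline_s + config$trials_per_block * (config$task_s + config$rest_s))
}

#' Build the event-marker table for a session schedule
#'
#' Onsets are 0-based samples; windows are half-open `[onset, onset + duration)`.
#'
#' @param config A [session_config()].
#' @param labels Character vector of task valence labels
#'   (`"positive"`/`"negative"`), one per trial, in presentation order.
#' @return Data frame with columns `onset`, `duration`, `kind`
#'   (baseline/task/rest), `valence`, `block`, `trial`.
#' @export
session_markers <- function(config, labels) {
  n_trials <- config$blocks * config$trials_per_block
  if (length(labels) != n_trials)
    stop("session_markers: need ", n_trials, " labels, got ", length(labels))
  fs <- config$fs
  rows <- list()
  pos <- 0L
  trial <- 0L
  for (b in seq_len(config$blocks)) {
    rows[[length(rows) + 1L]] <- data.frame(
      onset = pos, duration = as.integer(config$baseline_s * fs),
      kind = "baseline", valence = NA_character_, block = b, trial = NA_integer_)
    pos <- pos + as.integer(config$baseline_s * fs)
    for (k in seq_len(config$trials_per_block)) {
      trial <- trial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        onset = pos, duration = as.integer(config$task_s * fs),
        kind = "task", valence = labels[trial], block = b, trial = trial)
      pos <- pos + as.integer(config$task_s * fs)
      rows[[length(rows) + 1L]] <- data.frame(
        onset = pos, duration = as.integer(config$rest_s * fs),
        kind = "rest", valence = NA_character_, block = b, trial = NA_integer_)
      pos <- pos + as.integer(config$rest_s * fs)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a multichannel fNIRS recording
#'
#' @param data Numeric array, samples x channels x 2 chromophores
#'   (concentration changes, uM*mm). The chromophore slices are `"hbo"`
#'   (oxygenated) and `"hbr"` (deoxygenated hemoglobin).
#' @param fs Sampling rate, Hz.
#' @param montage An `fnirs_montage`; channel count must match `dim(data)[2]`.
#' @param markers Event-marker data frame as from [session_markers()].
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(data, fs = 10, montage = build_standard_montage(),
                           markers = NULL) {
  if (length(dim(data)) != 3L || dim(data)[3] != 2L)
    stop("nirs_recording: data must be samples x channels x 2 chromophores")
  if (dim(data)[2] != nrow(montage$channels))
    stop("nirs_recording: data has ", dim(data)[2],
         " channels but montage defines ", nrow(montage$channels))
  dimnames(data)[[3]] <- c("hbo", "hbr")
  rec <- structure(list(data = data, fs = fs, montage = montage,
                        markers = markers), class = "nirs_recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  m <- rec$markers
  if (!is.null(m) && nrow(m)) {
    if (any(diff(m$onset) <= 0))
      stop("nirs_recording: marker onsets must be strictly increasing")
    if (any(m$onset < 0) || any(m$onset + m$duration > dim(rec$data)[1]))
      stop("nirs_recording: marker extends beyond the recorded samples")
  }
  invisible(rec)
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("nirs_recording: %d samples (%.1f s) x %d channels x 2 chromophores at %g Hz\n",
              d[1], d[1] / x$fs, d[2], x$fs))
  if (!is.null(x$markers))
    cat("  markers:", sum(x$markers$kind == "task"), "task /",
        sum(x$markers$kind == "baseline"), "baseline /",
        sum(x$markers$kind == "rest"), "rest\n")
  if (isTRUE(attr(x, "preprocessed"))) cat("  preprocessed (filtered + baseline-corrected)\n")
  invisible(x)
}

marker_sidecar_path <- function(path) {
  paste0(sub("\\.csv$", "", path), "_markers.csv")
}

#' Write a recording to the columnar CSV dialect
#'
#' One row per sample with columns `t, ch01_hbo..chNN_hbo, ch01_hbr..chNN_hbr`,
#' plus a sidecar marker file (`<path minus .csv>_markers.csv`) with columns
#' `onset_s, duration_s, kind, valence, block, trial`.
#'
#' @param rec A [nirs_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n_ch <- dim(rec$data)[2]
  chn <- sprintf("ch%02d", seq_len(n_ch))
  df <- data.frame((seq_len(dim(rec$data)[1]) - 1) / rec$fs,
                   rec$data[, , "hbo"], rec$data[, , "hbr"])
  names(df) <- c("t", paste0(chn, "_hbo"), paste0(chn, "_hbr"))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(rec$markers)) {
    m <- rec$markers
    write.csv(data.frame(onset_s = m$onset / rec$fs,
                         duration_s = m$duration / rec$fs,
                         kind = m$kind, valence = m$valence,
                         block = m$block, trial = m$trial),
              marker_sidecar_path(path), row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads the columnar CSV dialect written by [write_recording()]. The
#' sampling rate is recovered from the `t` column; channel columns are
#' checked against the montage and a format error names any missing column.
#'
#' @param path Input file path.
#' @param format Only `"csv"` is supported.
#' @param montage Montage the file is expected to conform to.
#' @return A [nirs_recording()].
#' @export
read_recording <- function(path, format = c("csv", "snirf"),
                           montage = build_standard_montage()) {
  format <- match.arg(format)
  if (format == "snirf")
    stop("read_recording: SNIRF input is not supported; ",
         "use the columnar CSV dialect (see write_recording)")
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  n_ch <- nrow(montage$channels)
  chn <- sprintf("ch%02d", seq_len(n_ch))
  want <- c("t", paste0(chn, "_hbo"), paste0(chn, "_hbr"))
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop("read_recording: file is missing required column(s): ",
         paste(missing, collapse = ", "))
  fs <- 1 / stats::median(diff(df$t))
  fs <- round(fs, 6)
  n <- nrow(df)
  data <- array(NA_real_, c(n, n_ch, 2), dimnames = list(NULL, NULL, c("hbo", "hbr")))
  data[, , "hbo"] <- as.matrix(df[, paste0(chn, "_hbo")])
  data[, , "hbr"] <- as.matrix(df[, paste0(chn, "_hbr")])
  markers <- NULL
  mp <- marker_sidecar_path(path)
  if (file.exists(mp)) {
    md <- read.csv(mp)
    markers <- data.frame(onset = as.integer(round(md$onset_s * fs)),
                          duration = as.integer(round(md$duration_s * fs)),
                          kind = md$kind, valence = md$valence,
                          block = md$block, trial = md$trial)
  }
  nirs_recording(data, fs = fs, montage = montage, markers = markers)
}

#' Slice the task trials out of a preprocessed recording
#'
#' Returns one window per task marker over the half-open sample interval
#' `[onset, onset + duration)`, with the valence label copied from the
#' marker. The recording is expected to have been preprocessed
#' ([preprocess()]) so the windows are filtered and baseline-corrected.
#'
#' @param rec A [nirs_recording()] with task markers.
#' @return A list of `trial_window` objects, each a list with `data`
#'   (samples x channels x 2), `label`, `block`, `trial`.
#' @export
slice_trials <- function(rec) {
  m <- rec$markers
  if (is.null(m)) stop("slice_trials: recording has no markers")
  tm <- m[m$kind == "task", , drop = FALSE]
  n <- dim(rec$data)[1]
  lapply(seq_len(nrow(tm)), function(i) {
    on <- tm$onset[i]; du <- tm$duration[i]
    if (on + du > n)
      stop("slice_trials: trial ", tm$trial[i], " extends past the recording end")
    structure(list(data = rec$data[(on + 1):(on + du), , , drop = FALSE],
                   label = tm$valence[i], block = tm$block[i],
                   trial = tm$trial[i]),
              class = "trial_window")
  })
}

#' @export
print.trial_window <- function(x, ...) {
  cat(sprintf("trial_window: %d samples, label %s (block %d, trial %d)\n",
              dim(x$data)[1], x$label, x$block, x$trial))
  invisible(x)
}

trial_labels <- function(trials) vapply(trials, `[[`, character(1), "label")
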