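# Small protocol for fast tests: 2 blocks x 6 trials (3 positive each),
# same segment durations as the standard protocol.
small_config <- function() session_config(blocks = 2, trials_per_block = 6)

# cache expensive shared fixtures across test files within one run
fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, expr, fixture_env)
  get(key, fixture_env)
}

default_params <- function() cached("params_e1", synthetic_params())
effect2_params <- function() cached("params_e2", synthetic_params(effect_size = 2))
null_params <- function() cached("params_e0", synthetic_params(effect_size = 0))

# a preprocessed small session with a planted effect, plus its trials
small_session <- function(seed = 7, params = effect2_params()) {
  cached(paste0("small_", seed, "_", params$effect_size), {
    s <- generate_session(small_config(), params, seed = seed)
    pre <- preprocess(s$recording)
    list(raw = s$recording, pre = pre, trials = slice_trials(pre),
         truth = s$truth)
  })
}

# iid-Gaussian feature matrix with optional mean shift on given hbo channels
iid_features <- function(n = 24, shift = 0, shift_channels = integer(0),
                         seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 44), n)
  prov <- data.frame(channel = rep(1:22, 2),
                     chromophore = rep(c("hbo", "hbr"), each = 22),
                     feature = "mean")
  colnames(X) <- paste0("ch", sprintf("%02d", prov$channel), "_",
                        prov$chromophore)
  y <- rep(c("positive", "negative"), length.out = n)
  X[y == "positive", shift_channels] <- X[y == "positive", shift_channels] + shift
  structure(X, provenance = prov, labels = y, feature_type = "mean",
            class = c("bci_features", "matrix", "array"))
}

# raw trial windows with a constant offset planted on some channels for the
# positive class (discriminable by the mean feature only)
offset_trials <- function(n = 24, shift = 0.8, channels = 1:5, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- if (i %% 2 == 1) "positive" else "negative"
    arr <- array(rnorm(200 * 22 * 2, sd = 1), c(200, 22, 2),
                 dimnames = list(NULL, NULL, c("hbo", "hbr")))
    if (lab == "positive") arr[, channels, ] <- arr[, channels, ] + shift
    structure(list(data = arr, label = lab, block = (i - 1) %/% 12 + 1,
                   trial = i), class = "trial_window")
  })
}
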