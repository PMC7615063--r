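# shared fixtures and independent oracles used across test files

# brute-force DFT-sum power: the O(n^2)-style direct evaluation of
# |sum_j x_j W_n^{(j-1)(f-1)}|^2, independent of the fft-based implementation
brute_psd <- function(x, freq, srate) {
  n <- length(x)
  k <- freq * n / srate
  j <- seq_len(n) - 1
  Mod(sum(x * exp(-2i * pi * k * j / n)))^2
}

# a small, cheap profile for tests that only need structure, not the
# calibrated SNR targets (keeps the suite fast)
quick_profile <- function(seed = 1L, ...) {
  subject_profile(seed = seed, ...)
}

# a strong, nearly noise-free profile for closed-loop oracle runs
strong_profile <- function(seed = 1L) {
  subject_profile(amp_56 = 3, amp_60 = 3, attention_gain = 2,
                  noise_scale = 0.05, alpha_amp = 0.05, blink_rate = 0,
                  neural_lag_s = 0, seed = seed)
}

# cache expensive shared fixtures within one test run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one default-profile training session + features + decoder, shared by
# several files
default_session <- function() cached("session", {
  p <- subject_profile(seed = 101L)
  simulate_training_session(p)
})

default_features <- function() cached("features", {
  training_features(default_session())
})

default_decoder <- function() cached("decoder", {
  tf <- default_features()
  rift_decoder(tf$x, tf$y, seed = 101L)
})

# build a rift_epochs object directly from a per-trial generator function
synthetic_epochs <- function(gen, n_trials = 4, n_channels = 1, duration = 1.5,
                             srate = 1000, labels = NULL) {
  n <- round(duration * srate)
  dat <- array(0, c(n_trials, n_channels, n))
  for (i in seq_len(n_trials))
    for (c in seq_len(n_channels))
      dat[i, c, ] <- gen(n)
  structure(list(data = dat, time = (seq_len(n) - 1) / srate,
                 labels = labels %||% rep("x", n_trials), srate = srate,
                 channel_names = paste0("ch", seq_len(n_channels)),
                 n_dropped = 0L),
            class = "rift_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
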