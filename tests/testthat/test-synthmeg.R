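test_that("training session has the fixed trial protocol", {
  sess <- default_session()
  rec <- sess$recording
  expect_equal(length(sess$labels), 80)
  expect_equal(sum(sess$labels == "left"), 40)
  expect_equal(sum(sess$labels == "right"), 40)
  onsets <- rec$events[rec$events$code %in% c(21L, 22L), ]
  trial_starts <- rec$events[rec$events$code == 1L, ]
  offsets <- rec$events[rec$events$code == 3L, ]
  expect_equal(nrow(onsets), 80)
  # 1 s baseline between trial onset and tagging onset, 2 s of tagging
  expect_true(all(onsets$sample - trial_starts$sample == 1000))
  expect_true(all(offsets$sample - onsets$sample == 2000))
  # event-coded sides match the returned labels
  expect_equal(ifelse(onsets$code == 21L, "left", "right"),
               as.character(sess$labels))
})

test_that("training session is bit-identical under the same seed", {
  p <- quick_profile(seed = 77)
  a <- simulate_training_session(p, n_trials = 4)
  b <- simulate_training_session(p, n_trials = 4)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$labels, b$labels)
  c <- simulate_training_session(quick_profile(seed = 78), n_trials = 4)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("tagging produces narrowband peaks absent during baseline", {
  sess <- default_session()
  rec <- sess$recording
  onsets <- rec$events[rec$events$code %in% c(21L, 22L), "sample"]
  peak_ratio <- function(spans_start, f, ch) {
    # mean power at f vs mean of +-2 Hz neighbours, averaged over trials
    p <- sapply(spans_start, function(s0) {
      w <- rec$data[ch, s0 + 0:999]
      c(psd_at(w, f - 2), psd_at(w, f), psd_at(w, f + 2))
    })
    m <- rowMeans(p)
    m[2] / (0.5 * (m[1] + m[3]))
  }
  # each frequency assessed on a channel whose gain favours it:
  # MRO11 (ch 5) is 56-dominant, MLO11 (ch 1) is 60-dominant
  tag_ratio56 <- peak_ratio(onsets + 1000, 56, 5)  # second half of tagging
  base_ratio56 <- peak_ratio(onsets - 1000, 56, 5) # baseline second
  expect_gt(tag_ratio56, 2)
  expect_lt(base_ratio56, 1.5)
  expect_gt(peak_ratio(onsets + 1000, 60, 1), 1.3)
  expect_lt(peak_ratio(onsets - 1000, 60, 1), 1.5)
})

test_that("attention modulation raises the attended frequency's power", {
  sess <- default_session()
  rec <- sess$recording
  onsets <- rec$events[rec$events$code %in% c(21L, 22L), "sample"]
  left <- sess$labels == "left"
  p56 <- sapply(onsets, function(s0)
    mean(sapply(5:7, function(ch) psd_at(rec$data[ch, s0 + 1000:1999], 56))))
  p60 <- sapply(onsets, function(s0)
    mean(sapply(1:3, function(ch) psd_at(rec$data[ch, s0 + 1000:1999], 60))))
  expect_gt(mean(p56[left]), mean(p56[!left]))   # 56 Hz up when left attended
  expect_gt(mean(p60[!left]), mean(p60[left]))   # 60 Hz up when right attended
})

test_that("attention_gain = 1 removes the left/right power difference", {
  p <- quick_profile(seed = 5, attention_gain = 1)
  sess <- simulate_training_session(p)
  rec <- sess$recording
  onsets <- rec$events[rec$events$code %in% c(21L, 22L), "sample"]
  left <- sess$labels == "left"
  p56 <- sapply(onsets, function(s0) psd_at(rec$data[5, s0 + 1000:1999], 56))
  expect_gt(t.test(p56[left], p56[!left])$p.value, 0.001)
})

test_that("background noise is 1/f-like with an alpha bump", {
  set.seed(31)
  # averaged periodogram over independent 2-s realisations
  n <- 2000
  spec <- rowMeans(replicate(30, Mod(fft(pink_noise(n)))[2:160]^2))
  f <- (1:159) * 0.5
  fit <- lm(log10(spec) ~ log10(f), subset = f >= 2 & f <= 80)
  expect_gt(coef(fit)[2], -2)
  expect_lt(coef(fit)[2], -0.5)
  # alpha bump: background channel spectrum peaks near 10 Hz relative to the
  # 1/f trend
  bg <- rowMeans(replicate(20,
    Mod(fft(riftbci:::background_channel(n, 1000, 1, 1.5)))[2:160]^2))
  band <- function(lo, hi) mean(bg[f >= lo & f <= hi])
  expect_gt(band(9, 11), 3 * band(15, 20))
})

test_that("pink noise spectral density does not depend on generated length", {
  set.seed(12)
  # power at the 56 Hz bin of a 1-s window, from 1-s vs 30-s generation;
  # bin powers are exponential (CV = 1), so average many windows
  p_short <- mean(replicate(150, psd_at(pink_noise(1000), 56)))
  p_long <- mean(replicate(4, {
    long <- pink_noise(30000)
    mean(sapply(0:29, function(k) psd_at(long[k * 1000 + 1:1000], 56)))
  }))
  expect_equal(p_short / p_long, 1, tolerance = 0.3)
})

test_that("eye traces satisfy the fixation-containment conditions", {
  p <- quick_profile(seed = 2)
  set.seed(2)
  eye <- simulate_eye_trace(p, duration = 120)
  fr <- gaze_containment(eye$gaze_x)
  expect_gte(fr[["within_1deg"]], 0.95)
  expect_lt(1 - fr[["within_2deg"]], 0.03)   # ~1 % outside 2 degrees
  expect_gt(sum(is.na(eye$gaze_x)), 0)       # blinks present at 6/min
  # blink spans are the NA spans
  expect_true(all(is.na(eye$gaze_x[eye$blinks[1, "start"]:eye$blinks[1, "end"]])))
})

test_that("blink_rate = 0 produces gap-free gaze", {
  p <- quick_profile(seed = 3, blink_rate = 0)
  set.seed(3)
  eye <- simulate_eye_trace(p, duration = 30)
  expect_false(anyNA(eye$gaze_x))
  expect_false(anyNA(eye$gaze_y))
  expect_equal(nrow(eye$blinks), 0)
})

test_that("game stream yields 3000 blocks for a 5-minute session", {
  p <- quick_profile(seed = 4, blink_rate = 0)
  stream <- simulate_game_stream(p, duration = 300)
  expect_equal(attr(stream, "n_blocks"), 3000)
  blk <- stream("left")
  expect_identical(dim(blk), c(10L, 100L))
  # a short stream ends cleanly with NULL
  s2 <- simulate_game_stream(p, duration = 1)
  for (i in 1:10) expect_false(is.null(s2("left")))
  expect_null(s2("left"))
})

test_that("a fixed-left policy tilts 56 Hz power above 60 Hz on 56-dominant channels", {
  p <- quick_profile(seed = 6, blink_rate = 0)
  stream <- simulate_game_stream(p, duration = 30)
  samples <- matrix(0, 7, 30 * 1000)
  i <- 0L
  repeat {
    blk <- stream("left")
    if (is.null(blk)) break
    samples[, i * 100 + 1:100] <- blk[1:7, ]
    i <- i + 1L
  }
  p56 <- mean(sapply(0:28, function(k)
    mean(sapply(5:7, function(ch) psd_at(samples[ch, k * 1000 + 1:1000], 56)))))
  p60 <- mean(sapply(0:28, function(k)
    mean(sapply(5:7, function(ch) psd_at(samples[ch, k * 1000 + 1:1000], 60)))))
  expect_gt(p56, p60)
})

test_that("with zero lag an attention switch crosses over within one window", {
  p <- strong_profile(seed = 8)
  stream <- simulate_game_stream(p, duration = 12)
  n <- 12 * 1000
  x <- matrix(0, 7, n)
  for (k in 0:119) {
    side <- if (k < 60) "left" else "right"
    x[, k * 100 + 1:100] <- stream(side)[1:7, ]
  }
  # oracle: sliding-window PSD asymmetry on the midline channel, whose equal
  # gains make the attended frequency dominate
  asym <- function(s0) psd_at(x[4, s0 + 0:999], 56) - psd_at(x[4, s0 + 0:999], 60)
  expect_gt(asym(4001), 0)     # well before the switch at t = 6 s
  expect_lt(asym(7001), 0)     # one window after the switch
})

test_that("amplitude calibration recovers targets, is monotone, and anchors at 1", {
  p <- quick_profile(seed = 10)
  expect_equal(calibrate_amplitude(p, target_snr = 1, freq = 56), 0)
  amps <- sapply(c(1.5, 2.5, 4), function(s)
    calibrate_amplitude(p, target_snr = s, freq = 56, n_windows = 200))
  expect_true(all(diff(amps) > 0))
  # measurement at the calibrated amplitude reproduces the target (a light
  # version of the acceptance-level +-0.2 check, which uses more windows)
  p$amp_56 <- amps[2]
  set.seed(123)
  expect_equal(measure_snr(p, freq = 56, n_windows = 300), 2.5, tolerance = 0.15)
})
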