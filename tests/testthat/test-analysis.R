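make_rec <- function(x, srate = 1000, events = NULL) {
  recording(matrix(x, 1), srate = srate, channel_names = "ch1",
            channel_kinds = "meg", events = events)
}

test_that("preprocessing notches 50 Hz, removes drift, and passes 56 Hz", {
  t <- (0:9999) / 1000
  rms <- function(v) sqrt(mean(v[1000:9000]^2))   # avoid filter edges
  r50 <- preprocess(make_rec(sin(2 * pi * 50 * t)))
  expect_lt(rms(r50$data[1, ]) / rms(sin(2 * pi * 50 * t)), 10^(-20 / 20))
  rdrift <- preprocess(make_rec(sin(2 * pi * 0.2 * t)))
  expect_lt(rms(rdrift$data[1, ]), 0.1)
  r56 <- preprocess(make_rec(sin(2 * pi * 56 * t)))
  expect_equal(rms(r56$data[1, ]) / rms(sin(2 * pi * 56 * t)), 1,
               tolerance = 0.05)
  expect_error(preprocess(make_rec(rnorm(1000), srate = 150)), "low")
})

test_that("epoching cuts labelled windows and reports dropped trials", {
  sess <- default_session()
  ep <- epoch_recording(sess$recording, c(21L, 22L), c(-1, 3))
  expect_identical(dim(ep$data), c(80L, 7L, 4000L))
  expect_equal(ep$n_dropped, 0L)
  expect_equal(range(ep$time), c(-1, 3 - 1e-3))
  expect_equal(grepl("left", ep$labels), as.vector(sess$labels == "left"))
  # an event too close to the recording start is dropped and counted
  ev <- data.frame(sample = c(100L, 5000L), code = 9L, label = "z")
  rec <- make_rec(rnorm(10000), events = ev)
  ep2 <- epoch_recording(rec, 9L, c(-3, 1), channels = 1)
  expect_equal(dim(ep2$data)[1], 1L)
  expect_equal(ep2$n_dropped, 1L)
  expect_warning(epoch_recording(rec, 55L, c(-1, 1), channels = 1), "no usable")
})

test_that("the TFR uses 20-cycle windows and localizes a tagging burst in time", {
  set.seed(41)
  # 56 Hz burst over t in [0.25, 0.75) on a weak noise floor
  ep <- synthetic_epochs(function(n) {
    t <- (seq_len(n) - 1) / 1000
    rnorm(n, sd = 0.3) + sin(2 * pi * 56 * t) * (t >= 0.25 & t < 0.75)
  }, n_trials = 6, duration = 1.5)
  tfr <- tfr_hanning(ep)
  expect_equal(diff(tfr$times)[1], 0.025, tolerance = 1e-9)
  i56 <- which(tfr$freqs == 56)
  during <- mean(tfr$power[1, i56, tfr$times > 0.4 & tfr$times < 0.6])
  after <- mean(tfr$power[1, i56, tfr$times > 1.1 & tfr$times < 1.35],
                na.rm = TRUE)
  expect_gt(during, 10 * after)
  # edges without a full 20-cycle window are NA, not zero
  expect_true(anyNA(tfr$power[1, i56, ]))
  expect_error(tfr_hanning(synthetic_epochs(rnorm, duration = 0.3)), "shorter")
})

test_that("TFR of pure sinusoids peaks at the nearest frequency-axis bin", {
  for (f0 in c(41, 50, 63, 70)) {
    ep <- synthetic_epochs(function(n) sin(2 * pi * f0 * (seq_len(n) - 1) / 1000),
                           n_trials = 2, duration = 1.5)
    tfr <- tfr_hanning(ep)
    mid <- which.min(abs(tfr$times - 0.75))
    fpk <- tfr$freqs[which.max(tfr$power[1, , mid])]
    expect_lte(abs(fpk - f0), min(abs(tfr$freqs - f0)) + 1e-9)
  }
})

test_that("TFR of white noise shows no systematic spectral peak", {
  set.seed(42)
  ep <- synthetic_epochs(function(n) rnorm(n), n_trials = 8, duration = 1.5)
  tfr <- tfr_hanning(ep)
  p <- tfr$power[1, , ]
  # bound calibrated by Monte Carlo for 8-trial averages (observed ~2.6,
  # max over 40 draws 4.0)
  expect_lt(max(p, na.rm = TRUE) / median(p, na.rm = TRUE), 6)
})

test_that("narrowband SNR follows its defining ratio", {
  expect_equal(snr(c(2, 4, 2), c(54, 56, 58), 56), 2)
  expect_equal(snr(rep(3, 5), c(52, 54, 56, 58, 60), 56), 1)
  expect_error(snr(c(2, 4, 2), c(54, 56, 58), 60), "defined")
  expect_error(snr(c(0, 4, 0), c(54, 56, 58), 56), "zero")
})

test_that("information transfer rate matches closed forms and conventions", {
  expect_equal(itr(2, 0.5, 10, 5), 0)
  expect_equal(itr(2, 1, 10, 5), 2)
  # independent evaluation of the closed form at N=2, P=0.75, S=20, T=5
  oracle <- (log2(2) + 0.75 * log2(0.75) + 0.25 * log2(0.25 / 1)) * 20 / 5
  expect_equal(itr(2, 0.75, 20, 5), oracle)
  expect_equal(itr(2, 0.75, 20, 5), 0.7549, tolerance = 1e-4)
  # strictly increasing in P above chance, linear in S/T
  ps <- seq(0.5, 1, by = 0.05)
  vals <- sapply(ps, function(p) itr(2, p, 10, 5))
  expect_true(all(diff(vals) > 0))
  expect_equal(itr(2, 0.8, 20, 5), 2 * itr(2, 0.8, 10, 5))
  expect_error(itr(2, 0.4, 10, 5), "1/N")
  # the printed variant divides (1-P) by N and is negative at chance
  expect_lt(itr(2, 0.5, 10, 5, convention = "printed"), 0)
})

test_that("sliding power is flat for a stationary sinusoid and tracks steps", {
  t <- (0:9999) / 1000
  x <- sin(2 * pi * 56 * t)
  sp <- sliding_power(x, 56)
  expect_lt(sd(sp$power) / mean(sp$power), 0.01)
  # amplitude step at t0 = 5 s: power transition completes within 1 s
  xs <- ifelse(t < 5, 1, 3) * sin(2 * pi * 56 * t)
  sps <- sliding_power(xs, 56)
  before <- sps$power[sps$time < 5]
  after <- sps$power[sps$time > 6]
  expect_equal(sd(before) / mean(before), 0, tolerance = 0.01)
  expect_equal(mean(after) / mean(before), 9, tolerance = 0.05)
})

test_that("sliding power agrees with per-step recomputation and with psd_at", {
  set.seed(43)
  x <- rnorm(4000)
  sp <- sliding_power(x, 60)
  idx <- sample(nrow(sp), 100)
  for (i in idx) {
    s_end <- round(sp$time[i] * 1000)
    expect_equal(sp$power[i], psd_at(x[(s_end - 999):s_end], 60, 1000),
                 tolerance = 1e-6)
  }
  # cross-module consistency at the final full window
  last <- sliding_power(x, 56, out_rate = 1000)
  expect_equal(last$power[nrow(last)], psd_at(x[3001:4000], 56, 1000),
               tolerance = 1e-6)
  expect_error(sliding_power(x[1:500], 56), "shorter")
  expect_error(sliding_power(x, 56.5), "bin")
})

test_that("cluster permutation finds nothing under the exact null and everything under a huge shift", {
  set.seed(44)
  a <- matrix(rnorm(10 * 50), 10)
  res0 <- cluster_permutation(a, a, n_perm = 200)
  expect_equal(nrow(res0$clusters), 0)
  b <- a + 5
  res1 <- cluster_permutation(b, a, n_perm = 500)
  expect_equal(nrow(res1$clusters), 1)
  expect_equal(res1$clusters$start, 1)
  expect_equal(res1$clusters$end, 50)
  expect_true(res1$clusters$significant)
  # near-minimal p: only the two all-same-sign flips can match the shift
  expect_lt(res1$clusters$p, 0.02)
  expect_error(cluster_permutation(a, a[, 1:10]), "shape")
  expect_warning(cluster_permutation(b, a, n_perm = 50), "coarse")
})

test_that("exact enumeration at n = 5 matches an independent sign-flip oracle", {
  set.seed(45)
  a <- matrix(rnorm(5 * 20), 5)
  b <- a + matrix(rnorm(5 * 20, 0.8), 5)
  res <- cluster_permutation(a, b, exact = TRUE)
  expect_equal(res$n_permutations, 32L)
  # oracle: enumerate all 2^5 sign patterns with independent code
  d <- a - b
  tcrit <- qt(0.975, 4)
  tstat <- function(m) apply(m, 2, function(col) t.test(col)$statistic)
  clusters_of <- function(tv) {
    lab <- ifelse(tv > tcrit, 1, ifelse(tv < -tcrit, -1, 0))
    out <- c(); cur <- 0; run <- 0
    for (i in seq_along(lab)) {
      if (lab[i] != 0 && lab[i] == cur) run <- run + tv[i]
      else {
        if (cur != 0) out <- c(out, run)
        cur <- lab[i]; run <- tv[i] * (lab[i] != 0)
      }
    }
    if (cur != 0) out <- c(out, run)
    out
  }
  null_max <- apply(expand.grid(rep(list(c(1, -1)), 5)), 1, function(s) {
    cl <- clusters_of(tstat(d * s))
    if (length(cl)) max(abs(cl)) else 0
  })
  for (j in seq_len(nrow(res$clusters))) {
    p_oracle <- mean(null_max >= abs(res$clusters$t_sum[j]))
    expect_equal(res$clusters$p[j], p_oracle, tolerance = 1e-12)
  }
  # observed clusters also match the oracle's cluster sums
  expect_equal(sort(res$clusters$t_sum), sort(clusters_of(tstat(d))),
               tolerance = 1e-9)
})

test_that("eye-position histograms bin power correctly", {
  set.seed(46)
  pw <- rexp(5000)
  h0 <- eye_power_histogram(rep(0, 5000), pw)
  expect_equal(sum(h0$n > 0), 1)
  expect_equal(h0$mean_power[h0$n > 0], mean(pw))
  gz <- runif(5000, -2, 2)
  h1 <- eye_power_histogram(gz, pw)
  expect_equal(nrow(h1), 40)
  expect_true(all(h1$n > 0))
  expect_equal(sum(h1$n), 5000)
  # gaze independent of power: no rank trend across bins
  expect_lt(abs(cor(h1$bin_centre, h1$mean_power, method = "spearman")), 0.45)
  # blinks and out-of-range samples are excluded
  gz[1:100] <- NA
  h2 <- eye_power_histogram(gz, pw)
  expect_equal(sum(h2$n), sum(!is.na(gz) & abs(gz) <= 2))
})

test_that("gaze containment fractions behave at the extremes", {
  expect_equal(unname(gaze_containment(rep(0, 100))), c(1, 1))
  g <- c(rep(0.5, 90), rep(1.5, 8), rep(3, 2))
  expect_equal(unname(gaze_containment(g)), c(0.90, 0.98))
})

test_that("long-format CSV exports cover TFR and cluster results", {
  set.seed(47)
  ep <- synthetic_epochs(function(n) rnorm(n), n_trials = 2, duration = 1)
  tfr <- tfr_hanning(ep, fmin = 50, fmax = 60, fstep = 5)
  f1 <- tempfile(fileext = ".csv")
  write_tfr_csv(tfr, f1)
  df <- read.csv(f1)
  expect_equal(nrow(df), length(tfr$freqs) * length(tfr$times))
  a <- matrix(rnorm(6 * 30), 6); b <- a + 2
  ct <- cluster_permutation(b, a, n_perm = 200)
  f2 <- tempfile(fileext = ".csv")
  write_cluster_csv(ct, f2)
  dc <- read.csv(f2)
  expect_equal(nrow(dc), 30)
  expect_true(any(!is.na(dc$cluster_id)))
})
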