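#' Offline preprocessing: band-pass and notch filtering
#'
#' Zero-phase 4th-order Butterworth band-pass between 1 and 80 Hz plus a
#' 2 Hz-wide zero-phase notch at 50 Hz (line noise), applied to the MEG
#' channels only. Deliberately minimal: no baseline correction, no artifact
#' rejection, so the offline data stay close to what the online path saw.
#'
#' @param rec A [recording()].
#' @param band Pass band in Hz (default `c(1, 80)`).
#' @param notch Notch centre in Hz (default 50; `NA` disables).
#' @param notch_width Full notch width in Hz (default 2).
#' @return The filtered [recording()].
#' @export
preprocess <- function(rec, band = c(1, 80), notch = 50, notch_width = 2) {
  stopifnot(inherits(rec, "rift_recording"))
  nyq <- rec$srate / 2
  if (rec$srate < 200 || band[2] >= nyq)
    stop("sampling rate too low for the requested band edges")
  bp <- signal::butter(4, band / nyq, type = "pass")
  use_notch <- !is.na(notch)
  if (use_notch)
    bs <- signal::butter(2, (notch + c(-1, 1) * notch_width / 2) / nyq,
                         type = "stop")
  for (ch in meg_channels(rec)) {
    x <- signal::filtfilt(bp, rec$data[ch, ])
    if (use_notch) x <- signal::filtfilt(bs, x)
    rec$data[ch, ] <- x
  }
  rec
}

#' Cut a recording into event-locked epochs
#'
#' Extracts windows relative to the events carrying the requested codes.
#' Training epochs conventionally span \[-1, +3\] s around tagging onset
#' (1 s baseline + 2 s tagging + 1 s post); game epochs span \[-3, +1\] s
#' around the collision. Events whose window exceeds the recording bounds
#' are dropped and counted.
#'
#' @param rec A [recording()].
#' @param event_codes Integer vector of event codes to lock to.
#' @param window Two-element numeric, window in seconds relative to the
#'   event sample, e.g. `c(-1, 3)`.
#' @param channels Channels to keep (default: the MEG channels).
#' @param labels Optional per-event labels (recycled from the event table's
#'   `label` column when absent).
#' @return An object of class `rift_epochs`: `data` (trials x channels x
#'   samples array), `time` (seconds relative to the event), `labels`,
#'   `srate`, `n_dropped`. With no matching events, an empty object with a
#'   warning.
#' @export
epoch_recording <- function(rec, event_codes, window, channels = NULL,
                            labels = NULL) {
  stopifnot(inherits(rec, "rift_recording"), length(window) == 2,
            window[1] < window[2])
  if (is.null(channels)) channels <- meg_channels(rec)
  if (is.character(channels)) channels <- match(channels, rec$channel_names)
  ev <- rec$events[rec$events$code %in% event_codes, , drop = FALSE]
  i0 <- round(window[1] * rec$srate)
  i1 <- round(window[2] * rec$srate) - 1L
  time <- (i0:i1) / rec$srate
  ok <- ev$sample + i0 >= 1 & ev$sample + i1 <= ncol(rec$data)
  n_dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    warning("no usable events for codes ", paste(event_codes, collapse = ","))
    return(structure(list(data = array(0, c(0, length(channels), length(time))),
                          time = time, labels = character(0), srate = rec$srate,
                          channel_names = rec$channel_names[channels],
                          n_dropped = n_dropped), class = "rift_epochs"))
  }
  dat <- array(0, c(nrow(ev), length(channels), length(time)))
  for (k in seq_len(nrow(ev)))
    dat[k, , ] <- rec$data[channels, ev$sample[k] + (i0:i1), drop = FALSE]
  if (is.null(labels)) labels <- ev$label
  structure(list(data = dat, time = time, labels = labels, srate = rec$srate,
                 channel_names = rec$channel_names[channels],
                 n_dropped = n_dropped),
            class = "rift_epochs")
}

#' @export
print.rift_epochs <- function(x, ...) {
  cat(sprintf("<rift_epochs> %d trials x %d channels x %d samples (%.2f..%.2f s, %d dropped)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time), x$n_dropped))
  invisible(x)
}

#' Time-frequency decomposition with a frequency-dependent Hanning window
#'
#' Trial-averaged spectral power between `fmin` and `fmax` using, at each
#' frequency f, a sliding Hanning-tapered window of `cycles`/f seconds
#' centred on time points spaced `step` seconds apart. Edge time points
#' whose window does not fit inside the epoch are returned as `NA`, never
#' zero-filled. Power is `|sum(x * hanning * exp(-2*pi*i*f*t))|^2`,
#' normalized so a sinusoid at an on-grid frequency yields its squared
#' amplitude independent of window length.
#'
#' @param epochs A `rift_epochs`.
#' @param fmin,fmax Frequency range in Hz (defaults 40 and 70).
#' @param fstep Frequency step in Hz (default 2).
#' @param cycles Cycles per window (default 20).
#' @param step Time step in seconds (default 0.025).
#' @return Object of class `rift_tfr`: `power` (channels x frequencies x
#'   times, trial-averaged), `freqs`, `times`, `taper = "hanning"`.
#' @export
tfr_hanning <- function(epochs, fmin = 40, fmax = 70, fstep = 2,
                        cycles = 20, step = 0.025) {
  stopifnot(inherits(epochs, "rift_epochs"), fmin > 0, fmax > fmin)
  srate <- epochs$srate
  epoch_len <- diff(range(epochs$time)) + 1 / srate
  if (epoch_len < cycles / fmin)
    stop("epochs shorter than the longest analysis window (", cycles / fmin, " s)")
  freqs <- seq(fmin, fmax, by = fstep)
  t0 <- min(epochs$time)
  times <- seq(ceiling(t0 / step) * step, max(epochs$time), by = step)
  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  n_sm <- dim(epochs$data)[3]
  # trials*channels x samples matrix for vectorized window products
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_sm)
  pow <- array(NA_real_, c(n_ch, length(freqs), length(times)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    wlen <- round(cycles / f * srate)
    taper <- hanning_taper(wlen)
    carrier <- exp(-2i * pi * f * (seq_len(wlen) - 1) / srate)
    kern <- taper * carrier
    norm <- (sum(taper) / 2)^2        # unit sinusoid -> amplitude^2 / 4
    for (ti in seq_along(times)) {
      centre <- round((times[ti] - t0) * srate) + 1L
      start <- centre - wlen %/% 2L
      if (start < 1L || start + wlen - 1L > n_sm) next   # edge: stays NA
      seg <- flat[start:(start + wlen - 1L), , drop = FALSE]
      amp2 <- Mod(crossprod(seg, kern))^2 / norm
      pow[, fi, ti] <- colMeans(matrix(amp2, n_tr, n_ch))
    }
  }
  structure(list(power = pow, freqs = freqs, times = times,
                 channel_names = epochs$channel_names, taper = "hanning"),
            class = "rift_tfr")
}

hanning_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Export a TFR as a long-format CSV
#'
#' One row per (channel, frequency, time) with the trial-averaged power.
#'
#' @param tfr A `rift_tfr`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tfr_csv <- function(tfr, path) {
  g <- expand.grid(channel = tfr$channel_names, frequency = tfr$freqs,
                   time = tfr$times, stringsAsFactors = FALSE)
  g$power <- as.vector(tfr$power)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' Narrowband signal-to-noise ratio of a power spectrum
#'
#' The tagging-response SNR: power at the tagged frequency divided by the
#' mean power at its +-2 Hz neighbours,
#' `SNR = p(f1) / (0.5 * (p(f1-2) + p(f1+2)))`. A flat spectrum gives 1.
#'
#' @param power Numeric vector of spectral power values.
#' @param freqs Frequencies (Hz) corresponding to `power`.
#' @param f1 Tagged frequency; `f1` and `f1 +- 2` must be present in `freqs`.
#' @param neighbour Offset of the flanking bins in Hz (default 2).
#' @return SNR ratio (scalar).
#' @export
snr <- function(power, freqs, f1, neighbour = 2) {
  idx <- match(c(f1 - neighbour, f1, f1 + neighbour), freqs)
  if (anyNA(idx))
    stop("spectrum must be defined at f1 and f1 +- ", neighbour, " Hz")
  denom <- 0.5 * (power[idx[1]] + power[idx[3]])
  if (denom == 0) stop("zero neighbour power: SNR undefined")
  power[idx[2]] / denom
}

#' Information transfer rate in bits per minute
#'
#' Wolpaw's ITR for an N-target selection task:
#' `bits/trial = log2(N) + P log2(P) + (1-P) log2((1-P)/(N-1))`, scaled by
#' the trial rate `S/T`. The limit P = 1 is handled exactly (the `(1-P)`
#' term vanishes). `convention = "printed"` instead divides `(1-P)` by `N`,
#' a variant that appears in some reports but is negative at chance for
#' N = 2; the Wolpaw form (zero at chance) is the default.
#'
#' @param N Number of targets (>= 2).
#' @param P Classification accuracy in `[1/N, 1]`.
#' @param S Number of trials (>= 1).
#' @param T_min Time in minutes (> 0).
#' @param convention `"wolpaw"` (default) or `"printed"`.
#' @return ITR in bits per minute.
#' @export
itr <- function(N, P, S, T_min, convention = c("wolpaw", "printed")) {
  convention <- match.arg(convention)
  stopifnot(N >= 2, S >= 1, T_min > 0)
  if (P < 1 / N || P > 1)
    stop("P must lie in [1/N, 1] for the ITR to be defined")
  denom <- if (convention == "wolpaw") N - 1 else N
  bits <- log2(N) +
    (if (P > 0) P * log2(P) else 0) +
    (if (P < 1) (1 - P) * log2((1 - P) / denom) else 0)
  bits * S / T_min
}

#' Sliding-window power at one frequency, downsampled to 100 Hz
#'
#' Power of the tagged response over a trailing (causal) 1 s window slid in
#' 1 ms steps - mirroring the online ring buffer - then decimated to
#' 100 Hz by keeping every `srate/out_rate`-th step. The window power is the
#' single-bin DFT power of [psd_at()]. Computed with a cumulative-sum
#' sliding DFT, identical (to floating point) to recomputing the DFT at
#' every step.
#'
#' @param x Numeric vector, one channel.
#' @param freq Frequency in Hz; must align to a DFT bin of the window.
#' @param srate Sampling rate in Hz.
#' @param window Window length in seconds (default 1).
#' @param out_rate Output rate in Hz after decimation (default 100).
#' @return Data frame with `time` (seconds, right edge of the window) and
#'   `power`.
#' @export
sliding_power <- function(x, freq, srate = 1000, window = 1, out_rate = 100) {
  n <- round(window * srate)
  if (length(x) < n) stop("recording shorter than the analysis window")
  bin <- freq * n / srate
  if (abs(bin - round(bin)) > 1e-9)
    stop("freq does not align to a DFT bin of the window")
  m <- length(x)
  # S_t = sum_{j=0}^{n-1} x[t+j] e^{-2 pi i f j / srate}
  #     = e^{+2 pi i f t / srate} * (C[t+n] - C[t]),  C = cumsum(x * e^{-...})
  ph <- exp(-2i * pi * freq * (seq_len(m) - 1) / srate)
  C <- c(0, cumsum(x * ph))
  starts <- seq_len(m - n + 1L)
  S <- (C[starts + n] - C[starts]) * exp(2i * pi * freq * (starts - 1) / srate)
  pow <- Mod(S)^2
  keep <- seq(1L, length(pow), by = round(srate / out_rate))
  data.frame(time = (starts[keep] + n - 1L) / srate, power = pow[keep])
}

#' Cluster-based permutation test on paired time courses
#'
#' Dependent-samples t-test at every time point between two paired
#' conditions, clustering of consecutive supra-threshold same-sign t values,
#' and a sign-flip permutation null for the cluster t-sums: on each
#' permutation the two conditions are swapped within a random subset of
#' subjects and the maximum absolute cluster t-sum is recorded; a cluster is
#' significant when its |t-sum| exceeds the (1 - alpha) quantile of that
#' max-statistic null, which controls the family-wise error over time
#' points. The cluster-forming threshold is the two-tailed critical t at
#' `cluster_alpha`.
#'
#' @param condA,condB Numeric matrices, subjects x timepoints, paired by row.
#' @param n_perm Number of random permutations (default 1000; fewer than
#'   100 draws a warning). Ignored when `exact = TRUE`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param cluster_alpha Per-timepoint two-tailed threshold forming clusters
#'   (default 0.05).
#' @param exact Enumerate all `2^n` sign flips instead of sampling (feasible
#'   for small subject counts; makes p-values exact).
#' @return Object of class `rift_cluster_test`: `t` (per-timepoint t),
#'   `clusters` (data frame `start`, `end`, `t_sum`, `p`, `significant`),
#'   `null_max` (permutation distribution of the max |t-sum|),
#'   `n_permutations`, `alpha`.
#' @export
cluster_permutation <- function(condA, condB, n_perm = 1000, alpha = 0.05,
                                cluster_alpha = 0.05, exact = FALSE) {
  condA <- as.matrix(condA); condB <- as.matrix(condB)
  if (!all(dim(condA) == dim(condB)))
    stop("condA and condB must have identical subjects x timepoints shape")
  n <- nrow(condA)
  if (n < 2) stop("need at least 2 subjects")
  if (!exact && n_perm < 100) warning("n_perm < 100: p-values will be coarse")
  d <- condA - condB
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tvals <- paired_t(d)
  obs <- find_clusters(tvals, tcrit)
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  # sign flips leave each subject's squared difference unchanged, so the
  # per-timepoint sum of squares is permutation-invariant and all permuted
  # t curves come from one matrix product
  ss <- colSums(d^2)
  mean_mat <- (signs %*% d) / n
  var_mat <- sweep(-n * mean_mat^2, 2, ss, "+") / (n - 1)
  t_mat <- mean_mat / sqrt(pmax(var_mat, 0) / n)
  t_mat[is.nan(t_mat)] <- 0
  null_max <- vapply(seq_len(nrow(t_mat)), function(i) {
    cl <- find_clusters(t_mat[i, ], tcrit)
    if (nrow(cl)) max(abs(cl$t_sum)) else 0
  }, numeric(1))
  if (nrow(obs)) {
    if (exact) {
      obs$p <- vapply(obs$t_sum,
                      function(ts) mean(null_max >= abs(ts)), numeric(1))
    } else {
      # add-one correction keeps p in (0, 1]
      obs$p <- vapply(obs$t_sum, function(ts)
        (1 + sum(null_max >= abs(ts))) / (length(null_max) + 1), numeric(1))
    }
    obs$significant <- obs$p < alpha
  } else {
    obs$p <- numeric(0); obs$significant <- logical(0)
  }
  structure(list(t = tvals, clusters = obs, null_max = null_max,
                 n_permutations = length(null_max), alpha = alpha,
                 t_critical = tcrit),
            class = "rift_cluster_test")
}

paired_t <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2, m)^2) / (n - 1))
  tv <- m / (s / sqrt(n))
  tv[s == 0 & m == 0] <- 0
  tv[s == 0 & m != 0] <- sign(m[s == 0 & m != 0]) * Inf
  tv
}

# maximal runs of consecutive supra-threshold t values of the same sign
find_clusters <- function(tvals, tcrit) {
  lab <- ifelse(tvals > tcrit, 1L, ifelse(tvals < -tcrit, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(start = starts[keep], end = ends[keep],
             t_sum = vapply(which(keep),
                            function(i) sum(tvals[starts[i]:ends[i]]),
                            numeric(1)))
}

#' @export
print.rift_cluster_test <- function(x, ...) {
  cat(sprintf("<rift_cluster_test> %d timepoints, %d permutations (|t| > %.2f forms clusters)\n",
              length(x$t), x$n_permutations, x$t_critical))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' Export a cluster test as a long-format CSV
#'
#' One row per time point with its t value, the id of the cluster covering
#' it (`NA` outside clusters) and that cluster's permutation p.
#'
#' @param result A `rift_cluster_test`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(result, path) {
  df <- data.frame(time_index = seq_along(result$t), t = result$t,
                   cluster_id = NA_integer_, p = NA_real_)
  if (nrow(result$clusters))
    for (i in seq_len(nrow(result$clusters))) {
      span <- result$clusters$start[i]:result$clusters$end[i]
      df$cluster_id[span] <- i
      df$p[span] <- result$clusters$p[i]
    }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mean tagging power binned by horizontal eye position
#'
#' Aggregates time-aligned gaze and power samples (both at 100 Hz after
#' [sliding_power()]) into `n_bins` equal-width bins over the given gaze
#' range and reports per-bin mean power and sample count - the eye-movement
#' confound check: under covert attention the binned power shows no
#' systematic trend across gaze position.
#'
#' @param gaze_x Horizontal gaze in degrees (NA = blink, excluded).
#' @param power Power samples aligned with `gaze_x`.
#' @param n_bins Number of bins (default 40).
#' @param range Gaze range covered, degrees (default `c(-2, 2)`).
#' @return Data frame with `bin_centre`, `mean_power` (`NA` for empty bins),
#'   `n`.
#' @export
eye_power_histogram <- function(gaze_x, power, n_bins = 40, range = c(-2, 2)) {
  stopifnot(length(gaze_x) == length(power))
  ok <- !is.na(gaze_x) & !is.na(power) & gaze_x >= range[1] & gaze_x <= range[2]
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- cut(gaze_x[ok], edges, include.lowest = TRUE, labels = FALSE)
  mp <- tapply(power[ok], factor(bin, levels = seq_len(n_bins)), mean)
  cnt <- tapply(rep(1, sum(ok)), factor(bin, levels = seq_len(n_bins)), sum)
  data.frame(bin_centre = (edges[-1] + edges[-length(edges)]) / 2,
             mean_power = as.numeric(mp),
             n = ifelse(is.na(cnt), 0L, as.integer(cnt)))
}

#' Fraction of gaze samples within fixation thresholds
#'
#' Computes, for each threshold, the fraction of non-blink samples whose
#' absolute gaze deviation from fixation is below it. Under the default
#' synthetic profile about 97 % of samples fall within 1 degree and about
#' 99 % within 2 degrees.
#'
#' @param gaze_x Gaze in degrees (NA = blink, excluded).
#' @param thresholds Thresholds in degrees (default `c(1, 2)`).
#' @return Named numeric vector of fractions.
#' @export
gaze_containment <- function(gaze_x, thresholds = c(1, 2)) {
  g <- gaze_x[!is.na(gaze_x)]
  stats::setNames(vapply(thresholds, function(th) mean(abs(g) < th), numeric(1)),
                  paste0("within_", thresholds, "deg"))
}
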