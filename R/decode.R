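#' Single-bin power spectral density of a window
#'
#' The online power estimate: the squared magnitude of the discrete Fourier
#' transform of the raw window at one frequency bin,
#' `P(f) = |sum_j X(j) W_n^((j-1)(f-1))|^2` with `W_n = exp(-2*pi*i/n)`,
#' where the 1-based bin index maps to frequency as
#' `bin = freq * n / srate`. No taper and no normalization are applied; the
#' offline time-frequency path uses a Hanning taper instead and the two are
#' kept distinct deliberately. A unit-amplitude sinusoid exactly on a bin
#' yields `(n/2)^2`.
#'
#' @param x Numeric vector, one channel's window (length >= 2).
#' @param freq Frequency in Hz; `freq * length(x) / srate` must be an
#'   integer (for a 1 s window at 1000 Hz: any integer frequency).
#' @param srate Sampling rate in Hz.
#' @return Non-negative scalar power (arbitrary units squared).
#' @export
psd_at <- function(x, freq, srate = 1000) {
  n <- length(x)
  if (n < 2) stop("window must have at least 2 samples")
  bin <- freq * n / srate
  if (abs(bin - round(bin)) > 1e-9)
    stop("freq = ", freq, " Hz does not align to a DFT bin of an ",
         n, "-sample window at ", srate, " Hz")
  Mod(stats::fft(x)[round(bin) + 1L])^2
}

#' Extract the 14-dimensional spectral feature vector
#'
#' Power at the two tagging frequencies for each of the seven named sensors,
#' computed with [psd_at()] on a one-second raw window. Feature order is
#' fixed and sensor-major: `(sensor1@56, sensor1@60, sensor2@56, ...)` with
#' sensors in the order given by `channels`. Rows of `window` are matched to
#' `channels` by name, so a permuted input with matching row names yields an
#' identical feature vector.
#'
#' @param window Numeric matrix, 7 MEG channels x window samples, with row
#'   names identifying sensors.
#' @param srate Sampling rate in Hz.
#' @param channels Sensor order defining the feature layout (default: the
#'   row names of `window` as given).
#' @param freqs The two tagged frequencies (default 56 and 60 Hz).
#' @return Named numeric vector of length `length(channels) * length(freqs)`
#'   (14 for the default layout), names `"<sensor>@<freq>"`.
#' @export
extract_features <- function(window, srate = 1000, channels = rownames(window),
                             freqs = c(56, 60)) {
  stopifnot(is.matrix(window))
  if (is.null(channels)) stop("window must carry sensor row names")
  if (length(channels) != 7)
    stop("expected exactly 7 sensors, got ", length(channels))
  idx <- match(channels, rownames(window))
  if (anyNA(idx)) stop("window is missing sensors: ",
                       paste(channels[is.na(idx)], collapse = ", "))
  out <- numeric(0)
  for (ch in idx)
    for (f in freqs)
      out <- c(out, psd_at(window[ch, ], f, srate))
  names(out) <- as.vector(t(outer(channels, freqs, paste, sep = "@")))
  out
}

#' Per-trial feature matrix of a training session
#'
#' Extracts one 14-dimensional feature vector per training trial from a
#' one-second window of the tagging phase (default: its last second,
#' matching the one-second online buffer), paired with the attended-side
#' labels.
#'
#' @param session The list returned by [simulate_training_session()] (or
#'   any list with a `recording` whose events code tagging onsets as
#'   21/left, 22/right, and `labels`).
#' @param window_offset_s Start of the feature window in seconds after
#'   tagging onset (default 1: the second half of the 2 s tagging phase).
#' @param window_s Window length in seconds (default 1).
#' @return List with `x` (trials x 14 matrix) and `y` (factor of sides).
#' @export
training_features <- function(session, window_offset_s = 1, window_s = 1) {
  rec <- session$recording
  stopifnot(inherits(rec, "rift_recording"))
  ev <- rec$events[rec$events$code %in% c(21L, 22L), , drop = FALSE]
  meg <- meg_channels(rec)
  n0 <- round(window_offset_s * rec$srate)
  nw <- round(window_s * rec$srate)
  x <- t(vapply(ev$sample, function(s0)
    extract_features(rec$data[meg, s0 + n0 + seq_len(nw) - 1L, drop = FALSE],
                     srate = rec$srate),
    numeric(2L * length(meg))))
  list(x = x, y = session$labels)
}

#' Train the covert-attention decoder
#'
#' Fits a linear support vector machine on spectral-power feature vectors
#' (14 features: 56 and 60 Hz power at seven occipital sensors) labelled
#' with the attended side, and estimates its accuracy by stratified k-fold
#' cross-validation (default 4 folds). Features are standardized (z-scored);
#' within cross-validation the standardization statistics are computed on
#' each training fold only, and the returned model carries the full-sample
#' statistics used at prediction time. The decision score is oriented so
#' that positive values mean "left".
#'
#' @param x Numeric matrix or data frame, trials x 14 features, column names
#'   as produced by [extract_features()].
#' @param y Labels: factor or character with values `"left"`/`"right"`.
#' @param folds Number of cross-validation folds (default 4).
#' @param cost SVM soft-margin constant C (default 1).
#' @param seed Seed for the fold assignment.
#' @return An object of class `rift_decoder` with components `weights`
#'   (length-14), `bias`, `center`, `scale`, `cv_accuracy`, `folds`,
#'   `feature_names`, `levels`.
#' @seealso [classify()], [predict.rift_decoder()], [write_decoder()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40 * 14, 2), 40), matrix(rnorm(40 * 14, -2), 40))
#' colnames(x) <- paste0("f", 1:14)
#' y <- rep(c("left", "right"), each = 40)
#' d <- rift_decoder(x, y)
#' d$cv_accuracy
#' @export
rift_decoder <- function(x, y, folds = 4, cost = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("left", "right"))
  if (anyNA(y) || nlevels(droplevels(y)) < 2)
    stop("both classes ('left', 'right') must be present")
  if (nrow(x) != length(y)) stop("x and y disagree on the number of trials")
  if (min(table(y)) < folds)
    stop("need at least ", folds, " trials per class for ", folds, "-fold CV")
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    fit <- svm_fit(x[tr, , drop = FALSE], y[tr], cost)
    pred <- decoder_scores(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(ifelse(pred > 0, "left", "right") == y[!tr])
  }
  cv_accuracy <- correct / length(y)
  final <- svm_fit(x, y, cost)
  structure(list(weights = final$weights, bias = final$bias,
                 center = final$center, scale = final$scale,
                 cv_accuracy = cv_accuracy, folds = folds, cost = cost,
                 feature_names = colnames(x), n_trials = nrow(x),
                 levels = c("left", "right")),
            class = "rift_decoder")
}

# standardize + linear SVM; returns weights/bias acting on RAW features'
# z-scores, oriented so positive score = "left"
svm_fit <- function(x, y, cost) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = center, scale = scale)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  b <- -fit$rho
  # libsvm orients decision values toward the first label it encounters
  positive_class <- levels(y)[fit$labels[1]]
  if (positive_class != "left") { w <- -w; b <- -b }
  list(weights = w, bias = b, center = unname(center), scale = unname(scale))
}

decoder_scores <- function(fit, x) {
  xs <- sweep(sweep(as.matrix(x), 2, fit$center), 2, fit$scale, "/")
  drop(xs %*% fit$weights) + fit$bias
}

#' @export
print.rift_decoder <- function(x, ...) {
  cat(sprintf("<rift_decoder> linear SVM, %d features, C = %g\n",
              length(x$weights), x$cost))
  cat(sprintf("  trained on %d trials; %d-fold CV accuracy = %.1f%%\n",
              x$n_trials, x$folds, 100 * x$cv_accuracy))
  invisible(x)
}

#' @export
summary.rift_decoder <- function(object, ...) {
  cat(sprintf("Covert-attention decoder (linear SVM, C = %g)\n", object$cost))
  cat(sprintf("Trials: %d   Folds: %d   CV accuracy: %.3f\n",
              object$n_trials, object$folds, object$cv_accuracy))
  cat("Standardized feature weights (positive pulls toward 'left'):\n")
  print(round(stats::setNames(object$weights, object$feature_names), 4))
  invisible(object)
}

#' @export
coef.rift_decoder <- function(object, ...) {
  c(stats::setNames(object$weights, object$feature_names),
    `(bias)` = object$bias)
}

#' Predict attended side for feature vectors
#'
#' @param object A [rift_decoder()].
#' @param newdata Matrix (trials x 14) or single named feature vector.
#' @param prev_side Side to keep when a score is zero to within numerical
#'   tolerance (hysteresis tie-break; default `"left"`).
#' @param ... Unused.
#' @return Data frame with columns `side` and `score` (signed distance-like
#'   decision value on standardized features; positive = left).
#' @export
predict.rift_decoder <- function(object, newdata, prev_side = "left", ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1,
                                               dimnames = list(NULL, names(newdata)))
  if (ncol(newdata) != length(object$weights))
    stop("expected ", length(object$weights), " features, got ", ncol(newdata))
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature (channel/frequency) order does not match the decoder")
  score <- decoder_scores(object, newdata)
  eps <- 1e-9    # scores this close to the hyperplane count as ties
  side <- ifelse(score > eps, "left", ifelse(score < -eps, "right", prev_side))
  data.frame(side = side, score = score)
}

#' Classify one window's feature vector
#'
#' Thin online wrapper around [predict.rift_decoder()] for a single feature
#' vector: returns the decoded side and the continuous decision score. A
#' score of exactly 0 keeps `prev_side` (hysteresis, avoids bar chatter).
#'
#' @param decoder A [rift_decoder()].
#' @param fv Named feature vector of length 14.
#' @param prev_side Side held before this tick.
#' @return List with `side` and `score`.
#' @export
classify <- function(decoder, fv, prev_side = "left") {
  p <- predict(decoder, fv, prev_side = prev_side)
  list(side = p$side[1], score = p$score[1])
}

#' Serialize a decoder to versioned JSON
#'
#' Writes weights, bias, standardization statistics, the feature/channel
#' order and the CV accuracy. [read_decoder()] refuses files whose format
#' version is unknown, and downstream prediction refuses feature vectors
#' whose channel order does not match.
#'
#' @param decoder A [rift_decoder()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_decoder <- function(decoder, path) {
  stopifnot(inherits(decoder, "rift_decoder"))
  obj <- unclass(decoder)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a decoder written by [write_decoder()]
#' @param path JSON path.
#' @return A [rift_decoder()].
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported decoder file version")
  obj$format_version <- NULL
  structure(obj, class = "rift_decoder")
}
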