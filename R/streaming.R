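#' Ring buffer over the most recent second of data
#'
#' Fixed-capacity FIFO holding the most recent `capacity` samples of a
#' multichannel stream, refreshed in fixed-size blocks: the online path is a
#' one-second buffer (1000 samples at 1000 Hz) updated every 100 ms. Window
#' queries are refused until the buffer has filled once.
#'
#' @param n_channels Number of channels.
#' @param capacity Buffer length in samples (default 1000).
#' @param block_size Samples per block (default 100); must divide `capacity`.
#' @return An object of class `ring_buffer`.
#' @export
ring_buffer <- function(n_channels, capacity = 1000, block_size = 100) {
  stopifnot(n_channels >= 1, capacity >= 1, block_size >= 1)
  if (capacity %% block_size != 0)
    stop("capacity must be an integer multiple of block_size")
  structure(list(data = matrix(0, n_channels, capacity),
                 n_channels = n_channels, capacity = capacity,
                 block_size = block_size, fill = 0L),
            class = "ring_buffer")
}

#' Push one block into a ring buffer
#'
#' Appends a channels x block_size block; once the buffer is full the oldest
#' block is evicted. Returns the updated buffer (value semantics).
#'
#' @param buffer A [ring_buffer()].
#' @param block Numeric matrix with the buffer's channel count and exactly
#'   `block_size` columns.
#' @return The updated buffer.
#' @export
push_block <- function(buffer, block) {
  stopifnot(inherits(buffer, "ring_buffer"))
  if (!is.matrix(block) || nrow(block) != buffer$n_channels)
    stop("block must have ", buffer$n_channels, " channels")
  if (ncol(block) != buffer$block_size)
    stop("block must have exactly ", buffer$block_size, " samples")
  bs <- buffer$block_size
  buffer$data <- cbind(buffer$data[, -(seq_len(bs)), drop = FALSE], block)
  buffer$fill <- min(buffer$capacity, buffer$fill + bs)
  buffer
}

#' Is the buffer filled to capacity?
#' @param buffer A [ring_buffer()].
#' @return Logical.
#' @export
buffer_full <- function(buffer) buffer$fill >= buffer$capacity

#' Current one-second window of a full buffer
#'
#' Returns the most recent `capacity` samples in chronological order. The
#' query is non-mutating and is refused (error of class
#' `riftbci_not_ready`) before the buffer has filled once.
#'
#' @param buffer A [ring_buffer()].
#' @return A channels x capacity matrix.
#' @export
current_window <- function(buffer) {
  stopifnot(inherits(buffer, "ring_buffer"))
  if (!buffer_full(buffer))
    stop(structure(class = c("riftbci_not_ready", "error", "condition"),
                   list(message = "buffer not yet filled", call = sys.call())))
  buffer$data
}

#' Detect a blink in a gaze segment
#'
#' A blink is a contiguous span of gap samples (`NA` sentinel, eye-tracker
#' signal loss) of at least `min_gap_s` seconds - the standard pupil-loss
#' criterion, default 50 ms.
#'
#' @param gaze Numeric vector of gaze samples, `NA` marking gaps.
#' @param srate Sampling rate in Hz.
#' @param min_gap_s Minimum gap duration counting as a blink (default 0.05).
#' @return Logical scalar.
#' @export
detect_blink <- function(gaze, srate = 1000, min_gap_s = 0.05) {
  if (!anyNA(gaze)) return(FALSE)
  r <- rle(is.na(gaze))
  any(r$values & r$lengths >= min_gap_s * srate)
}

#' Flag a trial's validity from its gaze trace
#'
#' Training trials are invalid if a blink occurs anywhere in the 2 s tagging
#' phase; game trials are invalid if a blink occurs in the last second
#' before the ball collision. The gaze passed in must already be restricted
#' to the scrutinized span.
#'
#' @param trial_id Identifier copied into the flag.
#' @param gaze Gaze samples over the scrutinized span (`NA` = gap).
#' @param phase `"training_tagging"` or `"game_pre_collision"`.
#' @param srate Sampling rate in Hz.
#' @return A list of class `validity_flag` with `trial_id`, `valid`,
#'   `reason` (one of `"ok"`, `"blink_in_tagging"`, `"blink_pre_collision"`).
#' @export
flag_trial <- function(trial_id, gaze,
                       phase = c("training_tagging", "game_pre_collision"),
                       srate = 1000) {
  phase <- match.arg(phase)
  blink <- detect_blink(gaze, srate)
  reason <- if (!blink) "ok"
            else if (phase == "training_tagging") "blink_in_tagging"
            else "blink_pre_collision"
  structure(list(trial_id = trial_id, valid = !blink, reason = reason),
            class = "validity_flag")
}

#' Replay a stored recording as 100 ms blocks
#'
#' Turns a [recording()] into a block generator compatible with the online
#' path: each call returns the next channels x block matrix, or `NULL` when
#' the recording is exhausted.
#'
#' @param rec A [recording()].
#' @param block_s Block duration in seconds (default 0.1).
#' @return A function `f()` yielding blocks.
#' @export
replay_blocks <- function(rec, block_s = 0.1) {
  stopifnot(inherits(rec, "rift_recording"))
  block_n <- round(block_s * rec$srate)
  n_blocks <- ncol(rec$data) %/% block_n
  i <- 0L
  function(...) {
    if (i >= n_blocks) return(NULL)
    out <- rec$data[, i * block_n + seq_len(block_n), drop = FALSE]
    i <<- i + 1L
    out
  }
}
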