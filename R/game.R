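#' Configuration of the pong world
#'
#' Geometry and speeds are configuration with documented defaults, chosen so
#' that a 5-minute session yields a trial rate comparable to a human game:
#' the ball falls from the top to the collision height in about 3 s at full
#' speed, moves at half speed for the first second after a reset
#' (orientation period), and after a hit follows the 90-degree reflection to
#' the nearer side wall, bounces, descends, and is then reset.
#'
#' @param fall_speed Vertical speed in screen units per second (default
#'   0.8 / 3: collision height reached in ~3 s).
#' @param drift_speed Maximal horizontal drift speed during the fall.
#' @param collision_height Ball y at which the bar collision is evaluated.
#' @param slow_factor Speed multiplier during the first second after reset.
#' @param slow_duration_s Duration of the reduced-speed phase (default 1 s).
#' @param tick_s Tick length in seconds (default 0.1 = one stream block).
#' @return List of class `game_config`.
#' @export
game_config <- function(fall_speed = 0.8 / 3, drift_speed = 0.05,
                        collision_height = 0.9, slow_factor = 0.5,
                        slow_duration_s = 1, tick_s = 0.1) {
  stopifnot(fall_speed > 0, collision_height > 0, collision_height < 1,
            slow_factor > 0, slow_factor <= 1, tick_s > 0)
  structure(list(fall_speed = fall_speed, drift_speed = drift_speed,
                 collision_height = collision_height,
                 slow_factor = slow_factor,
                 slow_duration_s = slow_duration_s, tick_s = tick_s),
            class = "game_config")
}

#' Fresh game state
#'
#' @param config A [game_config()].
#' @param bar_side Starting bar side during decoder warm-up.
#' @return List of class `game_state`.
#' @export
new_game_state <- function(config = game_config(), bar_side = "left") {
  st <- structure(list(config = config,
                       ball = c(x = 0.5, y = 0.1),
                       vel = c(x = 0, y = config$fall_speed),
                       phase = "falling", bar_side = bar_side,
                       tick = 0L, reset_tick = 0L, n_resets = 0L,
                       hits = 0L, misses = 0L, trial_id = 1L,
                       last_outcome = NA_character_),
                  class = "game_state")
  reset_ball(st)
}

#' Reset the ball to a random top position
#'
#' Places the ball uniformly at random in the top quarter of the screen
#' (y < 0.25), pointing downward with a random small horizontal drift, and
#' starts the reduced-speed orientation phase (`slow_start`) lasting
#' `slow_duration_s`. Called at session start and after every completed
#' trial, so over a full session the number of resets equals
#' hits + misses + 1. Draws from the current R random stream; seed the
#' session for reproducibility.
#'
#' @param state A `game_state`.
#' @return The updated state.
#' @export
reset_ball <- function(state) {
  cfg <- state$config
  state$ball <- c(x = stats::runif(1), y = stats::runif(1, 0, 0.25))
  state$vel <- c(x = stats::runif(1, -cfg$drift_speed, cfg$drift_speed),
                 y = cfg$fall_speed)
  state$phase <- "slow_start"
  state$reset_tick <- state$tick
  state$n_resets <- state$n_resets + 1L
  state
}

#' Side of the screen the ball is on
#' @param state A `game_state`.
#' @return `"left"` or `"right"`.
#' @export
ball_side <- function(state) if (state$ball[["x"]] < 0.5) "left" else "right"

#' Advance the game by one tick
#'
#' Sets the bar to the decoded side (the bar teleports between sides; the
#' hit rule is side-equality), advances the ball, and resolves collisions.
#' When the ball reaches the collision height: if the bar is on the ball's
#' side the trial is a hit and the ball is reflected in a 90-degree angle -
#' its downward motion becomes horizontal motion toward the nearer side
#' wall, where it bounces off and descends until it leaves the bottom and is
#' reset; if the bar is on the opposite side the trial is a miss and the
#' ball falls through and is reset immediately. `state$last_outcome` is
#' `"hit"`/`"miss"` on the tick a trial completes and `NA` otherwise.
#'
#' @param state A `game_state`.
#' @param decoded_side `"left"`, `"right"`, or `NA` (bar holds, e.g. during
#'   buffer warm-up).
#' @return The updated state.
#' @export
game_step <- function(state, decoded_side = NA) {
  cfg <- state$config
  if (!is.na(decoded_side)) state$bar_side <- decoded_side
  state$tick <- state$tick + 1L
  state$last_outcome <- NA_character_
  slow <- state$phase == "slow_start"
  speed <- if (slow) cfg$slow_factor else 1
  state$ball <- state$ball + speed * state$vel * cfg$tick_s
  # sides and top are reflecting walls
  if (state$ball[["x"]] < 0) { state$ball[["x"]] <- 0; state$vel[["x"]] <- abs(state$vel[["x"]]) }
  if (state$ball[["x"]] > 1) { state$ball[["x"]] <- 1; state$vel[["x"]] <- -abs(state$vel[["x"]]) }
  if (state$ball[["y"]] < 0) { state$ball[["y"]] <- 0; state$vel[["y"]] <- abs(state$vel[["y"]]) }
  if (slow && (state$tick - state$reset_tick) * cfg$tick_s >= cfg$slow_duration_s)
    state$phase <- "falling"
  if (state$phase %in% c("slow_start", "falling") &&
      state$vel[["y"]] > 0 && state$ball[["y"]] >= cfg$collision_height) {
    state$last_ball_side <- ball_side(state)
    state$last_bar_side <- state$bar_side
    if (state$bar_side == ball_side(state)) {            # hit
      state$hits <- state$hits + 1L
      state$last_outcome <- "hit"
      # 90-degree reflection: downward motion becomes horizontal motion
      # toward the nearer side wall
      toward <- if (state$ball[["x"]] < 0.5) -1 else 1
      v <- abs(state$vel[["y"]])
      state$vel <- c(x = toward * v, y = -0.4 * v)
      state$phase <- "reflected_up"
    } else {                                             # miss
      state$misses <- state$misses + 1L
      state$last_outcome <- "miss"
      state$trial_id <- state$trial_id + 1L
      state <- reset_ball(state)
      return(state)
    }
  } else if (state$phase == "reflected_up") {
    # reached a side wall: bounce off and descend again
    if (state$ball[["x"]] <= 0 || state$ball[["x"]] >= 1) {
      inward <- if (state$ball[["x"]] <= 0) 1 else -1
      state$vel <- c(x = inward * 0.3 * cfg$fall_speed, y = cfg$fall_speed)
      state$phase <- "wall_bounce"
    }
  } else if (state$phase == "wall_bounce") {
    # after a hit the ball leaves through the bottom, completing the trial
    if (state$ball[["y"]] >= 1) {
      state$trial_id <- state$trial_id + 1L
      state <- reset_ball(state)
    }
  }
  state$ball <- pmin(pmax(state$ball, 0), 1)
  state
}

#' Run a closed-loop game session
#'
#' The full online path: every 100 ms tick a stream block (MEG + gaze +
#' trigger) is pushed into the one-second ring buffer; once the buffer is
#' full the 14 spectral features of the current window are extracted and
#' classified, and the decoded side drives the bar. The simulated
#' participant attends the current ball side, which the stream generator
#' turns into attention-modulated tagging power (after its neural lag).
#' Trials in which a blink (eye-tracker gap >= 50 ms) falls in the last
#' second before the collision are flagged invalid and excluded from the
#' accuracy, though hits and misses still count toward the raw score.
#'
#' @param decoder A [rift_decoder()].
#' @param stream A generator from [simulate_game_stream()] (or any function
#'   of the attended side returning channels x block matrices, with the
#'   stream attributes set).
#' @param config A [game_config()].
#' @param seed Seed for the ball reset stream.
#' @param record_scores Keep per-tick decoder scores in the result.
#' @return An object of class `game_result`: data frame `trials` (columns
#'   `trial_id`, `ball_side`, `bar_side`, `outcome`, `valid`,
#'   `collision_tick`), `hits`, `misses`, `n_valid`, `accuracy` (hits over
#'   blink-valid trials; `NA` if none), `duration_s`, `partial`, and
#'   optionally `scores`.
#' @export
run_game <- function(decoder, stream, config = game_config(), seed = 1L,
                     record_scores = TRUE) {
  stopifnot(inherits(decoder, "rift_decoder"), is.function(stream))
  ch_names <- attr(stream, "channel_names")
  ch_kinds <- attr(stream, "channel_kinds")
  srate <- attr(stream, "srate") %||% 1000
  block_n <- attr(stream, "block_n") %||% round(config$tick_s * srate)
  meg_idx <- which(ch_kinds == "meg")
  gx_idx <- which(ch_kinds == "gaze_x")
  set.seed(seed)
  state <- new_game_state(config)
  buf <- ring_buffer(length(meg_idx) + 1L, capacity = 10L * block_n,
                     block_size = block_n)
  side <- NA_character_
  prev_side <- "left"
  trials <- list(); scores <- numeric(0)
  expected_blocks <- attr(stream, "n_blocks")
  n_ticks <- 0L
  repeat {
    blk <- stream(ball_side(state))
    if (is.null(blk)) break
    n_ticks <- n_ticks + 1L
    rownames(blk) <- ch_names
    # buffer carries the 7 MEG channels plus gaze_x for blink flagging
    buf <- push_block(buf, blk[c(meg_idx, gx_idx), , drop = FALSE])
    score <- NA_real_
    if (buffer_full(buf)) {
      win <- current_window(buf)
      fv <- extract_features(win[seq_along(meg_idx), , drop = FALSE],
                             srate = srate, channels = ch_names[meg_idx])
      cl <- classify(decoder, fv, prev_side = prev_side)
      side <- cl$side; score <- cl$score
      prev_side <- side
    }
    if (record_scores) scores <- c(scores, score)
    pre_state <- state
    state <- game_step(state, side)
    if (!is.na(state$last_outcome)) {
      gaze_last_s <- if (buffer_full(buf)) current_window(buf)[length(meg_idx) + 1L, ]
                     else buf$data[length(meg_idx) + 1L, ]
      fl <- flag_trial(pre_state$trial_id, gaze_last_s,
                       phase = "game_pre_collision", srate = srate)
      trials[[length(trials) + 1L]] <- data.frame(
        trial_id = pre_state$trial_id,
        ball_side = state$last_ball_side,
        bar_side = state$last_bar_side,
        outcome = state$last_outcome,
        valid = fl$valid,
        collision_tick = state$tick)
    }
  }
  trials <- if (length(trials)) do.call(rbind, trials)
            else data.frame(trial_id = integer(0), ball_side = character(0),
                            bar_side = character(0), outcome = character(0),
                            valid = logical(0), collision_tick = integer(0))
  valid <- trials[trials$valid, , drop = FALSE]
  res <- structure(list(
    trials = trials, hits = state$hits, misses = state$misses,
    n_valid = nrow(valid),
    accuracy = if (nrow(valid)) mean(valid$outcome == "hit") else NA_real_,
    duration_s = n_ticks * config$tick_s,
    partial = !is.null(expected_blocks) && n_ticks < expected_blocks,
    seed = seed), class = "game_result")
  if (record_scores) res$scores <- scores
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.game_result <- function(x, ...) {
  cat(sprintf("<game_result> %.1f min%s: %d hits, %d misses (%d trials, %d blink-valid)\n",
              x$duration_s / 60, if (x$partial) " [partial]" else "",
              x$hits, x$misses, nrow(x$trials), x$n_valid))
  if (is.na(x$accuracy)) cat("  accuracy: undefined (no valid trials)\n")
  else cat(sprintf("  accuracy over valid trials: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Write per-trial game records and a session summary
#'
#' The trial table goes to `<base>.trials.csv` (one row per trial) and the
#' session summary (hits, misses, accuracy, duration, seed) to
#' `<base>.summary.json`.
#'
#' @param result A `game_result`.
#' @param base Output path prefix.
#' @return `base`, invisibly.
#' @export
write_game_result <- function(result, base) {
  stopifnot(inherits(result, "game_result"))
  utils::write.csv(result$trials, paste0(base, ".trials.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(hits = result$hits, misses = result$misses,
         n_valid = result$n_valid, accuracy = result$accuracy,
         duration_s = result$duration_s, partial = result$partial,
         seed = result$seed),
    paste0(base, ".summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(base)
}
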