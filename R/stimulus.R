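#' Flicker specification for a frequency-tagged patch
#'
#' Describes the luminance modulation of one tagged stimulus patch: the
#' tagging frequency, the frame clock it is sampled on, and the modulation
#' waveform and depth. The default frequencies follow the two-patch layout
#' used throughout the package: 56 Hz on the left patch, 60 Hz on the right,
#' driven by a 1440 Hz frame clock.
#'
#' @param tag_frequency Tagging frequency in Hz. Must be below half the frame
#'   rate (Nyquist of the frame clock).
#' @param frame_rate Display frame rate in Hz (default 1440).
#' @param duration Sequence duration in seconds.
#' @param waveform `"sinusoidal"` (default) or `"square"` luminance
#'   modulation.
#' @param depth Modulation depth as a fraction of full luminance, in
#'   \[0, 1\]. Depth 0 means a constant mid-grey.
#' @return An object of class `flicker_spec`.
#' @examples
#' spec <- flicker_spec(56, duration = 1)
#' lum <- luminance_sequence(spec)
#' length(lum)  # 1440 frames
#' @export
flicker_spec <- function(tag_frequency = 56, frame_rate = 1440, duration = 1,
                         waveform = c("sinusoidal", "square"), depth = 1) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(tag_frequency), length(tag_frequency) == 1L,
            is.numeric(frame_rate), frame_rate > 0,
            is.numeric(duration), is.numeric(depth))
  if (tag_frequency >= frame_rate / 2)
    stop("tag_frequency must be below frame_rate / 2 (aliasing)")
  if (tag_frequency <= 0) stop("tag_frequency must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  structure(list(tag_frequency = tag_frequency, frame_rate = frame_rate,
                 duration = duration, waveform = waveform, depth = depth),
            class = "flicker_spec")
}

#' Frame-wise luminance sequence of a flickering patch
#'
#' Samples the continuous luminance modulation at the frame times of the
#' display clock. The sequence oscillates about mid-grey (0.5) with the
#' requested depth, so full-depth modulation spans \[0, 1\]. Tagging
#' frequencies that do not divide the frame rate (56 Hz at 1440 Hz gives
#' 25.71 frames per cycle) are sampled exactly at frame times rather than
#' forced to integer cycles; the residual spectral leakage is negligible at
#' one-second analysis windows.
#'
#' @param spec A [flicker_spec()].
#' @return Numeric vector of luminance values in \[0, 1\], one per frame,
#'   of length `round(frame_rate * duration)`.
#' @export
luminance_sequence <- function(spec) {
  stopifnot(inherits(spec, "flicker_spec"))
  n <- round(spec$frame_rate * spec$duration)
  t <- (seq_len(n) - 1L) / spec$frame_rate
  mod <- switch(spec$waveform,
    sinusoidal = sin(2 * pi * spec$tag_frequency * t),
    # square wave: +1 for the first half of each cycle, -1 for the second
    square = ifelse((spec$tag_frequency * t) %% 1 < 0.5, 1, -1)
  )
  lum <- 0.5 + 0.5 * spec$depth * mod
  pmin(pmax(lum, 0), 1)
}

#' Export a luminance sequence as a CSV table
#'
#' Writes one row per frame with `frame_index` (1-based), `time_s`, and
#' `luminance`, for external inspection of the flicker drive.
#'
#' @param spec A [flicker_spec()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_luminance_csv <- function(spec, path) {
  lum <- luminance_sequence(spec)
  df <- data.frame(frame_index = seq_along(lum),
                   time_s = (seq_along(lum) - 1) / spec$frame_rate,
                   luminance = lum)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Patch geometry for a tagged stimulus
#'
#' Normalized screen coordinates in \[0, 1\] x \[0, 1\], origin at the top
#' left, x rightward, y downward. The patch edges are fully transparent and
#' fade to full visibility over a fixed fraction of the patch extent, so the
#' visible flicker has no hard boundary.
#'
#' @param side `"left"` or `"right"` half of the screen.
#' @param width,height Patch extent in normalized units, each in (0, 1\].
#' @param fade_fraction Fraction of the patch length/height over which
#'   opacity ramps from 0 to 1 (default 0.10); must lie in (0, 0.5).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(side = c("left", "right"), width = 0.45, height = 0.9,
                       fade_fraction = 0.10) {
  side <- match.arg(side)
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(fade_fraction))
  if (width <= 0 || width > 1 || height <= 0 || height > 1)
    stop("width and height must lie in (0, 1]")
  if (fade_fraction <= 0 || fade_fraction >= 0.5)
    stop("fade_fraction must lie in (0, 0.5)")
  structure(list(side = side, width = width, height = height,
                 fade_fraction = fade_fraction),
            class = "patch_spec")
}

#' Opacity mask of a tagged patch
#'
#' Rasterises the patch transparency ramp on a `grid_h` x `grid_w` cell grid
#' covering the patch. Boundary cells are fully transparent (opacity 0); the
#' central region outside the fade bands is fully opaque (opacity 1); within a
#' fade band opacity increases linearly moving inward. Left and right patches
#' are mirror images of each other: the mask of a right patch is the
#' column-reversed mask of the equivalent left patch.
#'
#' @param spec A [patch_spec()].
#' @param grid_w,grid_h Raster dimensions in cells; each must be at least 10.
#' @return A `grid_h` x `grid_w` matrix of opacities in \[0, 1\].
#' @export
patch_alpha_mask <- function(spec, grid_w, grid_h) {
  stopifnot(inherits(spec, "patch_spec"))
  if (grid_w < 10 || grid_h < 10) stop("grid dimensions must be >= 10")
  ramp <- function(n) {
    # distance of cell centres from the nearest edge, in units of extent
    pos <- (seq_len(n) - 0.5) / n
    d <- pmin(pos, 1 - pos)
    # boundary cells clamp to 0 so the outline is fully transparent
    a <- pmin(d / spec$fade_fraction, 1)
    a[c(1L, n)] <- 0
    a
  }
  mask <- outer(ramp(grid_h), ramp(grid_w), pmin)
  if (spec$side == "right") mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  mask
}
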