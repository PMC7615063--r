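#' Multichannel recording container
#'
#' The common currency of all pipeline stages: a channels x samples numeric
#' matrix with a sampling rate, per-channel names and kinds, and an event
#' table. Channel kinds distinguish MEG-like sensors (`"meg"`), gaze traces in
#' degrees of visual angle (`"gaze_x"`, `"gaze_y"`), and the trigger channel
#' (`"trigger"`). Gaze channels may contain `NA` spans marking blinks; MEG
#' channels never contain `NA`.
#'
#' @param data Numeric matrix, channels x samples.
#' @param srate Sampling rate in Hz; must exceed twice the highest tagged
#'   frequency carried by the data (120 Hz for 56/60 Hz tagging).
#' @param channel_names Character vector, one name per row of `data`.
#' @param channel_kinds Character vector of kinds, one per channel; each is
#'   one of `"meg"`, `"gaze_x"`, `"gaze_y"`, `"trigger"`.
#' @param events Data frame with columns `sample` (1-based sample index),
#'   `code` (integer), `label` (character), or `NULL` for none.
#' @return An object of class `rift_recording`.
#' @export
recording <- function(data, srate = 1000, channel_names, channel_kinds,
                      events = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (missing(channel_names)) channel_names <- rownames(data)
  if (is.null(channel_names) || length(channel_names) != nrow(data))
    stop("channel_names must name every row of data")
  if (length(channel_kinds) != nrow(data))
    stop("channel_kinds must have one entry per channel")
  bad <- setdiff(unique(channel_kinds), c("meg", "gaze_x", "gaze_y", "trigger"))
  if (length(bad)) stop("unknown channel kind: ", paste(bad, collapse = ", "))
  if (srate <= 120)
    stop("srate must exceed twice the highest tagged frequency (60 Hz)")
  if (anyNA(data[channel_kinds == "meg", , drop = FALSE]))
    stop("MEG channels must not contain NA")
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = integer(0),
                         label = character(0))
  stopifnot(all(c("sample", "code", "label") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices must lie within the data")
  rownames(data) <- channel_names
  structure(list(data = data, srate = srate,
                 channel_names = channel_names,
                 channel_kinds = channel_kinds,
                 events = events),
            class = "rift_recording")
}

#' @export
print.rift_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$srate
  cat(sprintf("<rift_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), dur, x$srate))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  events: %d\n", nrow(x$events)))
  invisible(x)
}

#' @export
`[.rift_recording` <- function(x, channels, samples) {
  if (missing(channels)) channels <- seq_len(nrow(x$data))
  if (is.character(channels)) channels <- match(channels, x$channel_names)
  if (missing(samples)) samples <- seq_len(ncol(x$data))
  x$data[channels, samples, drop = FALSE]
}

meg_channels <- function(rec) which(rec$channel_kinds == "meg")
gaze_channel <- function(rec, axis = "gaze_x") which(rec$channel_kinds == axis)

#' Persist a recording to a plain-text container
#'
#' Writes a recording as three sibling files: `<base>.meta.json` (sampling
#' rate, channel names and kinds), `<base>.data.csv` (samples x channels,
#' full double precision so the round trip is lossless), and
#' `<base>.events.csv`. [read_recording()] restores the object exactly.
#'
#' @param rec A [recording()].
#' @param base Path prefix (without extension) for the three files.
#' @return `base`, invisibly.
#' @export
write_recording <- function(rec, base) {
  stopifnot(inherits(rec, "rift_recording"))
  meta <- list(srate = rec$srate, channel_names = rec$channel_names,
               channel_kinds = rec$channel_kinds, format_version = 1L)
  jsonlite::write_json(meta, paste0(base, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(base, ".data.csv"), "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_names, collapse = ","), con)
  # one text row per sample; 17 significant digits round-trip doubles exactly
  m <- format(t(rec$data), digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(do.call(paste, c(split(m, col(m)), sep = ",")), con)
  utils::write.csv(rec$events, paste0(base, ".events.csv"), row.names = FALSE)
  invisible(base)
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path prefix used when writing.
#' @return A [recording()].
#' @export
read_recording <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(base, ".data.csv"), check.names = FALSE)
  data <- t(as.matrix(df))
  ev <- utils::read.csv(paste0(base, ".events.csv"),
                        colClasses = c("integer", "integer", "character"))
  recording(data, srate = meta$srate, channel_names = meta$channel_names,
            channel_kinds = meta$channel_kinds, events = ev)
}
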