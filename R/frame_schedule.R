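#' Frame schedules for dynamic PET acquisitions
#'
#' A `frame_schedule` describes the timing of a dynamic acquisition as a
#' run-length encoded sequence of `(count, duration)` pairs, expanded into
#' per-frame start, end and mid times in seconds from injection. The default
#' clinical protocol used throughout the package is a 38-frame, 60-minute
#' schedule with fine early binning to resolve the bolus passage:
#' `"12,10;8,30;8,60;2,180;8,300"`.
#'
#' @param text Run-length string `"c1,d1;c2,d2;..."` where each `c` is a
#'   positive integer frame count and each `d` a positive duration in seconds.
#' @return A `frame_schedule` object: a list with `entries` (two-column matrix
#'   of counts and durations), and numeric vectors `durations_s`, `start_s`,
#'   `end_s`, `mid_s`, one element per expanded frame.
#' @examples
#' sched <- parse_frame_schedule("12,10;8,30;8,60;2,180;8,300")
#' n_frames(sched)       # 38
#' total_duration(sched) # 3600
#' @export
parse_frame_schedule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) {
    stop("empty frame schedule string", call. = FALSE)
  }
  counts <- integer(0)
  durs <- numeric(0)
  for (tok in tokens) {
    parts <- strsplit(trimws(tok), ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed frame-schedule pair '%s' (expected 'count,duration')", tok),
           call. = FALSE)
    }
    cnt <- suppressWarnings(as.numeric(parts[1]))
    dur <- suppressWarnings(as.numeric(parts[2]))
    if (!is.finite(cnt) || cnt <= 0 || cnt != round(cnt)) {
      stop(sprintf("invalid frame count in pair '%s': must be a positive integer", tok),
           call. = FALSE)
    }
    if (!is.finite(dur) || dur <= 0) {
      stop(sprintf("invalid frame duration in pair '%s': must be a positive number", tok),
           call. = FALSE)
    }
    counts <- c(counts, as.integer(cnt))
    durs <- c(durs, dur)
  }
  frame_schedule(counts, durs)
}

#' Construct a frame schedule from count/duration vectors
#'
#' @param counts Integer vector of frame counts per run-length entry.
#' @param durations_s Numeric vector (same length) of per-frame durations in
#'   seconds.
#' @return A `frame_schedule` object.
#' @export
frame_schedule <- function(counts, durations_s) {
  stopifnot(length(counts) == length(durations_s),
            all(counts >= 1), all(durations_s > 0))
  per_frame <- rep(durations_s, times = counts)
  end_s <- cumsum(per_frame)
  start_s <- c(0, end_s[-length(end_s)])
  structure(
    list(entries = cbind(count = as.integer(counts), duration_s = durations_s),
         durations_s = per_frame,
         start_s = start_s,
         end_s = end_s,
         mid_s = (start_s + end_s) / 2),
    class = "frame_schedule")
}

#' @rdname parse_frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$durations_s)

#' @rdname parse_frame_schedule
#' @export
total_duration <- function(schedule) sum(schedule$durations_s)

#' Serialize a frame schedule back to run-length text
#'
#' Inverse of [parse_frame_schedule()]: `parse_frame_schedule(format_frame_schedule(s))`
#' reproduces `s`.
#'
#' @param schedule A `frame_schedule`.
#' @return A single run-length string.
#' @export
format_frame_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  paste(sprintf("%d,%s", schedule$entries[, "count"],
                format(schedule$entries[, "duration_s"], trim = TRUE, scientific = FALSE)),
        collapse = ";")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %.0f s total (%s)\n",
              n_frames(x), total_duration(x), format_frame_schedule(x)))
  invisible(x)
}

#' The default 38-frame, 60-minute acquisition schedule
#'
#' Twelve 10-s frames, eight 30-s, eight 60-s, two 180-s and eight 300-s
#' frames: 38 frames totalling 3600 s.
#'
#' @return A `frame_schedule`.
#' @export
default_frame_schedule <- function() {
  parse_frame_schedule("12,10;8,30;8,60;2,180;8,300")
}
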