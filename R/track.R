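#' Two-marker head trajectory
#'
#' Container for a high-speed-video head track: per-frame 2D coordinates of
#' two markers (marker 1 = cheek paint mark, used for linear kinematics;
#' marker 2 = snout/dental-floss mark, used with marker 1 for head angle).
#' Coordinates are in meters, time in seconds.
#'
#' @param time numeric vector of frame times (s), uniformly sampled.
#' @param m1_x,m1_y,m2_x,m2_y numeric marker coordinates (m), one per frame.
#' @param frame_rate sampling rate (frames/s).
#' @param animal_id optional identifier.
#' @param impact_index optional integer (1 = day-1 impact, 2 = day-2 impact).
#'
#' @return A `marker_track`: a data frame with columns
#'   `frame, time_s, m1_x, m1_y, m2_x, m2_y` and attributes `frame_rate`,
#'   `animal_id`, `impact_index`.
#' @export
marker_track <- function(time, m1_x, m1_y, m2_x, m2_y, frame_rate,
                         animal_id = NA_character_, impact_index = NA_integer_) {
  n <- length(time)
  if (n < 50L)
    stop("a marker track needs at least 50 frames, got ", n)
  lens <- c(length(m1_x), length(m1_y), length(m2_x), length(m2_y))
  if (any(lens != n))
    stop("all coordinate series must have the same length as `time`")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number")
  if (anyNA(c(m1_x, m1_y, m2_x, m2_y, time)))
    stop("markers must be present in every frame (no missing values)")
  dt <- diff(time)
  if (any(abs(dt - 1 / frame_rate) > 1e-9))
    stop("`time` must be uniformly sampled at 1/frame_rate (within 1e-9 s)")
  out <- data.frame(frame = seq_len(n), time_s = time,
                    m1_x = m1_x, m1_y = m1_y, m2_x = m2_x, m2_y = m2_y)
  structure(out, frame_rate = frame_rate, animal_id = animal_id,
            impact_index = impact_index,
            class = c("marker_track", "data.frame"))
}

#' @export
print.marker_track <- function(x, ...) {
  fr <- attr(x, "frame_rate")
  cat(sprintf("Two-marker head track: %d frames at %g frames/s (%.1f ms)\n",
              nrow(x), fr, 1e3 * nrow(x) / fr))
  id <- attr(x, "animal_id")
  if (!is.na(id))
    cat(sprintf("  animal %s, impact %s\n", id, attr(x, "impact_index")))
  d <- sqrt((x$m1_x - x$m1_x[1])^2 + (x$m1_y - x$m1_y[1])^2)
  cat(sprintf("  cheek-marker excursion: %.1f mm\n", 1e3 * max(d)))
  invisible(x)
}

#' @export
plot.marker_track <- function(x, ...) {
  graphics::plot(1e3 * x$m1_x, 1e3 * x$m1_y, type = "l",
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = "Cheek-marker trajectory", asp = 1, ...)
  graphics::points(1e3 * x$m1_x[1], 1e3 * x$m1_y[1], pch = 19)
  invisible(x)
}

#' Read / write marker tracks as delimited text
#'
#' Tracks are exchanged as CSV with header
#' `frame,time_s,m1_x,m1_y,m2_x,m2_y` (meters / seconds, no missing frames).
#'
#' @param path file path.
#' @param frame_rate frames/s; if `NULL`, inferred from the time column.
#' @param ... passed to [marker_track()].
#' @return `read_track` returns a `marker_track`; `write_track` returns
#'   `path` invisibly.
#' @export
read_track <- function(path, frame_rate = NULL, ...) {
  d <- utils::read.csv(path)
  need <- c("frame", "time_s", "m1_x", "m1_y", "m2_x", "m2_y")
  if (!all(need %in% names(d)))
    stop("track file must have columns ", paste(need, collapse = ","))
  if (is.null(frame_rate))
    frame_rate <- 1 / stats::median(diff(d$time_s))
  marker_track(d$time_s, d$m1_x, d$m1_y, d$m2_x, d$m2_y,
               frame_rate = frame_rate, ...)
}

#' @rdname read_track
#' @param track a `marker_track`.
#' @export
write_track <- function(track, path) {
  utils::write.csv(as.data.frame(track)[, c("frame", "time_s", "m1_x",
                                            "m1_y", "m2_x", "m2_y")],
                   path, row.names = FALSE)
  invisible(path)
}
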