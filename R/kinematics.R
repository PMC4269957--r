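## Kinematic analysis of two-marker head tracks: zero-phase low-pass
## filtering, discrete differentiation, peak summaries, impact energy.

#' Zero-phase low-pass filter for marker tracks
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase
#' distortion, so times-to-peak are preserved) to each marker coordinate
#' series. The design cutoff is pre-warped so that the *effective* -3 dB
#' point of the bidirectional filter sits at `cutoff` (a single pass of an
#' order-`order` Butterworth applied twice is only -6 dB at its nominal
#' cutoff). Edge transients are suppressed by odd-reflection padding.
#'
#' @param track a [marker_track()].
#' @param cutoff low-pass cutoff frequency (Hz); default 400 Hz, standard for
#'   rodent head-impact videography.
#' @param order Butterworth order of a single pass (default 2; applied
#'   forward and backward this is the classic 4-pole phaseless filter of
#'   impact biomechanics).
#' @return A filtered `marker_track` of the same length.
#' @export
filter_track <- function(track, cutoff = 400, order = 2) {
  stopifnot(inherits(track, "marker_track"))
  fr <- attr(track, "frame_rate")
  if (cutoff >= fr / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fr / 2, " Hz)")
  out <- track
  for (col in c("m1_x", "m1_y", "m2_x", "m2_y"))
    out[[col]] <- lowpass_series(track[[col]], fr, cutoff, order)
  out
}

## forward-backward Butterworth on one series with odd-reflection padding
lowpass_series <- function(x, frame_rate, cutoff, order = 2) {
  # pre-warp: |H|^2 = 1/(1+(f/fc)^(2n)) must be 1/sqrt(2) at `cutoff`
  fc <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))
  if (fc >= frame_rate / 2) fc <- (cutoff + frame_rate / 2) / 2
  bf <- signal::butter(order, fc / (frame_rate / 2), type = "low")
  n <- length(x)
  np <- min(n - 1L, max(30L, ceiling(5 * frame_rate / cutoff)))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(np + 1):(np + n)]
}

## central differences, one-sided at the two boundary samples
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Derive linear and angular kinematics from a two-marker track
#'
#' Linear kinematics come from the cheek marker (marker 1): displacement is
#' the Euclidean distance from its pre-impact baseline position (mean of the
#' first `baseline_frames` frames); velocity and acceleration are central
#' differences of the X and Y components, combined as resultant magnitudes.
#' Head deflection is the unwrapped angle of the marker2-to-marker1 line with
#' the horizon, minus its pre-impact baseline; angular velocity and
#' acceleration are its successive central differences. Boundary samples use
#' one-sided differences and are excluded from downstream peak searches.
#'
#' The track should already be low-pass filtered (see [filter_track()]);
#' [kinematic_pipeline()] enforces the order.
#'
#' @param track a [marker_track()], normally filtered.
#' @param baseline_frames number of pre-impact frames defining the position
#'   and angle baselines (minimum and default 5).
#' @return A `kinematic_series`: data frame with columns `time`,
#'   `displacement` (m), `deflection` (rad), `linear_velocity` (m/s),
#'   `linear_acceleration` (m/s^2), `angular_velocity` (rad/s),
#'   `angular_acceleration` (rad/s^2).
#' @export
derive_kinematics <- function(track, baseline_frames = 5) {
  stopifnot(inherits(track, "marker_track"))
  if (baseline_frames < 5)
    stop("at least 5 pre-impact baseline frames are required")
  n <- nrow(track)
  if (n < baseline_frames)
    stop("track has fewer frames than `baseline_frames`")
  fr <- attr(track, "frame_rate")
  dt <- 1 / fr
  bl <- seq_len(baseline_frames)

  x <- track$m1_x; y <- track$m1_y
  x0 <- mean(x[bl]); y0 <- mean(y[bl])
  displacement <- sqrt((x - x0)^2 + (y - y0)^2)

  vx <- central_diff(x, dt); vy <- central_diff(y, dt)
  ax <- central_diff(vx, dt); ay <- central_diff(vy, dt)
  linear_velocity <- sqrt(vx^2 + vy^2)
  linear_acceleration <- sqrt(ax^2 + ay^2)

  phi <- unwrap_angle(atan2(track$m1_y - track$m2_y, track$m1_x - track$m2_x))
  deflection <- phi - mean(phi[bl])
  angular_velocity <- central_diff(deflection, dt)
  angular_acceleration <- central_diff(angular_velocity, dt)

  out <- data.frame(time = track$time_s, displacement = displacement,
                    deflection = deflection,
                    linear_velocity = linear_velocity,
                    linear_acceleration = linear_acceleration,
                    angular_velocity = angular_velocity,
                    angular_acceleration = angular_acceleration)
  structure(out, frame_rate = fr, baseline_frames = baseline_frames,
            animal_id = attr(track, "animal_id"),
            impact_index = attr(track, "impact_index"),
            class = c("kinematic_series", "data.frame"))
}

## unwrap radian phase across +/- pi jumps
unwrap_angle <- function(phi) {
  d <- diff(phi)
  jump <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  phi + jump
}

#' @export
plot.kinematic_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tms <- 1e3 * x$time
  graphics::plot(tms, 1e3 * x$displacement, type = "l",
                 xlab = "time (ms)", ylab = "displacement (mm)")
  graphics::plot(tms, x$deflection, type = "l",
                 xlab = "time (ms)", ylab = "deflection (rad)")
  graphics::plot(tms, x$linear_velocity, type = "l",
                 xlab = "time (ms)", ylab = "velocity (m/s)")
  graphics::plot(tms, x$linear_acceleration / 9.81, type = "l",
                 xlab = "time (ms)", ylab = "acceleration (g)")
  graphics::plot(tms, x$angular_velocity, type = "l",
                 xlab = "time (ms)", ylab = "ang. velocity (rad/s)")
  graphics::plot(tms, x$angular_acceleration / 1e3, type = "l",
                 xlab = "time (ms)", ylab = "ang. acceleration (krad/s²)")
  invisible(x)
}

kin_quantities <- c("displacement", "deflection", "linear_velocity",
                    "linear_acceleration", "angular_velocity",
                    "angular_acceleration")

#' Summarize per-impact kinematic peaks and repeatability
#'
#' For each of the six kinematic quantities the peak is the maximum absolute
#' value after impact onset, and the time-to-peak is measured from impactor
#' contact, detected as the first frame where the resultant linear
#' acceleration exceeds `onset_frac` of its global maximum. Boundary
#' (one-sided-difference) samples are excluded from the search. The change in
#' head velocity `delta_v` equals the peak resultant linear velocity, valid
#' because the head is stationary before impact.
#'
#' With several impacts, the coefficient of variation (CV = sample SD / mean)
#' is computed across animals on per-animal day-averaged peaks when
#' `animal_ids` is supplied (each animal contributes the average of its
#' impacts), or across all impacts pooled otherwise.
#'
#' @param series a `kinematic_series` or a list of them (one per impact).
#' @param animal_ids optional vector, one id per series, grouping impacts by
#'   animal for the CV.
#' @param onset_frac onset threshold as a fraction of the global maximum
#'   resultant linear acceleration (default 0.05).
#' @return A `peak_table`: data frame with one row per quantity and columns
#'   `quantity`, `peak`, `t_peak` (s, from onset; averaged across impacts)
#'   and `cv`; attributes `delta_v`, `n_impacts`, `scaled`.
#' @export
summarize_peaks <- function(series, animal_ids = NULL, onset_frac = 0.05) {
  if (inherits(series, "kinematic_series")) series <- list(series)
  if (!is.list(series) || length(series) == 0L)
    stop("`series` must be a kinematic_series or a non-empty list of them")
  per <- lapply(series, impact_peaks, onset_frac = onset_frac)
  peaks <- sapply(per, `[[`, "peak")      # quantities x impacts
  times <- sapply(per, `[[`, "t_peak")
  if (is.null(dim(peaks))) {
    peaks <- matrix(peaks, ncol = 1L)
    times <- matrix(times, ncol = 1L)
  }
  if (!is.null(animal_ids)) {
    if (length(animal_ids) != length(series))
      stop("`animal_ids` must have one entry per series")
    grp <- factor(animal_ids)
    av <- t(apply(peaks, 1L, function(p) tapply(p, grp, mean)))
    if (nlevels(grp) == 1L) av <- matrix(av, nrow = nrow(peaks))
    cv <- apply(av, 1L, function(p)
      if (length(p) > 1L) stats::sd(p) / mean(p) else NA_real_)
  } else {
    cv <- apply(peaks, 1L, function(p)
      if (length(p) > 1L) stats::sd(p) / mean(p) else NA_real_)
  }
  out <- data.frame(quantity = kin_quantities,
                    peak = rowMeans(peaks), t_peak = rowMeans(times),
                    cv = cv, row.names = NULL)
  structure(out, delta_v = out$peak[out$quantity == "linear_velocity"],
            n_impacts = length(series), scaled = FALSE,
            onset_frac = onset_frac,
            class = c("peak_table", "data.frame"))
}

## peaks of one impact; interior samples only, search from detected onset
impact_peaks <- function(ks, onset_frac = 0.05) {
  n <- nrow(ks)
  interior <- 3:(n - 2)   # acceleration uses twice-differenced boundaries
  acc <- ks$linear_acceleration
  amax <- max(acc[interior])
  onset <- interior[which(acc[interior] > onset_frac * amax)[1]]
  search <- onset:(n - 2)
  pk <- tp <- numeric(length(kin_quantities))
  names(pk) <- names(tp) <- kin_quantities
  for (q in kin_quantities) {
    v <- abs(ks[[q]])[search]
    i <- which.max(v)
    pk[q] <- v[i]
    tp[q] <- ks$time[search[i]] - ks$time[onset]
  }
  list(peak = pk, t_peak = tp, onset_frame = onset)
}

#' @export
print.peak_table <- function(x, ...) {
  lab <- c(displacement = "peak displacement",
           deflection = "peak deflection",
           linear_velocity = "peak linear velocity",
           linear_acceleration = "peak linear acceleration",
           angular_velocity = "peak angular velocity",
           angular_acceleration = "peak angular acceleration")
  conv <- c(displacement = 1e3, deflection = 1, linear_velocity = 1,
            linear_acceleration = 1 / 9.81, angular_velocity = 1,
            angular_acceleration = 1e-3)
  unit <- c(displacement = "mm", deflection = "rad", linear_velocity = "m/s",
            linear_acceleration = "g", angular_velocity = "rad/s",
            angular_acceleration = "krad/s²")
  cat(sprintf("Kinematic peak summary (%d impact%s)%s\n",
              attr(x, "n_impacts"), if (attr(x, "n_impacts") > 1) "s" else "",
              if (isTRUE(attr(x, "scaled"))) " [human-equivalent scale]" else ""))
  for (i in seq_len(nrow(x))) {
    q <- x$quantity[i]
    cvtxt <- if (is.finite(x$cv[i])) sprintf("  CV %.1f%%", 100 * x$cv[i]) else ""
    cat(sprintf("  %-28s %8.1f %-8s at %5.1f ms%s\n", lab[q],
                conv[q] * x$peak[i], unit[q], 1e3 * x$t_peak[i], cvtxt))
  }
  cat(sprintf("  ΔV = %.2f m/s\n", attr(x, "delta_v")))
  invisible(x)
}

#' Head-equivalent impact kinetic energy
#'
#' KE = 0.5 * M_e * dV^2, with the effective mass M_e approximated by head
#' mass and dV the change in resultant head velocity (equal to peak velocity
#' for a head at rest before impact).
#'
#' @param effective_mass effective (head) mass in kg; murine head mass is
#'   about 0.0034 kg.
#' @param delta_v change in head velocity (m/s).
#' @return An `energy_result` list with `effective_mass`, `delta_v` and
#'   `kinetic_energy` (J, exact); printing rounds to 2 decimals.
#' @examples
#' impact_energy(0.0034, 6.6)  # ~0.07 J
#' @export
impact_energy <- function(effective_mass, delta_v) {
  if (!is.numeric(effective_mass) || effective_mass <= 0)
    stop("`effective_mass` must be positive")
  if (delta_v < 0) stop("`delta_v` must be non-negative")
  structure(list(effective_mass = effective_mass, delta_v = delta_v,
                 kinetic_energy = 0.5 * effective_mass * delta_v^2),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("Impact energy: KE = 0.5 x %.4g kg x (%.3g m/s)^2 = %.2f J\n",
              x$effective_mass, x$delta_v, round(x$kinetic_energy, 2)))
  invisible(x)
}

#' Full kinematic pipeline: filter, differentiate, summarize
#'
#' Convenience wrapper enforcing the processing order used throughout:
#' low-pass filtering of the raw marker coordinates, then discrete
#' differentiation, then peak extraction.
#'
#' @param track a raw [marker_track()] or list of them.
#' @inheritParams filter_track
#' @inheritParams derive_kinematics
#' @inheritParams summarize_peaks
#' @return A `peak_table`.
#' @export
kinematic_pipeline <- function(track, cutoff = 400, order = 2,
                               baseline_frames = 5, onset_frac = 0.05,
                               animal_ids = NULL) {
  if (inherits(track, "marker_track")) track <- list(track)
  series <- lapply(track, function(tr)
    derive_kinematics(filter_track(tr, cutoff = cutoff, order = order),
                      baseline_frames = baseline_frames))
  summarize_peaks(series, animal_ids = animal_ids, onset_frac = onset_frac)
}
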