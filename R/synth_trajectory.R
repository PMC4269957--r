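## Synthetic impact-trajectory generator.
##
## The study's measurement chain is: track two head markers at 5,000
## frames/s, low-pass filter at 400 Hz (zero phase), differentiate, read off
## peaks. Published peak summaries are therefore *filtered-pipeline* values.
## The generator builds smooth parametric velocity-magnitude and
## deflection-angle profiles (clipped-Gaussian rise, algebraic decay, beta
## return bump), integrates them into marker positions, and solves the
## profile parameters by a damped fixed-point iteration against the very
## pipeline used for analysis, so that the recovered six (value, time) peak
## pairs match the requested spec.

#' Peak-constraint specification for a synthetic impact
#'
#' Defines the six kinematic peak (value, time) pairs a generated trajectory
#' must reproduce, plus sampling and noise settings. Defaults are the
#' reference murine CHIMERA impact at 0.5 J input energy: peak displacement
#' 49.6 mm at 15.7 ms, deflection 2.6 rad at 24.8 ms, linear velocity
#' 6.6 m/s at 3.4 ms, linear acceleration 385.3 g at 1.5 ms, angular
#' velocity 305.8 rad/s at 2.8 ms, angular acceleration 253.6 krad/s^2 at
#' 0.8 ms, sampled at 5,000 frames/s. Times are measured from impactor
#' contact (onset). Internal units are SI throughout (m, s, rad).
#'
#' @param peak_displacement,t_displacement peak resultant displacement (m)
#'   and its time (s).
#' @param peak_deflection,t_deflection peak head deflection (rad) and time (s).
#' @param peak_velocity,t_velocity peak resultant linear velocity (m/s) and
#'   time (s).
#' @param peak_acceleration,t_acceleration peak resultant linear
#'   acceleration (m/s^2) and time (s).
#' @param peak_ang_velocity,t_ang_velocity peak angular velocity (rad/s) and
#'   time (s).
#' @param peak_ang_acceleration,t_ang_acceleration peak angular acceleration
#'   (rad/s^2) and time (s).
#' @param frame_rate sampling rate (frames/s).
#' @param duration record length (s).
#' @param noise_sd isotropic Gaussian marker jitter SD (m); default 0.05 mm,
#'   a realistic sub-pixel tracking error.
#' @return An `impact_spec` list.
#' @export
impact_spec <- function(peak_displacement = 49.6e-3, t_displacement = 15.7e-3,
                        peak_deflection = 2.6, t_deflection = 24.8e-3,
                        peak_velocity = 6.6, t_velocity = 3.4e-3,
                        peak_acceleration = 385.3 * 9.81,
                        t_acceleration = 1.5e-3,
                        peak_ang_velocity = 305.8, t_ang_velocity = 2.8e-3,
                        peak_ang_acceleration = 253.6e3,
                        t_ang_acceleration = 0.8e-3,
                        frame_rate = 5000, duration = 0.08,
                        noise_sd = 0.05e-3) {
  spec <- list(peak_displacement = peak_displacement,
               t_displacement = t_displacement,
               peak_deflection = peak_deflection,
               t_deflection = t_deflection,
               peak_velocity = peak_velocity, t_velocity = t_velocity,
               peak_acceleration = peak_acceleration,
               t_acceleration = t_acceleration,
               peak_ang_velocity = peak_ang_velocity,
               t_ang_velocity = t_ang_velocity,
               peak_ang_acceleration = peak_ang_acceleration,
               t_ang_acceleration = t_ang_acceleration,
               frame_rate = frame_rate, duration = duration,
               noise_sd = noise_sd)
  validate_impact_spec(spec)
  structure(spec, class = "impact_spec")
}

validate_impact_spec <- function(s) {
  pk <- unlist(s[grep("^peak_", names(s))])
  if (any(pk < 0)) stop("all peak values must be >= 0")
  if (s$frame_rate <= 0) stop("frame_rate must be positive")
  if (s$duration <= 0) stop("duration must be positive")
  if (s$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(pk > 0)) {
    tt <- unlist(s[grep("^t_", names(s))])
    if (any(tt <= 0) || any(tt >= s$duration))
      stop("all peak times must lie strictly inside (0, duration)")
    if (!(s$t_acceleration <= s$t_velocity && s$t_velocity <= s$t_displacement))
      stop("need t_acceleration <= t_velocity <= t_displacement")
    if (!(s$t_ang_acceleration <= s$t_ang_velocity &&
          s$t_ang_velocity <= s$t_deflection))
      stop("need t_ang_acceleration <= t_ang_velocity <= t_deflection")
  }
  invisible(s)
}

#' @export
print.impact_spec <- function(x, ...) {
  cat("Impact peak-constraint spec:\n")
  cat(sprintf("  displacement %.1f mm @ %.1f ms | deflection %.2f rad @ %.1f ms\n",
              1e3 * x$peak_displacement, 1e3 * x$t_displacement,
              x$peak_deflection, 1e3 * x$t_deflection))
  cat(sprintf("  velocity %.2f m/s @ %.1f ms | acceleration %.1f g @ %.1f ms\n",
              x$peak_velocity, 1e3 * x$t_velocity,
              x$peak_acceleration / 9.81, 1e3 * x$t_acceleration))
  cat(sprintf("  ang. velocity %.1f rad/s @ %.1f ms | ang. accel %.1f krad/s² @ %.1f ms\n",
              x$peak_ang_velocity, 1e3 * x$t_ang_velocity,
              x$peak_ang_acceleration / 1e3, 1e3 * x$t_ang_acceleration))
  cat(sprintf("  %g frames/s, %.0f ms record, noise sd %.3g mm\n",
              x$frame_rate, 1e3 * x$duration, 1e3 * x$noise_sd))
  invisible(x)
}

## ---- pulse profile primitives -------------------------------------------

## Rise phase: u = V * pbeta(tau/tj, p, q). The S-curve starts at nominal
## contact (tau = 0), tops out with zero slope exactly at the velocity peak
## tj, and its slope (the acceleration) peaks at the beta mode. Given the
## requested acceleration (value A at time ta), the shape (p, q) is solved
## so the mode sits at ta and the peak slope equals A.
## mean of the decay shape (1 - x^2)^g over [0, 1]
decay_mean <- function(g) sqrt(pi) / 2 * exp(lgamma(g + 1) - lgamma(g + 1.5))

## solve decay exponent so that the decay phase contributes `frac` of V*Td
solve_decay <- function(frac, what) {
  if (!is.finite(frac) || frac <= 0)
    stop("infeasible constraint set: ", what,
         " is smaller than the travel already accumulated during the rise")
  if (frac >= decay_mean(1))
    stop("infeasible constraint set: ", what,
         " requires a slower-than-admissible decay (would spike the ",
         "acceleration at the velocity peak)")
  if (frac <= decay_mean(400))
    stop("infeasible constraint set: ", what, " is too small for the decay span")
  stats::uniroot(function(g) decay_mean(g) - frac, c(1, 400), tol = 1e-12)$root
}

## Signed velocity-magnitude profile on the sample grid, composed of
## three additive/sequential parts chosen so each (value, time) peak
## constraint maps onto its own parameter and every junction is smooth:
##   fast lobe: the acceleration is a Hann pulse of half-width w centered
##     at ta (peak value H/w, H = (1-gamma) V), so the velocity gains H in
##     a smooth step around the acceleration peak;
##   approach: a smoothstep carrying the remaining gamma V from 0 to the
##     velocity peak tj, whose derivative vanishes at tj -- this keeps the
##     velocity genuinely rising into a well-conditioned apex;
##   decay (tj, td]: u = V (1 - x^2)^g with g solved so the displacement
##     integral reaches D at the zero crossing td (the displacement peak);
##   return (td, t_end]: negative beta bump taking the head back by
##     rho * D.
## tau is measured from nominal impactor contact; the fast lobe may begin
## slightly before tau = 0 (a soft pre-contact toe), but never inside the
## stationary baseline window (t0_min).
pulse_profile <- function(tau, V, tj, w, ta, D, td, t_end, rho, what,
                          gamma = 0.15, t0_min = -Inf) {
  dt <- tau[2] - tau[1]
  if (td <= tj)
    stop("infeasible constraint set: ", what,
         " displacement peak must come after the velocity peak")
  if (ta >= tj)
    stop("infeasible constraint set: ", what,
         " acceleration peak must come before the velocity peak")
  if (ta + w >= tj)
    stop("infeasible constraint set: ", what,
         " acceleration peak is too close to the velocity peak for its ",
         "magnitude")
  if (ta - w < t0_min)
    stop("infeasible constraint set: ", what,
         " acceleration pulse would begin inside the stationary ",
         "pre-impact window")
  H <- (1 - gamma) * V
  G <- gamma * V
  u <- numeric(length(tau))
  ## fast lobe: velocity step H via Hann-shaped acceleration
  x <- pmin(pmax((tau - ta) / w, -1), 1)
  u <- u + H * (x + sin(pi * x) / pi + 1) / 2
  ## approach: smoothstep from 0 to G over (0, tj]
  z <- pmin(pmax(tau / tj, 0), 1)
  u <- u + G * z^2 * (3 - 2 * z)
  ## decay phase replaces everything past tj
  dist_tj <- H * (tj - ta) + G * tj / 2
  Td <- td - tj
  frac <- (D - dist_tj) / (V * Td)
  g <- solve_decay(frac, what)
  dec <- tau > tj & tau <= td
  u[dec] <- V * (1 - ((tau[dec] - tj) / Td)^2)^g
  u[tau > td] <- 0
  ## return bump bringing the head back by rho * D
  T_ret <- t_end - td
  if (rho > 0 && T_ret > 4 * dt) {
    wmax <- stats::dbeta(0.5, 2.5, 2.5)
    Vret <- rho * D / T_ret * wmax
    Vret <- Vret / max(Vret / (0.6 * V), 1)  # keep return sub-dominant
    ret <- tau > td & tau <= t_end
    u[ret] <- -Vret / wmax * stats::dbeta((tau[ret] - td) / T_ret, 2.5, 2.5)
  }
  u
}

cumtrapz <- function(y, dt) cumsum(c(0, (y[-1] + y[-length(y)]) / 2)) * dt

## assemble a marker_track from linear/angular profiles
profile_to_track <- function(tt, u_lin, u_ang, frame_rate, marker_distance,
                             loop_amp, animal_id, impact_index) {
  dt <- 1 / frame_rate
  y <- cumtrapz(u_lin, dt)
  theta <- cumtrapz(u_ang, dt)
  ## small lateral excursion in phase with path progress: closes the
  ## sagittal loop without perturbing the resultant peaks appreciably
  path <- cumtrapz(abs(u_lin), dt)
  s <- if (path[length(path)] > 0) path / path[length(path)] else path
  x <- loop_amp * sin(pi * s)
  m1x <- x; m1y <- y
  m2x <- m1x + marker_distance * cos(theta)
  m2y <- m1y + marker_distance * sin(theta)
  marker_track(tt, m1x, m1y, m2x, m2y, frame_rate = frame_rate,
               animal_id = animal_id, impact_index = impact_index)
}

## ---- generator -----------------------------------------------------------

#' Generate a two-marker impact trajectory matching a peak-constraint spec
#'
#' Builds a noiseless rigid-head two-marker track whose analysis by the
#' standard pipeline (400-Hz zero-phase Butterworth filter, central
#' differences, onset-referenced peak extraction; see
#' [kinematic_pipeline()]) reproduces all six (value, time) peak constraints
#' of `spec` — within 2% on values and one frame on times — then optionally
#' adds Gaussian tracking noise. The head is exactly stationary over the
#' pre-impact frames, the inter-marker distance is constant (rigid head),
#' and the trajectory loops: displacement rises to its peak and then
#' returns most of the way to baseline.
#'
#' The profile parameters are solved by a damped fixed-point iteration
#' against the analysis pipeline itself; if the constraint set cannot be
#' satisfied the function throws an explicit infeasibility error naming the
#' violated constraint rather than returning a best-effort track.
#'
#' @param spec an [impact_spec()].
#' @param seed RNG seed; required when `spec$noise_sd > 0`.
#' @param marker_distance cheek-to-snout marker separation (m).
#' @param pre_frames stationary frames before impactor contact (>= 8).
#' @param loop_amp lateral half-width of the sagittal loop (m).
#' @param return_frac fraction of peak displacement recovered in the return
#'   phase.
#' @param cutoff,order,onset_frac,baseline_frames analysis-pipeline settings
#'   the constraints are solved against (defaults match
#'   [kinematic_pipeline()]).
#' @param max_iter solver iteration cap.
#' @param animal_id,impact_index passed to [marker_track()].
#' @return A [marker_track()]; attribute `"generator"` records the solver's
#'   achieved peak errors.
#' @export
gen_impact_trajectory <- function(spec, seed = NULL,
                                  marker_distance = 0.015, pre_frames = 16,
                                  loop_amp = 1.5e-3, return_frac = 0.85,
                                  cutoff = 400, order = 2, onset_frac = 0.05,
                                  baseline_frames = 5, max_iter = 60,
                                  animal_id = NA_character_,
                                  impact_index = NA_integer_) {
  stopifnot(inherits(spec, "impact_spec"))
  validate_impact_spec(spec)
  if (spec$noise_sd > 0 && is.null(seed))
    stop("`seed` is required when `noise_sd` > 0")
  if (pre_frames < 10) stop("`pre_frames` must be at least 10")
  fr <- spec$frame_rate
  dt <- 1 / fr
  n <- round(spec$duration * fr) + 1L
  if (n < 50L) stop("duration x frame_rate must give at least 50 frames")
  tt <- (seq_len(n) - 1L) * dt
  tau <- tt - pre_frames * dt
  t_end <- tau[n]

  pk <- unlist(spec[grep("^peak_", names(spec))])
  if (all(pk == 0)) {                   # zero-motion case: stationary track
    tr <- marker_track(tt, rep(0, n), rep(0, n),
                       rep(marker_distance, n), rep(0, n), frame_rate = fr,
                       animal_id = animal_id, impact_index = impact_index)
    return(add_track_noise(tr, spec$noise_sd, seed))
  }
  if (any(pk == 0))
    stop("infeasible constraint set: peaks must be all zero or all positive")
  if (spec$t_displacement > t_end - 6 * dt)
    stop("infeasible constraint set: t_displacement too close to record end")
  if (spec$t_deflection > t_end - 6 * dt)
    stop("infeasible constraint set: t_deflection too close to record end")

  ## effective (solver-internal) targets, adapted toward the measured values
  lin <- list(V = spec$peak_velocity, tj = spec$t_velocity,
              w = 0.8 * spec$peak_velocity / spec$peak_acceleration,
              ta = spec$t_acceleration,
              D = spec$peak_displacement, td = spec$t_displacement)
  ang <- list(V = spec$peak_ang_velocity, tj = spec$t_ang_velocity,
              w = 0.8 * spec$peak_ang_velocity / spec$peak_ang_acceleration,
              ta = spec$t_ang_acceleration,
              D = spec$peak_deflection, td = spec$t_deflection)
  target <- c(linear_velocity = spec$peak_velocity,
              linear_acceleration = spec$peak_acceleration,
              displacement = spec$peak_displacement,
              angular_velocity = spec$peak_ang_velocity,
              angular_acceleration = spec$peak_ang_acceleration,
              deflection = spec$peak_deflection)
  t_target <- c(linear_velocity = spec$t_velocity,
                linear_acceleration = spec$t_acceleration,
                displacement = spec$t_displacement,
                angular_velocity = spec$t_ang_velocity,
                angular_acceleration = spec$t_ang_acceleration,
                deflection = spec$t_deflection)

  t0_min <- -(pre_frames - baseline_frames - 1) * dt
  lin$gamma <- ang$gamma <- 0.15
  tr <- NULL; meas <- NULL
  for (it in seq_len(max_iter)) {
    u_lin <- pulse_profile(tau, lin$V, lin$tj, lin$w, lin$ta, lin$D,
                           lin$td, t_end, return_frac, "linear",
                           gamma = lin$gamma, t0_min = t0_min)
    u_ang <- pulse_profile(tau, ang$V, ang$tj, ang$w, ang$ta, ang$D,
                           ang$td, t_end, return_frac, "angular",
                           gamma = ang$gamma, t0_min = t0_min)
    tr <- profile_to_track(tt, u_lin, u_ang, fr, marker_distance, loop_amp,
                           animal_id, impact_index)
    ks <- derive_kinematics(filter_track(tr, cutoff = cutoff, order = order),
                            baseline_frames = baseline_frames)
    m <- impact_peaks(ks, onset_frac = onset_frac)
    meas <- m
    verr <- m$peak[names(target)] / target - 1
    terr <- m$t_peak[names(t_target)] - t_target
    if (all(abs(verr) < 0.005) && all(abs(terr) <= 1.001 * dt)) break
    ## multiplicative updates on magnitudes (velocity scale, lobe width,
    ## displacement target); times move only when more than one frame off
    ## (the spec tolerance), to avoid chasing frame jitter
    lin$V <- lin$V * target["linear_velocity"] / m$peak["linear_velocity"]
    lin$w <- lin$w * m$peak["linear_acceleration"] /
      target["linear_acceleration"]
    lin$D <- lin$D * target["displacement"] / m$peak["displacement"]
    ang$V <- ang$V * target["angular_velocity"] / m$peak["angular_velocity"]
    ang$w <- ang$w * m$peak["angular_acceleration"] /
      target["angular_acceleration"]
    ang$D <- ang$D * target["deflection"] / m$peak["deflection"]
    tstep <- function(e) {
      if (abs(e) > 1.05 * dt) -0.6 * sign(e) * min(abs(e), 4 * dt) else 0
    }
    lin$ta <- lin$ta + tstep(terr["linear_acceleration"])
    lin$tj <- lin$tj + tstep(terr["linear_velocity"])
    if (abs(terr["displacement"]) < 8 * dt)
      lin$td <- lin$td + tstep(terr["displacement"])
    ang$ta <- ang$ta + tstep(terr["angular_acceleration"])
    ang$tj <- ang$tj + tstep(terr["angular_velocity"])
    if (abs(terr["deflection"]) < 8 * dt)
      ang$td <- ang$td + tstep(terr["deflection"])
    ## keep the time parameters near their targets and the orderings intact
    clamp <- function(x, t0, r) min(max(x, t0 - r), t0 + r)
    lin$ta <- clamp(lin$ta, spec$t_acceleration, 5 * dt)
    lin$tj <- clamp(lin$tj, spec$t_velocity, 5 * dt)
    lin$td <- clamp(lin$td, spec$t_displacement, 8 * dt)
    ang$ta <- clamp(ang$ta, spec$t_ang_acceleration, 5 * dt)
    ang$tj <- clamp(ang$tj, spec$t_ang_velocity, 5 * dt)
    ang$td <- clamp(ang$td, spec$t_deflection, 8 * dt)
    lin$ta <- max(lin$ta, dt)
    lin$tj <- max(lin$tj, lin$ta + 2 * dt)
    lin$td <- max(lin$td, lin$tj + 4 * dt)
    ang$ta <- max(ang$ta, dt)
    ang$tj <- max(ang$tj, ang$ta + 2 * dt)
    ang$td <- max(ang$td, ang$tj + 4 * dt)
    ## widen the approach if the velocity apex keeps being detected early
    if (it > 5 && terr["linear_velocity"] < -1.5 * dt)
      lin$gamma <- min(lin$gamma * 1.25, 0.35)
    if (it > 5 && terr["angular_velocity"] < -1.5 * dt)
      ang$gamma <- min(ang$gamma * 1.25, 0.35)
  }
  verr <- meas$peak[names(target)] / target - 1
  terr <- meas$t_peak[names(t_target)] - t_target
  if (any(abs(verr) > 0.02)) {
    w <- names(target)[which.max(abs(verr))]
    stop(sprintf(paste0("infeasible constraint set: could not match peak ",
                        "%s (achieved %.4g vs requested %.4g, %.1f%% off)"),
                 w, meas$peak[w], target[w], 100 * max(abs(verr))))
  }
  if (any(abs(terr) > 1.001 * dt)) {
    w <- names(t_target)[which.max(abs(terr))]
    stop(sprintf(paste0("infeasible constraint set: could not match the ",
                        "time of peak %s (achieved %.4g s vs requested ",
                        "%.4g s)"), w, meas$t_peak[w], t_target[w]))
  }
  attr(tr, "generator") <- list(value_rel_err = verr, time_err_s = terr,
                                onset_frame = meas$onset_frame)
  add_track_noise(tr, spec$noise_sd, seed)
}

add_track_noise <- function(track, noise_sd, seed) {
  if (noise_sd <= 0) return(track)
  set.seed(seed)
  n <- nrow(track)
  for (col in c("m1_x", "m1_y", "m2_x", "m2_y"))
    track[[col]] <- track[[col]] + stats::rnorm(n, 0, noise_sd)
  track
}
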