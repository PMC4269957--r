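## Impactor calibration: air pressure -> piston exit velocity -> impact
## energy. The measured relationship is fitted with a 2nd-order polynomial
## in the velocity domain (replicates enter individually); energy follows
## from E = 0.5 m v^2 with the piston mass.

#' Fit the pressure-to-velocity impactor calibration
#'
#' Least-squares quadratic fit of piston exit velocity against driving air
#' pressure, over all replicate measurements. Impact energy at any pressure
#' is derived as `0.5 * piston_mass * v(pressure)^2`.
#'
#' @param pressure air pressures (psi), one per measurement (replicates
#'   repeated); alternatively a data frame with columns `pressure` and
#'   `velocity`.
#' @param velocity piston exit velocities (m/s).
#' @param piston_mass piston mass (kg); default 0.050 kg (the standard 50 g
#'   piston).
#' @return A `calibration_curve` with the quadratic coefficients
#'   (intercept, linear, quadratic), `r_squared`, `piston_mass`,
#'   `n_points`, the calibrated pressure range and the underlying fit.
#' @examples
#' tab <- gen_calibration_table(coeffs = c(0.5, 1.2, -0.04), noise_sd = 0)
#' fit_calibration(tab)
#' @export
fit_calibration <- function(pressure, velocity = NULL, piston_mass = 0.050) {
  if (is.data.frame(pressure)) {
    d <- pressure
    if (!all(c("pressure", "velocity") %in% names(d)))
      stop("data frame input needs columns `pressure` and `velocity`")
  } else {
    d <- data.frame(pressure = pressure, velocity = velocity)
  }
  if (anyNA(d)) stop("calibration table must not contain missing values")
  if (length(unique(d$pressure)) < 3L)
    stop("need at least 3 distinct pressures for a quadratic fit")
  if (piston_mass <= 0) stop("`piston_mass` must be positive")
  fit <- stats::lm(velocity ~ pressure + I(pressure^2), data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$velocity - mean(d$velocity))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coefficients = unname(stats::coef(fit)),
                 piston_mass = piston_mass,
                 r_squared = r2, n_points = nrow(d),
                 pressure_range = range(d$pressure),
                 fit = fit, data = d),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  co <- x$coefficients
  cat("Impactor calibration (quadratic, velocity domain)\n")
  cat(sprintf("  v(p) = %.4g %+.4g p %+.4g p^2   [m/s; p in psi]\n",
              co[1], co[2], co[3]))
  cat(sprintf("  r^2 = %.4f over %d points, %.3g-%.3g psi; piston %g g\n",
              x$r_squared, x$n_points, x$pressure_range[1],
              x$pressure_range[2], 1e3 * x$piston_mass))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) object$coefficients

#' Predict piston velocity or impact energy from a calibration curve
#'
#' @param object a [fit_calibration()] curve.
#' @param pressure air pressures (psi).
#' @param type `"velocity"` (m/s) or `"energy"` (J).
#' @param ... unused.
#' @export
predict.calibration_curve <- function(object, pressure,
                                      type = c("velocity", "energy"), ...) {
  type <- match.arg(type)
  co <- object$coefficients
  v <- co[1] + co[2] * pressure + co[3] * pressure^2
  if (type == "velocity") v else 0.5 * object$piston_mass * v^2
}

#' @export
plot.calibration_curve <- function(x, ...) {
  d <- x$data
  graphics::plot(d$pressure, d$velocity, xlab = "air pressure (psi)",
                 ylab = "piston exit velocity (m/s)",
                 main = "Impactor calibration", ...)
  pg <- seq(x$pressure_range[1], x$pressure_range[2], length.out = 200)
  graphics::lines(pg, predict(x, pg))
  invisible(x)
}

#' Pressure required for a target impact energy
#'
#' Inverts the calibration: finds the air pressure whose predicted energy
#' `0.5 * piston_mass * v(p)^2` equals the target, by root-finding on the
#' calibrated pressure interval. Targets outside the calibrated energy
#' range are refused (no extrapolation); the practical usable range of the
#' impactor is about 0.01-1 J.
#'
#' @param curve a [fit_calibration()] curve.
#' @param target_energy target impact energy (J).
#' @return The pressure (psi).
#' @examples
#' tab <- gen_calibration_table(coeffs = c(0.5, 1.2, -0.04), noise_sd = 0)
#' cal <- fit_calibration(tab)
#' required_pressure(cal, 0.5)  # pressure where v = sqrt(2 * 0.5 / 0.05)
#' @export
required_pressure <- function(curve, target_energy) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (target_energy < 0) stop("`target_energy` must be non-negative")
  rng <- curve$pressure_range
  e_rng <- range(predict(curve, seq(rng[1], rng[2], length.out = 512),
                         type = "energy"))
  if (target_energy < e_rng[1] - 1e-12 || target_energy > e_rng[2] + 1e-12)
    stop(sprintf(paste0("extrapolation refused: target energy %.3g J is ",
                        "outside the calibrated range %.3g-%.3g J"),
                 target_energy, e_rng[1], e_rng[2]))
  f <- function(p) predict(curve, p, type = "energy") - target_energy
  stats::uniroot(f, interval = rng, tol = 1e-10,
                 extendInt = "no")$root
}
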