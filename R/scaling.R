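## Interspecies kinematic scaling under the equal-stress/equal-velocity
## framework: velocity is invariant, lengths and times scale with the cube
## root of the brain-mass ratio.

#' Interspecies scaling factor
#'
#' The length-scale ratio lambda = (target brain mass / source brain
#' mass)^(1/3) used to convert animal head kinematics to human-equivalent
#' values under equal-stress/equal-velocity scaling. The shipped
#' mouse-to-human constant is lambda = 13.8.
#'
#' @param lambda the ratio directly; or supply both masses instead.
#' @param source_mass,target_mass brain masses (any common unit).
#' @param source_species,target_species labels.
#' @return A `scaling_factor` object.
#' @examples
#' mouse_to_human()
#' scaling_factor(source_mass = 1, target_mass = 8)  # lambda = 2
#' @export
scaling_factor <- function(lambda = NULL, source_mass = NULL,
                           target_mass = NULL,
                           source_species = "source",
                           target_species = "target") {
  if (is.null(lambda)) {
    if (is.null(source_mass) || is.null(target_mass))
      stop("supply `lambda` or both `source_mass` and `target_mass`")
    if (source_mass <= 0 || target_mass <= 0)
      stop("brain masses must be positive")
    lambda <- (target_mass / source_mass)^(1 / 3)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number")
  structure(list(lambda = lambda, source_species = source_species,
                 target_species = target_species),
            class = "scaling_factor")
}

#' @rdname scaling_factor
#' @export
mouse_to_human <- function() {
  scaling_factor(13.8, source_species = "mouse", target_species = "human")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("Equal-stress/equal-velocity scaling: %s -> %s, lambda = %g\n",
              x$source_species, x$target_species, x$lambda))
  invisible(x)
}

## per-quantity lambda exponents for peak values; times all scale as lambda
scaling_exponents <- c(displacement = 1, deflection = 0,
                       linear_velocity = 0, linear_acceleration = -1,
                       angular_velocity = -1, angular_acceleration = -2)

#' Scale a kinematic peak table between species
#'
#' Applies equal-stress/equal-velocity scaling to a [summarize_peaks()]
#' table: velocities (linear peak and delta-V) are invariant, lengths and
#' times scale by lambda, linear acceleration and angular velocity by
#' 1/lambda, angular acceleration by 1/lambda^2; angles are dimensionless
#' and unchanged. CVs are dimensionless and unchanged.
#'
#' @param peaks a `peak_table`.
#' @param factor a [scaling_factor()]; default the mouse-to-human constant
#'   lambda = 13.8.
#' @return A new `peak_table` flagged as scaled; scaling an already-scaled
#'   table is an error (no double scaling), except with the exact reciprocal
#'   factor, which undoes the scaling and restores the original table.
#' @examples
#' \dontrun{
#' scale_kinematics(peaks, mouse_to_human())
#' }
#' @export
scale_kinematics <- function(peaks, factor = mouse_to_human()) {
  stopifnot(inherits(peaks, "peak_table"))
  stopifnot(inherits(factor, "scaling_factor"))
  lam <- factor$lambda
  undo <- FALSE
  if (isTRUE(attr(peaks, "scaled"))) {
    prev <- attr(peaks, "scaling")$lambda
    if (abs(lam * prev - 1) < 1e-12) undo <- TRUE
    else stop("table is already scaled; refusing to scale twice ",
              "(only the reciprocal factor 1/", prev, " may be applied ",
              "to undo)")
  }
  out <- peaks
  out$peak <- peaks$peak * lam^scaling_exponents[peaks$quantity]
  out$t_peak <- peaks$t_peak * lam
  attr(out, "delta_v") <- attr(peaks, "delta_v")   # velocity invariant
  attr(out, "scaled") <- !undo
  attr(out, "scaling") <- if (undo) NULL else factor
  out
}
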