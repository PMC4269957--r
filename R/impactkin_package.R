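#' impactkin: closed-head impact kinematics, histomorphometry and
#' behavioral injury indices
#'
#' Tools for analyzing pneumatic closed-head impact (CHIMERA-style) TBI
#' experiments: high-speed-video head kinematics ([kinematic_pipeline()]),
#' interspecies scaling ([scale_kinematics()]), impactor calibration
#' ([fit_calibration()]), white-matter histomorphometry ([boxcount_fd()],
#' [cell_density()], [percent_positive()]), behavioral indices
#' ([thigmotaxis_index()], [nss_score()], [pa_latency()]) and synthetic-data
#' generators for all of the above ([gen_impact_trajectory()],
#' [gen_microglia_image()], [gen_openfield_track()],
#' [gen_calibration_table()]).
#'
#' @importFrom stats coef lm predict residuals sd uniroot dbeta pbeta pnorm
#'   rnorm runif rpois median
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"

#' Read / write binary images as plain PNG
#'
#' Thin wrappers used to exchange silhouettes and ROI masks as 8-bit PNG
#' files (requires the `png` package).
#'
#' @param path file path.
#' @return `read_mask_png` returns a logical matrix; `write_mask_png`
#'   returns `path` invisibly.
#' @export
read_mask_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required for PNG input/output")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' @rdname read_mask_png
#' @param mask logical or 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required for PNG input/output")
  png::writePNG(mask * 1, path)
  invisible(path)
}
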