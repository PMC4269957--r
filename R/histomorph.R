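## White-matter histomorphometry: box-counting fractal dimension of
## microglial outlines, Iba-1 cell density per mm^2, and percent-positive
## stain burden within a region of interest.

## binarize a numeric/logical image matrix
as_binary_mask <- function(img) {
  if (is.logical(img)) return(img)
  if (!is.matrix(img) && !is.array(img)) stop("image must be a matrix")
  img > 0.5 * max(1, max(img))  # 0/1 or 0/255 conventions
}

## morphological erosion by a 3x3 square, zero-padded borders
erode3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- p[2:(nr + 1), 2:(nc + 1)]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    out <- out & p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' One-pixel outline of a binary silhouette
#'
#' Morphological perimeter: the foreground minus its erosion by a 3x3
#' square, matching the outline conversion used before box counting.
#'
#' @param img binary image matrix (logical, or numeric thresholded at half
#'   its maximum).
#' @return A logical matrix marking outline pixels.
#' @export
outline_image <- function(img) {
  m <- as_binary_mask(img)
  m & !erode3(m)
}

## keep the largest 8-connected foreground component
largest_component <- function(m) {
  lab <- EBImage::bwlabel(m * 1L)
  if (max(lab) <= 1L) return(m)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Box-counting fractal dimension of a shape outline
#'
#' Standard FracLac-style box counting: the binary input is reduced to its
#' largest connected component and converted to a one-pixel outline; for
#' each box size the image grid is overlaid at several offsets and the
#' minimum number of boxes containing foreground is kept; the dimension is
#' minus the slope of log N against log box size.
#'
#' For planar outlines D lies in about \[1, 2\]: a straight line gives 1, a
#' filled region (counted with `outline = FALSE`) gives 2; ramified
#' (resting) microglia score higher than amoeboid (activated) ones.
#'
#' @param img binary image matrix.
#' @param scales box sizes in pixels; default powers of 2 from 2 to a
#'   quarter of the smaller image side. At least 4 scales spanning at least
#'   two octaves are required.
#' @param n_offsets grid offsets tried per scale (minimum count kept).
#' @param outline reduce to the one-pixel outline first (default); set
#'   `FALSE` to box-count the raw set (e.g. filled regions or
#'   mathematically defined fractals).
#' @param keep_largest restrict to the largest connected component first.
#' @return The fractal dimension (numeric scalar) with attributes `scales`
#'   and `counts` carrying the log-log regression data.
#' @examples
#' line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
#' boxcount_fd(line)  # ~1
#' @export
boxcount_fd <- function(img, scales = NULL, n_offsets = 4,
                        outline = TRUE, keep_largest = TRUE) {
  m <- as_binary_mask(img)
  if (!any(m)) stop("image has no foreground pixels")
  if (keep_largest) m <- largest_component(m)
  if (outline) m <- m & !erode3(m)
  if (is.null(scales)) {
    smax <- floor(min(dim(m)) / 4)
    scales <- 2^(1:floor(log2(smax)))
  }
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4L)
    stop("need at least 4 distinct box sizes")
  if (log2(max(scales) / min(scales)) < 2)
    stop("box sizes must span at least two octaves")
  idx <- which(m, arr.ind = TRUE)
  counts <- vapply(scales, function(eps) {
    offs <- unique(floor(seq(0, eps - 1, length.out = n_offsets)))
    min(vapply(offs, function(o) {
      bx <- (idx[, 1] + o - 1L) %/% eps
      by <- (idx[, 2] + o - 1L) %/% eps
      length(unique(bx * 2147483647 + by))
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(scales))
  structure(-unname(stats::coef(fit)[2]), scales = scales, counts = counts)
}

#' Iba-1 positive cell density
#'
#' Cells are counted upstream (manually or by the caller); this converts a
#' count over an ROI mask to cells per square millimeter given the image
#' scale.
#'
#' @param count number of cells in the ROI (non-negative integer).
#' @param roi_mask binary ROI mask (matrix); its foreground area defines
#'   the ROI size.
#' @param px_per_mm image scale, pixels per millimeter.
#' @return Density in cells/mm^2.
#' @examples
#' mask <- matrix(TRUE, 500, 340)  # 170,000 px
#' cell_density(17, mask, px_per_mm = 1000)  # 100 cells/mm^2
#' @export
cell_density <- function(count, roi_mask, px_per_mm) {
  if (count < 0) stop("`count` must be non-negative")
  if (px_per_mm <= 0) stop("`px_per_mm` must be positive")
  m <- as_binary_mask(roi_mask)
  npx <- sum(m)
  if (npx == 0) stop("ROI mask is empty")
  area_mm2 <- npx / px_per_mm^2
  count / area_mm2
}

#' Percent-positive stain area within an ROI
#'
#' Thresholds a grayscale image (fixed threshold or Otsu's method computed
#' on the ROI histogram) and reports the positive fraction of the ROI as a
#' percentage, as used for silver-stain burden.
#'
#' @param img grayscale image matrix (values in \[0, 1\] or \[0, 255\]).
#' @param roi_mask binary ROI mask, same dimensions as `img`.
#' @param threshold numeric cutoff (pixels strictly above are positive), or
#'   `"otsu"` to derive it from the ROI histogram.
#' @return Percentage in \[0, 100\].
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' percent_positive(img, matrix(TRUE, 64, 64), threshold = 0.5)
#' @export
percent_positive <- function(img, roi_mask, threshold = "otsu") {
  if (!is.matrix(img)) stop("`img` must be a matrix")
  m <- as_binary_mask(roi_mask)
  if (!all(dim(m) == dim(img)))
    stop("`roi_mask` must match the image dimensions")
  n_roi <- sum(m)
  if (n_roi == 0) stop("ROI is empty")
  vals <- img[m]
  if (identical(threshold, "otsu")) {
    rng <- range(vals)
    if (diff(rng) == 0) return(0)
    scaled <- (vals - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(matrix(scaled, nrow = 1), range = c(0, 1))
  }
  100 * sum(vals > threshold) / n_roi
}
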