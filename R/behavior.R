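## Behavioral injury indices: open-field zoning and thigmotaxis,
## neurological severity score, passive-avoidance latency capping, and the
## fold-change / Bonferroni helpers used for biochemical endpoints.

#' Open-field arena geometry
#'
#' The standard open field is a 14 x 24 inch box whose floor is virtually
#' divided into 60 equal squares: 6 columns across the 14-inch side and 10
#' rows along the 24-inch side, so the cells are near-square.
#'
#' @param width,height arena dimensions (inches by convention; any unit
#'   works as long as tracks use the same one).
#' @return A list with `width` and `height`.
#' @export
open_field_arena <- function(width = 14, height = 24) {
  if (width <= 0 || height <= 0) stop("arena dimensions must be positive")
  list(width = width, height = height)
}

#' Partition an arena grid into peripheral and central zones
#'
#' Classifies each cell of a rows x cols grid as peripheral (touching the
#' arena wall) or central. The standard 10 x 6 grid gives 28 peripheral and
#' 32 central squares; in general a grid has 2 (rows + cols) - 4 perimeter
#' cells (all of them, when rows or cols <= 2).
#'
#' @param arena an [open_field_arena()].
#' @param rows,cols grid dimensions (default 10 x 6: rows along the long
#'   side).
#' @return An `open_field_zoning` list: `rows`, `cols`, logical matrix
#'   `peripheral` (rows x cols), counts `n_peripheral` and `n_central`,
#'   and the cell sizes.
#' @examples
#' zone_partition()                    # 28 peripheral, 32 central
#' zone_partition(rows = 3, cols = 3)  # 8 peripheral, 1 central
#' @export
zone_partition <- function(arena = open_field_arena(), rows = 10, cols = 6) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive")
  periph <- matrix(FALSE, rows, cols)
  periph[c(1, rows), ] <- TRUE
  periph[, c(1, cols)] <- TRUE
  structure(list(rows = rows, cols = cols, peripheral = periph,
                 n_peripheral = sum(periph),
                 n_central = as.integer(rows * cols) - sum(periph),
                 cell_w = arena$width / cols, cell_h = arena$height / rows,
                 arena = arena),
            class = "open_field_zoning")
}

#' @export
print.open_field_zoning <- function(x, ...) {
  cat(sprintf("Open-field zoning: %d x %d grid, %d peripheral / %d central cells\n",
              x$rows, x$cols, x$n_peripheral, x$n_central))
  invisible(x)
}

## classify sample positions into peripheral (TRUE) / central (FALSE);
## half-open cells, left/bottom inclusive; points on the far edges belong
## to the last cell
classify_samples <- function(x, y, zoning) {
  ar <- zoning$arena
  if (any(x < 0 | x > ar$width | y < 0 | y > ar$height))
    stop("track leaves the arena bounds")
  col <- pmin(floor(x / zoning$cell_w) + 1L, zoning$cols)
  row <- pmin(floor(y / zoning$cell_h) + 1L, zoning$rows)
  zoning$peripheral[cbind(row, col)]
}

#' Thigmotaxis index of an open-field track
#'
#' TI = (T_P - T_C) / (T_P + T_C), where T_P and T_C are the times spent in
#' the peripheral and central zones. Dwell times are sample counts divided
#' by the sampling rate; TI ranges from -1 (all central) to +1 (all
#' peripheral, i.e. maximal wall hugging).
#'
#' @param track a data frame with columns `x` and `y` (same units as the
#'   arena), e.g. from [gen_openfield_track()].
#' @param zoning an [zone_partition()] result.
#' @return The thigmotaxis index, with attributes `t_peripheral` and
#'   `t_central` (s) when the track carries a `rate` attribute (counts
#'   otherwise).
#' @examples
#' tr <- gen_openfield_track(2 / 3, duration = 600, seed = 1)
#' thigmotaxis_index(tr)  # about 1/3
#' @export
thigmotaxis_index <- function(track, zoning = zone_partition()) {
  if (!all(c("x", "y") %in% names(track)))
    stop("track needs columns `x` and `y`")
  n <- nrow(track)
  if (n == 0) stop("track has zero total time")
  peri <- classify_samples(track$x, track$y, zoning)
  rate <- attr(track, "rate")
  scale <- if (!is.null(rate)) 1 / rate else 1
  tp <- sum(peri) * scale
  tc <- sum(!peri) * scale
  structure((tp - tc) / (tp + tc), t_peripheral = tp, t_central = tc)
}

#' Neurological severity score
#'
#' Composite of ten pass/fail tasks probing motor reflexes, alertness and
#' physiological behavior; one point per failed task, so 0 is intact and 10
#' is maximal neurological dysfunction.
#'
#' @param task_failures logical vector of exactly 10 outcomes (`TRUE` =
#'   failed the task).
#' @return Integer score 0-10.
#' @examples
#' nss_score(rep(TRUE, 10))   # 10
#' nss_score(rep(FALSE, 10))  # 0
#' @export
nss_score <- function(task_failures) {
  if (length(task_failures) != 10L)
    stop("the NSS is a composite of exactly 10 tasks, got ",
         length(task_failures))
  if (!is.logical(task_failures) || anyNA(task_failures))
    stop("task outcomes must be TRUE/FALSE with no missing values")
  sum(task_failures)
}

#' Passive-avoidance crossing latency with ceiling
#'
#' Animals that never cross into the darkened compartment within the
#' session are assigned the full session duration (300 s by convention);
#' recorded crossings are capped at the same ceiling.
#'
#' @param crossing_time crossing latencies (s); `NA` means no crossing.
#' @param cap session ceiling (s), default 300.
#' @return Latencies (s), element-wise `min(crossing, cap)` with `NA`
#'   replaced by `cap`.
#' @examples
#' pa_latency(c(42, NA, 400))  # 42 300 300
#' @export
pa_latency <- function(crossing_time, cap = 300) {
  if (cap <= 0) stop("`cap` must be positive")
  if (any(crossing_time < 0, na.rm = TRUE))
    stop("latencies must be non-negative")
  out <- pmin(crossing_time, cap)
  out[is.na(out)] <- cap
  out
}

#' Fold change of a group mean over the sham mean
#'
#' @param group_values measurements in the comparison group (one timepoint).
#' @param sham_values matched sham measurements.
#' @return `mean(group) / mean(sham)`.
#' @examples
#' fold_change(c(14, 16), c(9, 11))  # 1.5
#' @export
fold_change <- function(group_values, sham_values) {
  ms <- mean(sham_values)
  if (!is.finite(ms) || ms == 0)
    stop("sham mean must be non-zero")
  mean(group_values) / ms
}

#' Bonferroni-adjusted significance threshold
#'
#' @param family_size number of comparisons in the family.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / family_size` (e.g. 0.05 / 5 = 0.01).
#' @export
bonferroni_alpha <- function(family_size, alpha = 0.05) {
  if (family_size < 1) stop("`family_size` must be at least 1")
  alpha / family_size
}
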