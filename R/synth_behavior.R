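## Synthetic open-field tracks with controlled peripheral occupancy, and
## synthetic impactor calibration tables.

## map a perimeter coordinate s in [0, L) and per-sample insets to (x, y)
## on the rectangle [mx, W - mx] x [my, H - my]; all arguments recycle
## elementwise
perimeter_xy <- function(s, W, H, mx, my) {
  n <- max(length(s), length(mx), length(my))
  s <- rep_len(s, n); mx <- rep_len(mx, n); my <- rep_len(my, n)
  w <- W - 2 * mx; h <- H - 2 * my
  L <- 2 * (w + h)
  s <- s %% L
  x <- numeric(n); y <- numeric(n)
  a <- s < w
  x[a] <- mx[a] + s[a]
  y[a] <- my[a]
  b <- s >= w & s < w + h
  x[b] <- W - mx[b]
  y[b] <- my[b] + (s[b] - w[b])
  c2 <- s >= w + h & s < 2 * w + h
  x[c2] <- W - mx[c2] - (s[c2] - w[c2] - h[c2])
  y[c2] <- H - my[c2]
  d <- s >= 2 * w + h
  x[d] <- mx[d]
  y[d] <- H - my[d] - (s[d] - 2 * w[d] - h[d])
  cbind(x, y)
}

## reflected random walk on [lo, hi]
walk_reflect <- function(n, start, step, lo, hi) {
  z <- start + cumsum(stats::rnorm(n, 0, step))
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  lo + ifelse(z > span, 2 * span - z, z)
}

#' Generate an open-field track with controlled thigmotaxis
#'
#' Simulates an animal alternating between wall-following bouts in the
#' peripheral zone and excursions through the central zone, with the total
#' time budget split deterministically so the realized peripheral fraction
#' equals `frac_peripheral` to within sampling resolution. Within each bout
#' the position follows a reflected random walk confined to the zone.
#'
#' @param frac_peripheral target fraction of time in the 28 perimeter
#'   squares, in \[0, 1\].
#' @param duration recording length (s), default 600 (a 10-minute session).
#' @param rate sampling rate (samples/s).
#' @param seed RNG seed.
#' @param zoning arena partition, default the standard 10 x 6 grid of the
#'   14 x 24 inch box.
#' @param mean_bout mean bout length (s) for the peripheral/central
#'   alternation.
#' @return A data frame with columns `time`, `x`, `y` (arena units) and
#'   attributes `rate` and `zoning`.
#' @examples
#' tr <- gen_openfield_track(2 / 3, duration = 600, seed = 1)
#' thigmotaxis_index(tr)  # about (400 - 200) / 600 = 1/3
#' @export
gen_openfield_track <- function(frac_peripheral, duration = 600, rate = 30,
                                seed = 1, zoning = zone_partition(),
                                mean_bout = 8) {
  if (frac_peripheral < 0 || frac_peripheral > 1)
    stop("`frac_peripheral` must be in [0, 1]")
  if (duration <= 0 || rate <= 0)
    stop("duration and rate must be positive")
  set.seed(seed)
  n <- round(duration * rate)
  n_p <- round(frac_peripheral * n)
  ## deterministic split into alternating bouts with random lengths
  state <- logical(n)   # TRUE = peripheral
  rem_p <- n_p; rem_c <- n - n_p
  i <- 1L
  cur <- rem_p >= rem_c
  while (i <= n) {
    budget <- if (cur) rem_p else rem_c
    if (budget == 0L) { cur <- !cur; next }
    len <- min(budget, max(1L, stats::rpois(1, mean_bout * rate)))
    state[i:(i + len - 1L)] <- cur
    if (cur) rem_p <- rem_p - len else rem_c <- rem_c - len
    i <- i + len
    if ((if (cur) rem_c else rem_p) > 0L) cur <- !cur
  }
  ar <- zoning$arena
  W <- ar$width; H <- ar$height
  cw <- zoning$cell_w; ch <- zoning$cell_h
  x <- numeric(n); y <- numeric(n)
  ## peripheral samples: walk along the wall at mid-band depth with jitter
  ## kept strictly inside the one-cell-deep peripheral band
  runs <- rle(state)
  pos <- cumsum(c(1L, runs$lengths))
  s_cur <- stats::runif(1, 0, 2 * (W + H))
  for (k in seq_along(runs$lengths)) {
    idx <- pos[k]:(pos[k] + runs$lengths[k] - 1L)
    nk <- length(idx)
    if (runs$values[k]) {
      s_cur <- s_cur + cumsum(stats::rnorm(nk, 0, 0.8))
      ## inset from the wall by a fraction of one cell (stays inside the
      ## one-cell-deep peripheral band)
      depth <- walk_reflect(nk, 0.5, 0.08, 0.1, 0.9)
      xy <- perimeter_xy(s_cur, W, H, pmin(depth * cw, W / 2 - 0.01),
                         pmin(depth * ch, H / 2 - 0.01))
      x[idx] <- xy[, 1]; y[idx] <- xy[, 2]
      s_cur <- s_cur[nk]
    } else {
      x[idx] <- walk_reflect(nk, stats::runif(1, cw * 1.1, W - cw * 1.1),
                             0.3, cw * 1.05, W - cw * 1.05)
      y[idx] <- walk_reflect(nk, stats::runif(1, ch * 1.1, H - ch * 1.1),
                             0.3, ch * 1.05, H - ch * 1.05)
    }
  }
  structure(data.frame(time = (seq_len(n) - 1L) / rate, x = x, y = y),
            rate = rate, zoning = zoning, class = c("data.frame"))
}

#' Generate a synthetic impactor calibration table
#'
#' Piston exit velocities at the standard calibration pressures, three
#' replicates per pressure, following a quadratic pressure-velocity law
#' plus optional Gaussian measurement noise. The default coefficients span
#' the impactor's practical 0.01-1 J energy range with the 50 g piston.
#'
#' @param pressures air pressures (psi); default the standard ladder
#'   0.5, 1, 1.5, 2, 3, 5, 7, 10.
#' @param coeffs quadratic coefficients `c(intercept, linear, quadratic)`
#'   of velocity (m/s) against pressure (psi).
#' @param noise_sd velocity measurement noise SD (m/s).
#' @param seed RNG seed; required when `noise_sd > 0`.
#' @param replicates measurements per pressure (default 3).
#' @return A data frame with columns `pressure`, `velocity`, `replicate`.
#' @examples
#' tab <- gen_calibration_table(noise_sd = 0)
#' nrow(tab)  # 24 rows: 8 pressures x 3 replicates
#' @export
gen_calibration_table <- function(pressures = c(0.5, 1, 1.5, 2, 3, 5, 7, 10),
                                  coeffs = c(0.3, 0.75, -0.015),
                                  noise_sd = 0.05, seed = NULL,
                                  replicates = 3) {
  if (length(pressures) == 0 || any(pressures <= 0))
    stop("`pressures` must be non-empty and positive")
  if (length(coeffs) != 3) stop("`coeffs` must have length 3")
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required when `noise_sd` > 0")
    set.seed(seed)
  }
  p <- rep(pressures, each = replicates)
  v <- coeffs[1] + coeffs[2] * p + coeffs[3] * p^2
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
  data.frame(pressure = p, velocity = v,
             replicate = rep(seq_len(replicates), length(pressures)))
}
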