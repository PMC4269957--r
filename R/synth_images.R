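## Synthetic microglial silhouettes spanning the activation spectrum.
## Morphology follows the classic continuum: resting cells are ramified
## (small soma, long thin recursively branching processes), activation
## retracts and thickens the processes (hypertrophic, then bushy) until the
## cell is a smooth amoeboid blob. Outline complexity, and hence the
## box-counting fractal dimension, decreases monotonically along that
## sequence.

draw_disc <- function(m, cx, cy, r) {
  n <- nrow(m)
  i0 <- max(1L, floor(cx - r)); i1 <- min(n, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(ncol(m), ceiling(cy + r))
  if (i0 > i1 || j0 > j1) return(m)
  ii <- i0:i1; jj <- j0:j1
  dd <- outer((ii - cx)^2, (jj - cy)^2, "+")
  m[ii, jj] <- m[ii, jj] | (dd <= r^2)
  m
}

draw_segment <- function(m, x0, y0, x1, y1, half_width) {
  n <- nrow(m)
  i0 <- max(1L, floor(min(x0, x1) - half_width))
  i1 <- min(n, ceiling(max(x0, x1) + half_width))
  j0 <- max(1L, floor(min(y0, y1) - half_width))
  j1 <- min(ncol(m), ceiling(max(y0, y1) + half_width))
  if (i0 > i1 || j0 > j1) return(m)
  ii <- i0:i1; jj <- j0:j1
  px <- matrix(rep(ii, length(jj)), ncol = length(jj))
  py <- matrix(rep(jj, each = length(ii)), ncol = length(jj))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  t <- if (len2 > 0) pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2)) else 0
  d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  m[ii, jj] <- m[ii, jj] | (d2 <= half_width^2)
  m
}

## recursively grow a branching process from (x, y); each branch is drawn
## as two half-segments with a small bend (real processes are tortuous,
## and the wiggle contributes outline structure at intermediate scales)
grow_branch <- function(m, x, y, ang, len, hw, gens, spread, taper = 0.7) {
  a1 <- ang + stats::runif(1, -0.25, 0.25)
  xm <- x + len / 2 * cos(a1); ym <- y + len / 2 * sin(a1)
  a2 <- ang + stats::runif(1, -0.25, 0.25)
  x1 <- xm + len / 2 * cos(a2); y1 <- ym + len / 2 * sin(a2)
  m <- draw_segment(m, x, y, xm, ym, hw)
  m <- draw_segment(m, xm, ym, x1, y1, hw)
  if (gens > 1L) {
    nchild <- if (stats::runif(1) < 0.25) 3L else 2L
    for (s in seq_len(nchild)) {
      a <- a2 + (s - (nchild + 1) / 2) * stats::runif(1, 0.4, spread)
      m <- grow_branch(m, x1, y1, a,
                       len * taper * stats::runif(1, 0.85, 1.1),
                       max(hw * 0.85, 0.8), gens - 1L, spread, taper)
    }
  }
  m
}

#' Generate a synthetic microglial silhouette
#'
#' Draws one binary cell silhouette of the requested activation morphology:
#' `ramified` (resting: small soma, >= 3 generations of long thin
#' processes), `hypertrophic` (thickened soma, primary branches only),
#' `bushy` (retracted stubby protrusions) or `amoeboid` (fully activated:
#' smooth blob with a gently lobed boundary). The expected box-counting
#' fractal dimension of the outline decreases strictly along
#' ramified > hypertrophic > bushy > amoeboid.
#'
#' @param morphology one of `"ramified"`, `"hypertrophic"`, `"bushy"`,
#'   `"amoeboid"`.
#' @param size_px image side in pixels (>= 128).
#' @param seed RNG seed.
#' @return A logical `size_px` x `size_px` matrix (single connected
#'   silhouette).
#' @examples
#' img <- gen_microglia_image("ramified", 256, seed = 1)
#' boxcount_fd(img)
#' @export
gen_microglia_image <- function(morphology = c("ramified", "hypertrophic",
                                               "bushy", "amoeboid"),
                                size_px = 256, seed = 1) {
  morphology <- match.arg(morphology)
  if (size_px < 128) stop("`size_px` must be at least 128")
  set.seed(seed)
  sc <- size_px / 256
  m <- matrix(FALSE, size_px, size_px)
  cx <- size_px / 2 + stats::runif(1, -4, 4) * sc
  cy <- size_px / 2 + stats::runif(1, -4, 4) * sc
  if (morphology == "amoeboid") {
    ## smooth blob: low-order Fourier perturbation of the radius
    k <- 2:4
    amp <- stats::runif(3, 0.03, 0.10)
    ph <- stats::runif(3, 0, 2 * pi)
    r0 <- 30 * sc
    ii <- seq_len(size_px)
    px <- matrix(rep(ii, size_px), ncol = size_px)
    py <- matrix(rep(ii, each = size_px), ncol = size_px)
    th <- atan2(py - cy, px - cx)
    rr <- sqrt((px - cx)^2 + (py - cy)^2)
    rad <- r0 * (1 + amp[1] * cos(k[1] * th + ph[1]) +
                   amp[2] * cos(k[2] * th + ph[2]) +
                   amp[3] * cos(k[3] * th + ph[3]))
    m <- rr <= rad
    return(m)
  }
  par <- switch(morphology,
    ramified = list(soma = 6, nb = 6L, len = 34, hw = 1.0, gens = 5L,
                    spread = 0.8),
    hypertrophic = list(soma = 13, nb = 4L, len = 24, hw = 3.4, gens = 2L,
                        spread = 0.6),
    bushy = list(soma = 18, nb = 7L, len = 12, hw = 4.5, gens = 1L,
                 spread = 0.5))
  m <- draw_disc(m, cx, cy, par$soma * sc)
  angs <- stats::runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = par$nb + 1L)[-1] +
    stats::runif(par$nb, -0.3, 0.3)
  for (a in angs) {
    m <- grow_branch(m, cx + 0.8 * par$soma * sc * cos(a),
                     cy + 0.8 * par$soma * sc * sin(a), a,
                     par$len * sc * stats::runif(1, 0.8, 1.15),
                     par$hw * sc, par$gens, par$spread)
  }
  m
}
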