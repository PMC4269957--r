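## Shared lazily-computed fixtures (building the constrained trajectory and
## the morphology panel once keeps the suite fast).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

reference_spec <- function() impact_spec(noise_sd = 0)

reference_track <- function() {
  memo("reference_track", gen_impact_trajectory(reference_spec()))
}

reference_peaks <- function() {
  memo("reference_peaks", kinematic_pipeline(reference_track()))
}

peak_of <- function(pt, q) pt$peak[pt$quantity == q]

## fractal dimensions of the four morphologies over n seeds (256 px)
morphology_fd_panel <- function(n = 20) {
  memo("morph_fd", {
    morphs <- c("ramified", "hypertrophic", "bushy", "amoeboid")
    sapply(morphs, function(mo)
      sapply(seq_len(n), function(s)
        as.numeric(boxcount_fd(gen_microglia_image(mo, 256, seed = s)))))
  })
}

## Sierpinski triangle on a 2^k grid (Pascal's triangle mod 2)
sierpinski <- function(n = 512) {
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0L)
}

## a plain sinusoidal "track" (both markers) for filter-response oracles
sine_track <- function(freq, frame_rate = 5000, n = 2000, amp = 1e-3) {
  tt <- (seq_len(n) - 1) / frame_rate
  s <- amp * sin(2 * pi * freq * tt)
  marker_track(tt, s, s, s + 0.015, s, frame_rate = frame_rate)
}
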