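test_that("zero-phase filter has unit DC gain and the specified passband", {
  n <- 500
  tt <- (seq_len(n) - 1) / 5000
  const <- marker_track(tt, rep(0.01, n), rep(0.02, n), rep(0.03, n),
                        rep(0.02, n), frame_rate = 5000)
  out <- filter_track(const)
  expect_equal(out$m1_x, const$m1_x, tolerance = 1e-10)
  expect_equal(out$m2_y, const$m2_y, tolerance = 1e-10)

  ## 50 Hz well inside the 400 Hz passband: amplitude preserved within 1%
  tr50 <- sine_track(50)
  f50 <- filter_track(tr50)
  mid <- 500:1500  # away from edges
  expect_equal(max(abs(f50$m1_x[mid])) / max(abs(tr50$m1_x[mid])), 1,
               tolerance = 0.01)

  ## 2000 Hz far above cutoff: attenuated below 1% of input
  tr2k <- sine_track(2000)
  f2k <- filter_track(tr2k)
  expect_lt(max(abs(f2k$m1_x[mid])) / max(abs(tr2k$m1_x[mid])), 0.01)

  ## passband idempotence: double filtering changes a 50 Hz signal < 2%
  ff50 <- filter_track(f50)
  expect_equal(max(abs(ff50$m1_x[mid])) / max(abs(f50$m1_x[mid])), 1,
               tolerance = 0.02)

  expect_error(filter_track(tr50, cutoff = 2500), "Nyquist")
})

test_that("discrete differentiation matches analytic derivatives on polynomials", {
  fr <- 1000
  n <- 200
  tt <- (seq_len(n) - 1) / fr
  ## linear motion: constant velocity, zero acceleration at interior points
  trk <- marker_track(tt, 0.2 * tt, 0.1 * tt, 0.2 * tt + 0.015, 0.1 * tt,
                      frame_rate = fr)
  ks <- derive_kinematics(trk)
  interior <- 3:(n - 2)
  expect_equal(ks$linear_velocity[interior],
               rep(sqrt(0.2^2 + 0.1^2), length(interior)), tolerance = 1e-9)
  expect_equal(max(abs(ks$linear_acceleration[interior])), 0,
               tolerance = 1e-8)
  ## horizontal marker pair: deflection identically zero
  expect_equal(max(abs(ks$deflection)), 0, tolerance = 1e-12)

  ## quadratic motion: exact first and second derivatives at interior points
  a0 <- 3
  trq <- marker_track(tt, 0.5 * a0 * tt^2, rep(0, n),
                      0.5 * a0 * tt^2 + 0.015, rep(0, n), frame_rate = fr)
  kq <- derive_kinematics(trq)
  expect_equal(kq$linear_velocity[interior], a0 * tt[interior],
               tolerance = 1e-9)
  expect_equal(kq$linear_acceleration[interior],
               rep(a0, length(interior)), tolerance = 1e-7)

  ## constant-rate rotation: angular velocity = rate, zero angular accel;
  ## the angle sweeps far past +/- pi, so this also exercises unwrapping
  r <- 40
  trr <- marker_track(tt, rep(0, n), rep(0, n),
                      0.015 * cos(r * tt), 0.015 * sin(r * tt),
                      frame_rate = fr)
  kr <- derive_kinematics(trr)
  expect_gt(max(abs(kr$deflection)), pi)
  ## marker 2 orbits marker 1 counter-clockwise at rate r; the m2 -> m1
  ## line turns at the same rate
  expect_equal(kr$angular_velocity[interior],
               rep(r, length(interior)), tolerance = 1e-4)
  expect_equal(max(abs(kr$angular_acceleration[interior])), 0,
               tolerance = 1e-4)

  expect_error(derive_kinematics(trk, baseline_frames = 3), "baseline")
})

test_that("peak summaries: CV definitions and the delta-V invariant", {
  ## identical impacts give zero CV
  spec <- reference_spec()
  ks <- derive_kinematics(filter_track(reference_track()))
  pt2 <- summarize_peaks(list(ks, ks), animal_ids = c("a", "b"))
  expect_equal(pt2$cv, rep(0, 6))
  expect_equal(attr(pt2, "n_impacts"), 2L)

  ## CV across per-animal day-averaged peaks: hand-computed case.
  ## Three animals with day-averaged peak velocities 10, 12, 14 (scaled
  ## versions of the same series): CV = sd({10,12,14}) / 12.
  scale_series <- function(ks, f) {
    out <- ks
    for (cn in setdiff(names(ks), "time")) out[[cn]] <- ks[[cn]] * f
    out
  }
  base <- ks$linear_velocity
  pk <- max(ks$linear_velocity[3:(nrow(ks) - 2)])
  lst <- lapply(c(10, 12, 14) / pk, scale_series, ks = ks)
  pt3 <- summarize_peaks(lst, animal_ids = c("a", "b", "c"))
  expect_equal(pt3$cv[pt3$quantity == "linear_velocity"],
               sd(c(10, 12, 14)) / 12, tolerance = 1e-6)

  ## delta-V equals peak linear velocity for a stationary start
  pt <- reference_peaks()
  expect_equal(attr(pt, "delta_v"), peak_of(pt, "linear_velocity"))

  expect_error(summarize_peaks(list()), "non-empty")
})

test_that("impact energy follows KE = 0.5 m dV^2 exactly", {
  e <- impact_energy(0.0034, 6.6)
  expect_equal(e$kinetic_energy, 0.5 * 0.0034 * 6.6^2)
  expect_equal(round(e$kinetic_energy, 2), 0.07)
  expect_output(print(e), "0.07 J")
  expect_equal(impact_energy(1, 0)$kinetic_energy, 0)
  ## the 50 g piston at 4.472 m/s carries the 0.5 J input energy
  expect_equal(round(impact_energy(0.050, 4.472)$kinetic_energy, 2), 0.5)
  expect_error(impact_energy(0, 1), "positive")
  expect_error(impact_energy(0.003, -1), "non-negative")
})

test_that("track container validates sampling and round-trips through CSV", {
  tt <- (0:99) / 5000
  trk <- marker_track(tt, tt, tt, tt + 0.015, tt, frame_rate = 5000)
  f <- tempfile(fileext = ".csv")
  write_track(trk, f)
  back <- read_track(f)
  expect_equal(back$m1_x, trk$m1_x, tolerance = 1e-12)
  expect_equal(attr(back, "frame_rate"), 5000, tolerance = 1e-6)
  unlink(f)

  expect_error(marker_track(tt[1:30], tt[1:30], tt[1:30], tt[1:30],
                            tt[1:30], 5000), "50 frames")
  bad <- tt; bad[10] <- bad[10] + 1e-6
  expect_error(marker_track(bad, tt, tt, tt, tt, 5000), "uniform")
  na <- tt; na[5] <- NA
  expect_error(marker_track(tt, na, tt, tt, tt, 5000), "missing")
})
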