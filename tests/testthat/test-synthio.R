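test_that("impact-spec invariants are enforced", {
  expect_s3_class(impact_spec(), "impact_spec")
  expect_error(impact_spec(peak_velocity = -1), ">= 0")
  expect_error(impact_spec(t_velocity = 0.2), "inside")
  expect_error(impact_spec(t_acceleration = 5e-3), "t_acceleration")
  expect_error(impact_spec(t_ang_acceleration = 4e-3), "t_ang_acceleration")
  expect_error(impact_spec(frame_rate = 0), "frame_rate")
})

test_that("zero-motion spec yields a stationary two-marker track", {
  sp0 <- impact_spec(0, 1e-3, 0, 1e-3, 0, 1e-3, 0, 1e-3, 0, 1e-3, 0, 1e-3,
                     noise_sd = 0)
  tr <- gen_impact_trajectory(sp0)
  expect_equal(diff(range(tr$m1_x)), 0)
  expect_equal(diff(range(tr$m1_y)), 0)
  expect_equal(diff(range(tr$m2_x)), 0)
})

test_that("generated trajectory satisfies its peak constraints", {
  tr <- reference_track()
  sp <- reference_spec()

  ## brute-force oracle: unfiltered central differences on the raw
  ## positions recover peak velocity and displacement within 2%
  dt <- 1 / sp$frame_rate
  dx <- diff(tr$m1_x, lag = 2) / (2 * dt)
  dy <- diff(tr$m1_y, lag = 2) / (2 * dt)
  expect_equal(max(sqrt(dx^2 + dy^2)), sp$peak_velocity, tolerance = 0.02)
  disp <- sqrt((tr$m1_x - tr$m1_x[1])^2 + (tr$m1_y - tr$m1_y[1])^2)
  expect_equal(max(disp), sp$peak_displacement, tolerance = 0.02)

  ## rigid head: inter-marker distance constant to numerical precision
  L <- sqrt((tr$m1_x - tr$m2_x)^2 + (tr$m1_y - tr$m2_y)^2)
  expect_equal(diff(range(L)), 0, tolerance = 1e-12)

  ## stationary before impact: zero velocity over the first 5+ frames
  expect_equal(max(abs(diff(tr$m1_x[1:6]))), 0, tolerance = 1e-15)
  expect_equal(max(abs(diff(tr$m1_y[1:6]))), 0, tolerance = 1e-15)

  ## looped trajectory: displacement peaks, then decreases substantially
  expect_lt(disp[length(disp)], 0.5 * max(disp))
})

test_that("full pipeline round trip recovers the generating spec", {
  sp <- reference_spec()
  pt <- reference_peaks()
  want <- c(displacement = sp$peak_displacement,
            deflection = sp$peak_deflection,
            linear_velocity = sp$peak_velocity,
            linear_acceleration = sp$peak_acceleration,
            angular_velocity = sp$peak_ang_velocity,
            angular_acceleration = sp$peak_ang_acceleration)
  for (q in names(want))
    expect_equal(peak_of(pt, q), unname(want[q]), tolerance = 0.05)
  t_want <- c(displacement = sp$t_displacement,
              deflection = sp$t_deflection,
              linear_velocity = sp$t_velocity,
              linear_acceleration = sp$t_acceleration,
              angular_velocity = sp$t_ang_velocity,
              angular_acceleration = sp$t_ang_acceleration)
  dt <- 1 / sp$frame_rate
  for (q in names(t_want))
    expect_lte(abs(pt$t_peak[pt$quantity == q] - t_want[q]), 2 * dt)
})

test_that("round trip holds for rescaled impact severities", {
  for (f in c(0.8, 1.2)) {
    sp <- impact_spec(peak_displacement = 49.6e-3 * f,
                      peak_deflection = 2.6 * f,
                      peak_velocity = 6.6 * f,
                      peak_acceleration = 385.3 * 9.81 * f,
                      peak_ang_velocity = 305.8 * f,
                      peak_ang_acceleration = 253.6e3 * f,
                      noise_sd = 0)
    pt <- kinematic_pipeline(gen_impact_trajectory(sp))
    expect_equal(peak_of(pt, "linear_velocity"), 6.6 * f, tolerance = 0.05)
    expect_equal(peak_of(pt, "displacement"), 49.6e-3 * f, tolerance = 0.05)
    expect_equal(peak_of(pt, "angular_acceleration"), 253.6e3 * f,
                 tolerance = 0.05)
  }
})

test_that("tracking noise is seeded, reproducible, and does not move the truth", {
  sp <- impact_spec()  # default 0.05 mm noise
  expect_error(gen_impact_trajectory(sp), "seed")
  a1 <- gen_impact_trajectory(sp, seed = 11)
  a2 <- gen_impact_trajectory(sp, seed = 11)
  b <- gen_impact_trajectory(sp, seed = 12)
  expect_equal(a1$m1_y, a2$m1_y)
  expect_false(isTRUE(all.equal(a1$m1_y, b$m1_y)))
  ## the underlying noiseless construction still satisfies the constraints
  g <- attr(a1, "generator")
  expect_true(all(abs(g$value_rel_err) < 0.02))
})

test_that("infeasible constraint sets fail loudly, naming the violation", {
  ## acceleration far too small to reach the requested velocity in time
  expect_error(gen_impact_trajectory(
    impact_spec(peak_acceleration = 50 * 9.81, noise_sd = 0)),
    "infeasible")
  ## displacement smaller than the travel accumulated during the rise
  expect_error(gen_impact_trajectory(
    impact_spec(peak_displacement = 5e-3, noise_sd = 0)),
    "infeasible")
  ## mixed zero/non-zero peaks are not constructible
  expect_error(gen_impact_trajectory(
    impact_spec(peak_deflection = 0, peak_ang_velocity = 0,
                peak_ang_acceleration = 0, noise_sd = 0)),
    "infeasible")
})

test_that("synthetic microglia have the advertised gross structure", {
  am <- gen_microglia_image("amoeboid", 256, seed = 3)
  lab <- EBImage::bwlabel(am * 1L)
  expect_equal(max(lab), 1)                   # single connected blob
  ## smooth blob: area close to that of its convex-ish envelope; perimeter
  ## modest relative to a circle of equal area
  per <- sum(outline_image(am))
  expect_lt(per / (2 * sqrt(pi * sum(am))), 1.6)

  ra <- gen_microglia_image("ramified", 256, seed = 3)
  lab2 <- EBImage::bwlabel(ra * 1L)
  expect_equal(max(lab2), 1)                  # processes stay connected
  ## many fine processes: high perimeter-to-area ratio
  expect_gt(sum(outline_image(ra)) / (2 * sqrt(pi * sum(ra))), 3)

  expect_error(gen_microglia_image("fusiform", 256, 1), "arg")
  expect_error(gen_microglia_image("ramified", 64, 1), "128")
})

test_that("morphology ordering: outline fractal dimension tracks activation", {
  D <- morphology_fd_panel(20)
  mu <- colMeans(D)
  expect_true(mu["ramified"] > mu["hypertrophic"])
  expect_true(mu["hypertrophic"] > mu["bushy"])
  expect_true(mu["bushy"] > mu["amoeboid"])
  ## ramified > amoeboid in at least 95% of seed pairs
  expect_gte(mean(D[, "ramified"] > D[, "amoeboid"]), 0.95)
})

test_that("open-field generator hits its peripheral-occupancy target", {
  z <- zone_partition()
  for (f in c(0, 0.25, 2 / 3, 1)) {
    tr <- gen_openfield_track(f, duration = 300, rate = 30, seed = 7)
    peri <- impactkin:::classify_samples(tr$x, tr$y, z)
    expect_equal(mean(peri), f, tolerance = 0.02)
  }
  ## the documented worked case: 2/3 peripheral over 600 s
  tr <- gen_openfield_track(2 / 3, duration = 600, rate = 30, seed = 1)
  ti <- thigmotaxis_index(tr)
  expect_equal(attr(ti, "t_peripheral"), 400, tolerance = 0.01)
  expect_equal(attr(ti, "t_central"), 200, tolerance = 0.02)
  expect_equal(as.numeric(ti), 1 / 3, tolerance = 0.04)
  expect_error(gen_openfield_track(1.2, 60, seed = 1), "\\[0, 1\\]")
})

test_that("calibration tables have the study layout and recover their law", {
  tab <- gen_calibration_table(noise_sd = 0)
  expect_equal(nrow(tab), 24L)               # 8 pressures x 3 replicates
  expect_equal(sort(unique(tab$pressure)), c(0.5, 1, 1.5, 2, 3, 5, 7, 10))
  cal <- fit_calibration(tab)
  expect_equal(coef(cal), c(0.3, 0.75, -0.015), tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  ## with noise: r^2 < 1 but coefficients recovered within 3 standard
  ## errors in the vast majority of simulations
  truth <- c(0.3, 0.75, -0.015)
  ok <- vapply(1:100, function(s) {
    t2 <- gen_calibration_table(noise_sd = 0.05, seed = s)
    f2 <- fit_calibration(t2)
    se <- summary(f2$fit)$coefficients[, "Std. Error"]
    all(abs(coef(f2) - truth) < 3 * se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  f2 <- fit_calibration(gen_calibration_table(noise_sd = 0.05, seed = 1))
  expect_lt(f2$r_squared, 1)
  expect_error(gen_calibration_table(pressures = numeric()), "non-empty")
})
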