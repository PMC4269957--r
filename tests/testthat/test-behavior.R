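test_that("zone partition counts peripheral and central squares", {
  z <- zone_partition()
  expect_equal(z$n_peripheral, 28L)
  expect_equal(z$n_central, 32L)
  expect_equal(z$n_peripheral, 2L * (z$rows + z$cols) - 4L)
  z3 <- zone_partition(rows = 3, cols = 3)
  expect_equal(c(z3$n_peripheral, z3$n_central), c(8L, 1L))
  ## two-row grids have no interior
  z2 <- zone_partition(rows = 2, cols = 7)
  expect_equal(z2$n_central, 0L)
  expect_error(zone_partition(rows = 0, cols = 5), "positive")
})

test_that("thigmotaxis index follows (T_P - T_C) / (T_P + T_C)", {
  z <- zone_partition()
  ## all samples peripheral -> TI = 1; all central -> TI = -1
  corner <- data.frame(x = rep(0.5, 30), y = rep(0.5, 30))
  expect_equal(as.numeric(thigmotaxis_index(corner, z)), 1)
  centre <- data.frame(x = rep(7, 30), y = rep(12, 30))
  expect_equal(as.numeric(thigmotaxis_index(centre, z)), -1)
  ## T_P = T_C -> 0
  both <- rbind(corner, centre)
  expect_equal(as.numeric(thigmotaxis_index(both, z)), 0)
  ## T_P = 400 s, T_C = 200 s -> 1/3
  tr <- rbind(corner[rep(1, 400), ], centre[rep(1, 200), ])
  expect_equal(as.numeric(thigmotaxis_index(tr, z)), 1 / 3)
  expect_error(thigmotaxis_index(data.frame(x = numeric(), y = numeric()),
                                 z), "zero total time")
  expect_error(thigmotaxis_index(data.frame(x = 99, y = 1), z), "bounds")
})

test_that("swapping zone labels negates the thigmotaxis index", {
  z <- zone_partition()
  zswap <- z
  zswap$peripheral <- !z$peripheral
  for (f in c(0.2, 0.5, 0.8)) {
    tr <- gen_openfield_track(f, duration = 120, rate = 20, seed = 3)
    expect_equal(as.numeric(thigmotaxis_index(tr, zswap)),
                 -as.numeric(thigmotaxis_index(tr, z)))
  }
})

test_that("synthetic open-field tracks land on the requested index", {
  for (f in c(0.1, 0.5, 0.9)) {
    tr <- gen_openfield_track(f, duration = 300, rate = 30, seed = 5)
    expect_equal(as.numeric(thigmotaxis_index(tr)), 2 * f - 1,
                 tolerance = 0.04)
  }
})

test_that("NSS counts failures, bounded in 0..10, permutation-invariant", {
  expect_equal(nss_score(rep(TRUE, 10)), 10L)
  expect_equal(nss_score(rep(FALSE, 10)), 0L)
  x <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(nss_score(x), 3L)
  set.seed(1)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    s <- nss_score(y)
    expect_identical(s, nss_score(sample(y)))
    expect_true(s >= 0L && s <= 10L)
  }
  expect_error(nss_score(rep(TRUE, 9)), "10 tasks")
  expect_error(nss_score(c(rep(TRUE, 9), NA)), "missing")
})

test_that("passive-avoidance latencies are capped at the session ceiling", {
  expect_equal(pa_latency(NA), 300)
  expect_equal(pa_latency(42), 42)
  expect_equal(pa_latency(400), 300)
  expect_equal(pa_latency(c(42, NA, 400), cap = 300), c(42, 300, 300))
  expect_equal(pa_latency(100, cap = 60), 60)
  expect_error(pa_latency(-5), "non-negative")
  expect_error(pa_latency(10, cap = 0), "positive")
})

test_that("fold change and Bonferroni helpers match their definitions", {
  expect_equal(fold_change(c(10, 10), c(10, 10)), 1)
  expect_equal(fold_change(15, 10), 1.5)
  expect_error(fold_change(5, 0), "non-zero")
  expect_equal(bonferroni_alpha(5), 0.01)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(4, alpha = 0.1), 0.025)
  expect_error(bonferroni_alpha(0), "at least 1")
})
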