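test_that("corner-load CoP matches the moment-balance solution", {
  geom <- board_geometry(433, 238)
  # equal loads: centred
  rec <- make_board_rec(loads = matrix(20, 3, 4))
  cop <- cop_from_corner_loads(rec, geom)
  expect_equal(cop$ap, rep(0, 3))
  expect_equal(cop$ml, rep(0, 3))

  # all load on the top-right corner: half-span in both directions
  loads <- matrix(0, 2, 4); loads[, 2] <- 500
  rec <- make_board_rec(c(0, 0.01), loads)
  cop <- cop_from_corner_loads(rec, geom)
  expect_equal(cop$ap, rep(238 / 2, 2))
  expect_equal(cop$ml, rep(433 / 2, 2))

  # asymmetric case against the independent torque-balance oracle
  rec <- make_board_rec(c(0, 0.01), matrix(c(10, 30, 10, 30), 2, 4,
                                           byrow = TRUE))
  cop <- cop_from_corner_loads(rec, board_geometry(400, 200))
  expect_equal(cop$ml[1], 100)
  oracle <- oracle_cop_from_loads(10, 30, 10, 30, 400, 200)
  expect_equal(cop$ap[1], unname(oracle["ap"]), tolerance = 1e-12)
  expect_equal(cop$ml[1], unname(oracle["ml"]), tolerance = 1e-12)

  # random loads vs oracle
  set.seed(42)
  for (i in 1:20) {
    l <- runif(4, 50, 400)
    rec <- make_board_rec(c(0, 0.01), matrix(l, 2, 4, byrow = TRUE))
    cop <- cop_from_corner_loads(rec, geom)
    oracle <- oracle_cop_from_loads(l[1], l[2], l[3], l[4], 433, 238)
    expect_equal(cop$ap[1], unname(oracle["ap"]), tolerance = 1e-10)
    expect_equal(cop$ml[1], unname(oracle["ml"]), tolerance = 1e-10)
  }
})

test_that("corner-load CoP is scale invariant and confined to the sensor span", {
  geom <- board_geometry()
  set.seed(7)
  for (i in 1:25) {
    l <- matrix(runif(8, 20, 300), 2, 4)
    rec <- make_board_rec(c(0, 0.01), l)
    cop1 <- cop_from_corner_loads(rec, geom)
    c_mult <- runif(1, 0.5, 5)
    cop2 <- cop_from_corner_loads(make_board_rec(c(0, 0.01), l * c_mult), geom)
    expect_equal(cop1$ap, cop2$ap, tolerance = 1e-10)
    expect_equal(cop1$ml, cop2$ml, tolerance = 1e-10)
    expect_true(all(abs(cop1$ml) <= 433 / 2 + 1e-9))
    expect_true(all(abs(cop1$ap) <= 238 / 2 + 1e-9))
  }
})

test_that("low total load raises a low-load error with the sample index", {
  loads <- matrix(30, 3, 4); loads[2, ] <- 5
  rec <- make_board_rec(loads = loads)
  err <- expect_error(cop_from_corner_loads(rec), class = "sa_low_load_error")
  expect_identical(err$index, 2L)
  # configurable floor
  expect_silent(cop_from_corner_loads(rec, load_floor_n = 10))
})

test_that("wrench CoP matches the surface-transport solution", {
  # no moment: centred
  cop <- cop_from_wrench(make_plate_rec(c(0, 0.001), Fz = 800))
  expect_equal(cop$ap, c(0, 0))
  expect_equal(cop$ml, c(0, 0))

  # single-term closed form: My = -80 N.m, Fz = 800 N -> ml = +100 mm
  cop <- cop_from_wrench(make_plate_rec(c(0, 0.001), Fz = 800, My = -80))
  expect_equal(cop$ml, c(100, 100))

  # full transport with horizontal force and dz = 53 mm
  cop <- cop_from_wrench(make_plate_rec(c(0, 0.001), Fz = 700, Fx = 10,
                                        My = -70),
                         surface_offset_dz_mm = 53)
  expect_equal(cop$ml[1], (70 - 10 * 0.053) / 700 * 1000, tolerance = 1e-12)
  oracle <- oracle_cop_from_wrench(Fx = 10, Fy = 0, Fz = 700, Mx = 0,
                                   My = -70, dz_m = 0.053)
  expect_equal(cop$ml[1], unname(oracle["ml"]), tolerance = 1e-10)
  expect_equal(cop$ap[1], unname(oracle["ap"]), tolerance = 1e-10)

  # low |Fz| guard
  expect_error(cop_from_wrench(make_plate_rec(c(0, 0.001), Fz = 20)),
               class = "sa_low_load_error")
})

test_that("uniform resampling interpolates linearly without extrapolation", {
  s <- data.frame(t = c(0, 1), ap = c(0, 10), ml = c(0, -10))
  traj <- resample_uniform(s, rate = 1000)
  expect_equal(traj$n, 1001L)
  expect_equal(traj$ap[501], 5, tolerance = 1e-12)   # midpoint
  expect_equal(traj$ml[501], -5, tolerance = 1e-12)
  expect_equal(traj$ap[1001], 10, tolerance = 1e-12) # grid ends at last sample

  # identity on already-uniform input
  t <- seq(0, 0.5, by = 0.001)
  s <- data.frame(t = t, ap = sin(t), ml = cos(t))
  traj <- resample_uniform(s, rate = 1000)
  expect_identical(traj$ap, s$ap)
  expect_identical(traj$ml, s$ml)

  # exact on piecewise-linear signals at interior points
  t_raw <- c(0, 0.013, 0.04, 0.081, 0.1)
  f <- function(t) 3 * t + 0.5
  s <- data.frame(t = t_raw, ap = f(t_raw), ml = -f(t_raw))
  traj <- resample_uniform(s, rate = 1000)
  grid <- t_raw[1] + (seq_len(traj$n) - 1) / 1000
  expect_lt(max(abs(traj$ap - f(grid))), 1e-12)

  # grid anchored at the first raw timestamp, not t = 0
  s <- data.frame(t = c(2.0005, 2.5005, 3.0005), ap = 1:3, ml = 3:1)
  expect_equal(resample_uniform(s, 1000)$start_time, 2.0005)

  expect_error(resample_uniform(data.frame(t = 0, ap = 1, ml = 1)),
               class = "sa_too_short_error")
  expect_error(resample_uniform(data.frame(t = c(0, 1e-4), ap = 1:2, ml = 1:2),
                                rate = 1000),
               class = "sa_too_short_error")
})

test_that("jittered low-rate sinusoid is recovered within the interpolation bound", {
  # 1 Hz, 10 mm amplitude, ~100 Hz samples with timestamp jitter; linear
  # interpolation error bound h^2 * max|f''| / 8 = 0.015^2*(10*(2pi)^2)/8
  set.seed(3)
  t <- sort(runif(1000, 0, 10))
  t <- t[c(TRUE, diff(t) > 1e-4)]
  f <- function(t) 10 * sin(2 * pi * t)
  s <- data.frame(t = t, ap = f(t), ml = f(t))
  traj <- resample_uniform(s, rate = 1000)
  grid <- t[1] + (seq_len(traj$n) - 1) / 1000
  h <- max(diff(t))
  bound <- h^2 * 10 * (2 * pi)^2 / 8
  expect_lt(max(abs(traj$ap - f(grid))), bound)
})

test_that("zero-phase Butterworth filter honors the analytic contract", {
  # DC invariance
  traj <- cop_trajectory(rep(7, 2000), rep(-2, 2000), rate = 1000)
  out <- butterworth_lowpass(traj)
  expect_lt(max(abs(out$ap - 7)), 1e-9)
  expect_lt(max(abs(out$ml + 2)), 1e-9)

  # passband and stopband amplitude vs the analytic double-pass magnitude
  t <- (0:9999) / 1000
  mid <- 2000:8000
  for (freq in c(1, 50)) {
    s <- sin(2 * pi * freq * t)
    f <- butterworth_lowpass(cop_trajectory(s, s, 1000))
    ratio <- sqrt(mean(f$ap[mid]^2) / mean(s[mid]^2))
    expect_equal(ratio, oracle_butter_amplitude(freq), tolerance = 0.05)
  }
  s1 <- sin(2 * pi * 1 * t)
  f1 <- butterworth_lowpass(cop_trajectory(s1, s1, 1000))
  expect_gt(sqrt(mean(f1$ap[mid]^2) / mean(s1[mid]^2)), 0.99)

  # output has same length/rate; too-short input is rejected
  expect_identical(out$n, traj$n)
  expect_identical(out$rate, traj$rate)
  expect_error(butterworth_lowpass(cop_trajectory(1:5, 1:5, 1000)),
               class = "sa_too_short_error")
  expect_error(butterworth_lowpass(cop_trajectory(1:100, 1:100, 20)),
               class = "sa_validation_error")  # rate must exceed 2*cutoff
})

test_that("filtering never increases energy of zero-mean signals", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(3000)
    x <- x - mean(x)
    traj <- cop_trajectory(x, x, 1000)
    once <- butterworth_lowpass(traj)
    twice <- butterworth_lowpass(once)
    expect_lte(sum(once$ap^2), sum(x^2))
    expect_lte(sum(twice$ap^2), sum(once$ap^2) * (1 + 1e-12))
  }
})

test_that("the full conditioning chain is deterministic", {
  set.seed(5)
  loads <- matrix(runif(400, 100, 300), 100, 4)
  t <- cumsum(runif(100, 0.005, 0.015))
  rec1 <- make_board_rec(t, loads)
  rec2 <- make_board_rec(t, loads)
  tr1 <- process_trial(rec1)
  tr2 <- process_trial(rec2)
  expect_identical(tr1$ap, tr2$ap)
  expect_identical(tr1$ml, tr2$ml)
})
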