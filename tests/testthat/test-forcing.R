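test_that("radiant exchange follows black-body net flux", {
  expect_equal(radiant_exchange(400, 400), 0)
  # hand evaluation: sigma (673^4 - 300^4)
  expect_equal(radiant_exchange(300, 673),
               5.67e-8 * (673^4 - 300^4))
  expect_equal(radiant_exchange(300, 673), 1.12e4, tolerance = 0.01)
  # antisymmetry
  expect_equal(radiant_exchange(350, 500), -radiant_exchange(500, 350))
})

test_that("fire flux from temperature clamps and matches the hand value", {
  expect_equal(fire_flux_from_temperature(500, 500), 0)
  # surface-fire anchor temperatures: 823 K fire over 285 K ambient
  expect_equal(fire_flux_from_temperature(823, 285),
               5.67e-8 * (823^4 - 285^4))
  expect_equal(fire_flux_from_temperature(823, 285), 2.56e4,
               tolerance = 0.01)
  expect_message(q <- fire_flux_from_temperature(280, 285), "clamped")
  expect_equal(q, 0)
  # monotone in fire temperature
  expect_true(all(diff(fire_flux_from_temperature(seq(300, 900, 50), 295)) > 0))
  # composition consistency with radiant_exchange when T_f plays ambient
  expect_equal(fire_flux_from_temperature(700, 300),
               radiant_exchange(300, 700))
})

test_that("height interpolation scales the peak flux exponentially", {
  prof <- height_profile()   # c = -0.0155 by default
  shape <- list(times = 0:10 * 60, shape = c(0, 1, rep(0.5, 9)))
  f0 <- height_interpolated_flux(prof, 0, shape)
  f20 <- height_interpolated_flux(prof, 20, shape)
  expect_equal(max(f20$flux) / max(f0$flux), exp(-0.0155 * 20))
  expect_equal(exp(-0.0155 * 20), 0.7334, tolerance = 1e-3)
  # ground flux equals the fire-temperature-derived peak
  expect_equal(max(f0$flux), fire_flux_from_temperature(823, 285))
  # non-increasing with height for c < 0
  peaks <- vapply(c(0, 4, 8, 12, 17, 20), function(z)
    max(height_interpolated_flux(prof, z, shape)$flux), 0)
  expect_true(all(diff(peaks) < 0))
  expect_error(height_interpolated_flux(prof, 25, shape), "z must lie")
})

test_that("circumferential distributions match the prescribed shares", {
  nw <- 16L
  m2 <- circumferential_distribution(2, nw)
  expect_true(all(m2 == 1))
  m3 <- circumferential_distribution(3, nw)
  expect_equal(unique(m3[1:4]), 1.5)     # front quadrant: 3/8 of dose
  expect_equal(unique(m3[5:8]), 0.5)     # right quadrant: 1/8
  m4 <- circumferential_distribution(4, nw)
  expect_equal(m4[9] / m4[1], 2)         # lee twice the front share
  expect_true(all(m4[5:8] == 0) && all(m4[13:16] == 0))
  m1 <- circumferential_distribution(1, nw)
  expect_true(all(m1[1:4] == 2) && all(m1[9:12] == 2))
  expect_true(all(m1[c(5:8, 13:16)] == 0))
  m5 <- circumferential_distribution(5, nw)
  expect_equal(m5[c(1, 5, 9, 13)], c(1, 0.5, 2, 0.5))
  # dose conservation: mean multiplier exactly 1 for every case
  for (cs in 1:5)
    expect_equal(mean(circumferential_distribution(cs, nw)), 1)
  expect_error(circumferential_distribution(6, nw), "unknown")
  expect_error(circumferential_distribution(1, 12), "divisible by 8")
})

test_that("delivered energy is case-invariant for a shared base series", {
  base <- small_pulse()
  nw <- 16L
  dose <- vapply(1:5, function(cs) {
    m <- circumferential_distribution(cs, nw)
    fx <- base$flux %*% t(m)
    # equal wedge areas: total dose is the time integral summed over wedges
    sum(apply(fx, 2, function(q)
      sum(diff(base$times) * (head(q, -1) + tail(q, -1)) / 2)))
  }, 0)
  expect_equal(max(abs(dose - dose[1])) / dose[1], 0, tolerance = 1e-10)
})

test_that("synthetic lab pulse has the stated shape and integral", {
  f <- synthetic_lab_pulse(1e4, ramp_s = 60, hold_s = 120, cool_s = 300)
  expect_s3_class(f, "forcing_series")
  expect_equal(max(f$flux), 1e4)
  expect_equal(f$flux[f$times == 0], 0)
  # closed-form integral: ramp triangle + hold + truncated exponential
  tau <- 300 / 5
  exact <- 1e4 * (60 / 2 + 120 + tau * (1 - exp(-300 / tau)))
  trap <- sum(diff(f$times) * (head(f$flux, -1) + tail(f$flux, -1)) / 2)
  expect_equal(trap, exact, tolerance = 5e-4)
  # zero peak -> identically zero series
  expect_true(all(synthetic_lab_pulse(0, 10, 10, 10)$flux == 0))
  # zero ramp -> step onset
  fs <- synthetic_lab_pulse(1e4, 0, 60, 60)
  expect_equal(fs$flux[fs$times == 0], 1e4)
  # determinism
  expect_identical(synthetic_lab_pulse(1e4, 60, 120, 300),
                   synthetic_lab_pulse(1e4, 60, 120, 300))
})

test_that("forcing CSV round-trips and rejects malformed input", {
  set.seed(42)
  f <- forcing_series(times = seq(0, 100, by = 5),
                      flux = matrix(runif(21 * 4, 0, 3e4), 21, 4),
                      T_ambient = 295 + runif(21))
  path <- tempfile(fileext = ".csv")
  write_forcing_csv(f, path)
  f2 <- read_forcing_csv(path)
  expect_equal(f2$times, f$times, tolerance = 1e-12)
  expect_equal(unname(f2$flux), unname(f$flux), tolerance = 1e-12)
  expect_equal(f2$T_ambient, f$T_ambient, tolerance = 1e-12)

  # single flux column broadcasts to all wedges
  f1 <- forcing_series(c(0, 10), c(100, 200), 295)
  at <- forcing_at(f1, 5, n_wedges = 16)
  expect_equal(at$flux, rep(150, 16))
  expect_equal(at$T_ambient, 295)

  # malformed inputs are rejected with the offending row
  bad <- data.frame(time_s = c(0, 10, 5), T_ambient_K = 295,
                    flux = c(0, 1, 2))
  bp <- tempfile(fileext = ".csv"); write.csv(bad, bp, row.names = FALSE)
  expect_error(read_forcing_csv(bp), "row 3")
  bad2 <- data.frame(time_s = c(0, 10, 20), T_ambient_K = 295,
                     flux = c(0, -1, 2))
  bp2 <- tempfile(fileext = ".csv"); write.csv(bad2, bp2, row.names = FALSE)
  expect_error(read_forcing_csv(bp2), "row 2")
  bad3 <- data.frame(time_s = c(0, 10), flux = c(0, 1))
  bp3 <- tempfile(fileext = ".csv"); write.csv(bad3, bp3, row.names = FALSE)
  expect_error(read_forcing_csv(bp3), "T_ambient_K")
})

test_that("imported per-height series derive flux from fire temperature", {
  df <- data.frame(time_s = rep(c(0, 60, 120), 2),
                   height_m = rep(c(0, 10), each = 3),
                   T_fire_K = c(285, 823, 400, 285, 600, 350))
  p <- tempfile(fileext = ".csv"); write.csv(df, p, row.names = FALSE)
  series <- import_fire_series_csv(p, T_ambient = 285)
  expect_named(series, c("0", "10"))
  expect_equal(max(series[["0"]]$flux),
               fire_flux_from_temperature(823, 285))
  expect_error(import_fire_series_csv(tempfile()), "not found")
})
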