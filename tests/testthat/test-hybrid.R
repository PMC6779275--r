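# hybrid_simulator: death detection, operator splitting and the mean-field
# deterministic model

test_that("death detection interpolates the first threshold crossing", {
  flat <- data.frame(time_min = 0:10, fret_rate_nm_min = rep(0, 11))
  expect_false(detect_death(flat, 5)$died)
  ramp <- data.frame(time_min = 0:10, fret_rate_nm_min = 0:10)
  ev <- detect_death(ramp, 5)
  expect_true(ev$died)
  expect_equal(ev$death_time_min, 5)
  # interpolation between grid points
  ev2 <- detect_death(ramp, 4.5)
  expect_equal(ev2$death_time_min, 4.5)
  # touching the threshold exactly at a grid point dies there (>=, not >)
  touch <- data.frame(time_min = 0:4, fret_rate_nm_min = c(0, 1, 5, 1, 0))
  expect_equal(detect_death(touch, 5)$death_time_min, 2)
  expect_error(detect_death(data.frame(time_min = numeric(0),
                                       fret_rate_nm_min = numeric(0)), 1),
               class = "riposim_bad_value")
  expect_error(detect_death(ramp, 0), class = "riposim_bad_value")
})

test_that("zero dose produces no origins and no death in any simulator", {
  cfg <- default_cfg()
  h <- simulate_cell_hybrid(cfg, 0, TRUE, seed = 1, t_max = 60)
  expect_equal(nrow(h$platforms), 0L)
  expect_false(h$death$died)
  f <- simulate_cell_full_ssa(cfg, 0, TRUE, seed = 1, t_max = 60)
  expect_false(f$death$died)
  d <- deterministic_full_model(cfg, 0, TRUE, t_max = 60)
  expect_false(d$death$died)
})

test_that("halving the splitting window leaves ensemble deaths unchanged", {
  # the split is unbiased: mean death time over an ensemble moves < 2%
  cfg <- default_cfg()
  mean_death <- function(dt) {
    mean(vapply(1:40, function(i) {
      simulate_cell_hybrid(cfg, 50, TRUE, seed = 800 + i, t_max = 240,
                           dt_sync = dt)$death$death_time_min
    }, numeric(1)))
  }
  m1 <- mean_death(0.1)
  m2 <- mean_death(0.05)
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("pool reconciliation clamps are absent in routine runs", {
  cfg <- default_cfg()
  tr <- simulate_cell_hybrid(cfg, 50, TRUE, seed = 5, t_max = 120)
  expect_equal(tr$clamp_events, 0L)
})

test_that("deterministic death time decreases strictly with dose", {
  cfg <- default_cfg()
  deaths <- vapply(c(5, 7.5, 50, 250), function(d) {
    deterministic_full_model(cfg, d, TRUE, t_max = 2400)$death$death_time_min
  }, numeric(1))
  expect_true(all(is.finite(deaths)))
  expect_true(all(diff(deaths) < 0))
})

test_that("clustering accelerates the deterministic death", {
  cfg <- default_cfg()
  on <- deterministic_full_model(cfg, 5, TRUE, t_max = 2400)
  off <- deterministic_full_model(cfg, 5, FALSE, t_max = 2400)
  expect_lt(on$death$death_time_min, off$death$death_time_min)
})

test_that("hybrid trajectories expose aligned, monotone observables", {
  cfg <- default_cfg()
  tr <- simulate_cell_hybrid(cfg, 5, TRUE, seed = 31, t_max = 180)
  expect_equal(length(tr$time_min), nrow(tr$series))
  expect_true(all(diff(tr$series$fret_cleaved) >= -1e-12))
  expect_true(all(diff(tr$series$cum_casp8_dimers) >= 0))
  # FRET conservation on the hybrid path
  total <- cfg$initial_nm$fret_substrate
  expect_true(all(abs(tr$series$fret_intact + tr$series$fret_cleaved -
                        total) < 1e-4))
})
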