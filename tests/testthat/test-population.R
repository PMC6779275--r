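# population_analysis: ramp noise, histograms, survival, averages, scans

test_that("ramp CV follows the std/mean definition", {
  expect_equal(ramp_cv(fake_trajectory(rep(3, 50))), 0)
  expect_equal(ramp_cv(fake_trajectory(rep(0, 50))), 0)   # zero mean -> 0
  alt <- fake_trajectory(rep(c(0, 2), 100))
  expect_equal(ramp_cv(alt), 1, tolerance = 0.01)
  # the window ends at death
  tr <- fake_trajectory(c(rep(1, 50), rep(100, 50)))
  death <- structure(list(died = TRUE, death_time_min = 50,
                          threshold_rate = 1), class = "death_event")
  expect_equal(ramp_cv(tr, death), 0)
})

test_that("a single-cell ensemble reduces to the hybrid simulator", {
  cfg <- default_cfg()
  ens <- run_ensemble(cfg, 50, TRUE, n_cells = 1, master_seed = 5,
                      t_max = 120)
  tr <- simulate_cell_hybrid(cfg, 50, TRUE, seed = derive_cell_seed(5, 1),
                             t_max = 120)
  expect_equal(ens$summary$death_time_min[1], tr$death$death_time_min)
})

test_that("ensembles are reproducible under the master seed", {
  cfg <- default_cfg()
  a <- run_ensemble(cfg, 50, TRUE, n_cells = 5, master_seed = 3, t_max = 90,
                    keep_columns = NULL)
  b <- run_ensemble(cfg, 50, TRUE, n_cells = 5, master_seed = 3, t_max = 90,
                    keep_columns = NULL)
  expect_identical(a$summary$death_time_min, b$summary$death_time_min)
  expect_identical(a$summary$ramp_cv, b$summary$ramp_cv)
})

test_that("the histogram report flags known mixtures and rejects tiny n", {
  x <- generate_fixtures("two_mode_delays", seed = 2)$data
  rep2 <- delay_histogram(x, bin_width_min = 30, seed = 4)
  expect_true(rep2$bimodal)
  expect_lt(rep2$dip_p, 0.05)
  expect_gt(rep2$ashman_d, 2)
  same <- delay_histogram(rep(240, 50), bin_width_min = 30)
  expect_false(same$bimodal)
  expect_gte(same$dip_p, 0.05)
  expect_error(delay_histogram(1:5), class = "riposim_bad_value")
})

test_that("the dip test separates uniform from well-split samples", {
  set.seed(9)
  u <- runif(300)
  expect_gt(dip_test(u, n_boot = 300, seed = 2)$p_value, 0.05)
  mix <- c(rnorm(150, 0, 1), rnorm(150, 8, 1))
  expect_lt(dip_test(mix, n_boot = 300, seed = 2)$p_value, 0.05)
})

test_that("survival fractions bracket correctly", {
  ens <- scenario_ensemble(50, TRUE)
  expect_equal(survival_fraction(ens, 0), 1)
  expect_equal(survival_fraction(ens, 1440), 0)
  s300 <- survival_fraction(ens, 300)
  expect_gte(s300, 0)
  expect_lte(s300, 1)
})

test_that("population averages require aligned grids", {
  t1 <- list(time_min = 0:10, series = data.frame(cum_casp8_dimers = 0:10))
  t2 <- list(time_min = 0:10, series = data.frame(cum_casp8_dimers = 0:10))
  pa <- population_average(list(t1, t2))
  expect_true(all(pa$cv == 0))
  expect_equal(pa$mean, 0:10)
  t3 <- list(time_min = 0:5, series = data.frame(cum_casp8_dimers = 0:5))
  expect_error(population_average(list(t1, t3)),
               class = "riposim_bad_value")
  expect_error(population_average(list(t1)), class = "riposim_bad_value")
})

test_that("parameter scans validate their inputs and collapse to one call", {
  cfg <- default_cfg()
  expect_error(parameter_scan(cfg, "nonsense", 1), "scannable",
               class = "riposim_bad_value")
  expect_error(parameter_scan(cfg, "xiap_total", numeric(0)),
               class = "riposim_bad_value")
  one <- parameter_scan(cfg, "xiap_total", 63, dose_ng_ml = 50,
                        t_max = 300)
  ref <- deterministic_full_model(cfg, 50, TRUE, t_max = 300)
  expect_equal(one$death_time_min, ref$death$death_time_min)
})
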