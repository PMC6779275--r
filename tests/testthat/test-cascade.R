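# caspase_cascade_ode: mass-action structure, integration contract and
# closed-form oracles

test_that("the quiescent state is a fixed point", {
  cfg <- default_cfg()
  y0 <- cascade_initial_state(cfg)
  d <- cascade_rhs(y0, cfg$rates, casp8_source = 0)
  expect_true(all(abs(d) < 1e-12))
  tr <- integrate_cascade(y0, cfg$rates, function(t) 0, seq(0, 120, 10))
  expect_equal(unlist(tr[nrow(tr), -1]), y0, tolerance = 1e-8)
})

test_that("without XIAP active Casp3 increases while ProCasp3 lasts", {
  cfg <- config_update(default_model_config(),
                       initial_nm = list(xiap = 0),
                       rates = list(k_casp3_auto_nm_min = 0,
                                    k_basal_deg_min = 0.001))
  y0 <- cascade_initial_state(cfg)
  tr <- integrate_cascade(y0, cfg$rates, function(t) 0.01, seq(0, 300, 5))
  expect_true(all(diff(tr$casp3_active) > 0))
  expect_true(all(tr$procasp3 > 0))
})

test_that("the linear subsystem matches its matrix-exponential solution", {
  # freeze the dimer level and switch off every bilinear state-state term;
  # what remains is linear in (procasp3, casp3, fret_intact)
  cfg <- config_update(default_model_config(), rates = list(
    k_casp3_auto_nm_min = 0, k_casp8_mono_dimer_nm_min = 0,
    koff_casp8_dimer_min = 0, k_casp3_casp6_nm_min = 0,
    k_casp6_casp8_nm_min = 0, kon_xiap_casp3_nm_min = 0))
  c8d <- 0.75
  y0 <- cascade_initial_state(cfg)
  y0[["casp8_dimer_active"]] <- c8d
  times <- seq(0, 240, 20)
  tr <- integrate_cascade(y0, cfg$rates, function(t) 0, times, tol = 1e-10)
  k1 <- cfg$rates$k_casp8_casp3_nm_min * c8d
  kdeg <- cfg$rates$k_basal_deg_min
  kf <- cfg$rates$k_fret_cleave_nm_min * c8d
  A <- rbind(c(-k1, 0, 0),          # procasp3
             c(k1, -kdeg, 0),       # casp3
             c(0, 0, -kf))          # fret_intact
  x0 <- c(y0[["procasp3"]], 0, y0[["fret_intact"]])
  for (i in seq_along(times)) {
    xt <- as.numeric(Matrix::expm(A * times[i]) %*% x0)
    expect_equal(tr$procasp3[i], xt[1], tolerance = 1e-6)
    expect_equal(tr$casp3_active[i], xt[2], tolerance = 1e-6)
    expect_equal(tr$fret_intact[i], xt[3], tolerance = 1e-6)
  }
})

test_that("integration converges under tolerance refinement", {
  cfg <- default_cfg()
  y0 <- cascade_initial_state(cfg)
  src <- function(t) 2e-3
  t_end <- seq(0, 360, 60)
  a <- integrate_cascade(y0, cfg$rates, src, t_end, tol = 1e-8)
  b <- integrate_cascade(y0, cfg$rates, src, t_end, tol = 5e-9)
  rel <- abs(tail(a$fret_cleaved, 1) - tail(b$fret_cleaved, 1)) /
    tail(a$fret_cleaved, 1)
  expect_lt(rel, 1e-6)
})

test_that("FRET substrate is conserved and its cleavage is monotone", {
  cfg <- default_cfg()
  y0 <- cascade_initial_state(cfg)
  tr <- integrate_cascade(y0, cfg$rates, function(t) 5e-3, seq(0, 600, 10))
  total <- cfg$initial_nm$fret_substrate
  expect_true(all(abs(tr$fret_intact + tr$fret_cleaved - total) < 1e-5))
  expect_true(all(diff(tr$fret_cleaved) >= 0))
})

test_that("XIAP at its default level suppresses Casp3 for ten hours", {
  cfg <- default_cfg()
  y0 <- cascade_initial_state(cfg)
  tr <- integrate_cascade(y0, cfg$rates, function(t) 1e-4, seq(0, 600, 10))
  expect_lt(max(tr$casp3_active), 0.5)   # nM; pre-MOMP sacrifice of Casp3
})

test_that("the cleavage-rate readout is bilinear", {
  cfg <- default_cfg()
  st <- cascade_initial_state(cfg)
  expect_equal(fret_cleavage_rate(st, cfg$rates), 0)
  st[["casp8_dimer_active"]] <- 1
  r1 <- fret_cleavage_rate(st, cfg$rates)
  expect_equal(r1, cfg$rates$k_fret_cleave_nm_min * 1 *
                 cfg$initial_nm$fret_substrate)
  st[["casp8_dimer_active"]] <- 2
  expect_equal(fret_cleavage_rate(st, cfg$rates), 2 * r1)
  st[["fret_intact"]] <- 0
  expect_equal(fret_cleavage_rate(st, cfg$rates), 0)
  expect_error(cascade_rhs(st - 10, cfg$rates), "nonnegative")
})
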