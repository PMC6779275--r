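# compiled engine: reproducibility, conservation, and brute-force CME
# validation on the tiny network

test_that("identical seeds give bit-identical trajectories", {
  cfg <- default_cfg()
  a <- simulate_assembly(cfg, 5, TRUE, seed = 123, t_max = 30)
  b <- simulate_assembly(cfg, 5, TRUE, seed = 123, t_max = 30)
  expect_identical(a$series, b$series)
  expect_identical(a$platforms, b$platforms)
  c <- simulate_assembly(cfg, 5, TRUE, seed = 124, t_max = 30)
  expect_false(identical(a$series, c$series))
  h1 <- simulate_cell_hybrid(cfg, 50, TRUE, seed = 9, t_max = 90)
  h2 <- simulate_cell_hybrid(cfg, 50, TRUE, seed = 9, t_max = 90)
  expect_identical(h1$series, h2$series)
  expect_identical(h1$death$death_time_min, h2$death$death_time_min)
})

test_that("species-conservation ledgers hold throughout long simulations", {
  cfg <- default_cfg()
  expect_no_error(simulate_assembly(cfg, 5, TRUE, seed = 3, t_max = 120,
                                    validate = TRUE))
  expect_no_error(simulate_cell_hybrid(cfg, 50, TRUE, seed = 3, t_max = 90,
                                       validate = TRUE))
  expect_no_error(simulate_cell_full_ssa(cfg, 50, TRUE, seed = 3, t_max = 60,
                                         validate = TRUE))
})

test_that("cumulative outputs are monotone and pools stay nonnegative", {
  cfg <- default_cfg()
  tr <- simulate_assembly(cfg, 5, TRUE, seed = 8, t_max = 240)
  s <- tr$series
  expect_true(all(diff(s$cum_casp8_dimers) >= 0))
  expect_true(all(diff(s$cum_ded12_released) >= 0))
  expect_true(all(diff(s$cum_heterodimers) >= 0))
  expect_true(all(s[, grepl("^free_", names(s))] >= 0))
  # RIP1 dominates the platform composition (20 min, 5 ng/mL)
  expect_gt(s$mean_rip1_per_origin[21],
            max(s$mean_rip3_per_origin[21], s$mean_fadd_per_origin[21],
                s$mean_procasp8_per_origin[21], s$mean_ded12_per_origin[21]))
})

test_that("tiny-network state distribution matches the exact CME solution", {
  cfg <- tiny_cfg()
  t_obs <- 2
  cme <- tiny_network_cme(cfg, t_obs)
  expect_lte(nrow(cme$states), 32)
  n_mc <- 4000
  rel <- integer(n_mc)
  for (i in seq_len(n_mc)) {
    tr <- simulate_assembly(cfg, 50, TRUE, seed = 10000 + i, t_max = t_obs,
                            record_dt = t_obs)
    rel[i] <- tr$series$cum_casp8_dimers[2]
  }
  obs <- table(factor(rel, levels = names(cme$released_dist)))
  for (k in names(cme$released_dist)) {
    p <- cme$released_dist[[k]]
    se <- sqrt(p * (1 - p) / n_mc)
    expect_lt(abs(obs[[k]] / n_mc - p), max(3 * se, 0.02),
              label = sprintf("P(released = %s): MC %.4f vs CME %.4f",
                              k, obs[[k]] / n_mc, p))
  }
})

test_that("pure-R reference and compiled engine agree on the tiny network", {
  cfg <- tiny_cfg()
  # R reference Monte Carlo against the same CME categories
  cme <- tiny_network_cme(cfg, 2)
  rates <- stochastic_rates(cfg)
  n_mc <- 600
  rel <- integer(n_mc)
  set.seed(77)
  for (i in seq_len(n_mc)) {
    cl <- assign_clusters(1L, cfg$clustering$size_trimers,
                          cfg$clustering$probability, TRUE)
    st <- new_stochastic_state(cfg, cl)
    sim <- simulate_assembly_r(st, rates, 2, record_grid = c(0, 2))
    rel[i] <- sim$series$cum_casp8_dimers[2]
  }
  obs <- table(factor(rel, levels = names(cme$released_dist)))
  for (k in names(cme$released_dist)) {
    p <- cme$released_dist[[k]]
    se <- sqrt(p * (1 - p) / n_mc)
    expect_lt(abs(obs[[k]] / n_mc - p), max(3.5 * se, 0.03))
  }
  # and the channel enumerations agree at the initial state
  cl <- assign_clusters(1L, 1L, 1, TRUE)
  st <- new_stochastic_state(cfg, cl)
  ch <- build_propensities(st, rates)
  tr <- simulate_assembly(cfg, 50, TRUE, seed = 1, t_max = 0.001,
                          record_dt = 0.001)
  expect_equal(nrow(tr$platforms), 1L)
})

test_that("per-origin recording reproduces aggregate series", {
  cfg <- default_cfg()
  tr <- simulate_assembly(cfg, 5, TRUE, seed = 21, t_max = 20,
                          record_origins = TRUE)
  o <- tr$origins
  last <- nrow(o$n_rip1)
  expect_equal(rowMeans(o$n_fadd), tr$series$mean_fadd_per_origin,
               tolerance = 1e-12)
  m <- default_cfg()$masses_kda
  masses <- o$n_rip1[last, ] * m$rip1 + o$n_rip3[last, ] * m$rip3 +
    o$n_fadd[last, ] * m$fadd + o$n_procasp8[last, ] * m$procasp8 +
    o$n_cflip_l[last, ] * m$cflip_l + o$n_cflip_s[last, ] * m$cflip_s +
    o$n_ded12[last, ] * m$ded12 +
    c(0, m$procasp8, m$ded12)[o$cap[last, ] + 1]
  expect_equal(max(masses), tr$series$max_mass_kda[last])
})
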