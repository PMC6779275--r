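# platform_assembly_ssa: channel enumeration, direct-method kernel and the
# pure-R reference path

make_bare_state <- function(n_platforms = 1, cluster_id = seq_len(n_platforms),
                            pools = c(rip1 = 0, rip3 = 0, fadd = 0,
                                      procasp8 = 0, cflip_l = 0, cflip_s = 0,
                                      ded12 = 0)) {
  platforms <- data.frame(
    n_rip1 = rep(1L, n_platforms), n_rip3 = 0L, n_fadd = 0L,
    n_procasp8 = 0L, n_cflip_l = 0L, n_cflip_s = 0L, n_ded12 = 0L,
    cap = 0L, cluster_id = as.integer(cluster_id))
  structure(list(pools = pools, platforms = platforms, n_dim_pend = 0L,
                 n_het_l = 0L, n_het_s = 0L, n_het_d = 0L,
                 cum_casp8_dimers = 0L, cum_ded12_released = 0L,
                 cum_heterodimers = 0L, clock = 0),
            class = "stochastic_cell_state")
}

test_that("bare origins with empty pools have no recruitment propensity", {
  rates <- stochastic_rates(default_cfg())
  st <- make_bare_state(3)
  ch <- build_propensities(st, rates)
  recruit <- ch$kind %in% c("rip1_elong", "rip3_on", "fadd_on", "c8_on",
                            "flipl_on", "flips_on", "ded_on", "cap_on_c8",
                            "cap_on_ded")
  expect_equal(sum(ch$propensity[recruit]), 0)
})

test_that("cis and trans channels follow pair combinatorics", {
  rates <- stochastic_rates(default_cfg())
  st <- make_bare_state(1)
  st$platforms$n_fadd <- 2L
  st$platforms$n_procasp8 <- 2L
  ch <- build_propensities(st, rates)
  cis <- ch[ch$kind == "cis_dimer", ]
  expect_equal(nrow(cis), 1L)          # exactly one pair
  expect_equal(cis$propensity, rates$k_cis)
  # two origins sharing one cluster, one bound ProCasp8 each
  st2 <- make_bare_state(2, cluster_id = c(1L, 1L))
  st2$platforms$n_fadd <- 1L
  st2$platforms$n_procasp8 <- 1L
  ch2 <- build_propensities(st2, rates)
  trans <- ch2[ch2$kind == "trans_dimer", ]
  expect_equal(nrow(trans), 1L)
  expect_equal(trans$propensity, rates$k_trans)
  expect_equal(nrow(ch2[ch2$kind == "cis_dimer", ]), 0L)
  # disrupting clustering removes every trans channel
  cfg_d <- default_model_config()
  cfg_d$clustering$enabled <- FALSE
  rates_d <- stochastic_rates(cfg_d)
  ch3 <- build_propensities(st2, rates_d)
  expect_equal(nrow(ch3[ch3$kind == "trans_dimer", ]), 0L)
})

test_that("direct-method waiting times are exponential", {
  # single active channel with rate k: mean dt = 1/k within 3 standard errors
  k <- 1.0   # the dimer-activation rate of the default configuration
  st <- make_bare_state(1)
  st$n_dim_pend <- 1L
  rates <- stochastic_rates(default_cfg())
  rates$k_dimoff <- 0
  ch <- build_propensities(st, rates)
  expect_equal(nrow(ch), 1L)
  set.seed(42)
  n <- 1e4
  dts <- replicate(n, gillespie_step(st, ch)$dt)
  se <- (1 / k) / sqrt(n)
  expect_lt(abs(mean(dts) - 1 / k), 3 * se)
})

test_that("channel selection frequencies are multinomial", {
  # two channels with rates k and 3k select with probability 1/4 and 3/4
  st <- make_bare_state(1)
  st$n_dim_pend <- 1L
  rates <- stochastic_rates(default_cfg())
  rates$k_act <- 1
  rates$k_dimoff <- 3
  ch <- build_propensities(st, rates)
  expect_equal(nrow(ch), 2L)
  set.seed(43)
  n <- 1e4
  picks <- replicate(n, gillespie_step(st, ch)$index)
  p_act <- mean(picks == which(ch$kind == "dimer_act"))
  expect_lt(abs(p_act - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("an exhausted state returns dt = Inf and is left unchanged", {
  st <- make_bare_state(1)
  rates <- stochastic_rates(default_cfg())
  ch <- build_propensities(st, rates)
  out <- gillespie_step(st, ch)
  expect_identical(out$dt, Inf)
  expect_identical(out$state, st)
})

test_that("platform mass sums subunit masses including the cap", {
  m <- default_cfg()$masses_kda
  one <- list(n_rip1 = 1, n_rip3 = 0, n_fadd = 0, n_procasp8 = 0,
              n_cflip_l = 0, n_cflip_s = 0, n_ded12 = 0, cap = 0)
  expect_equal(platform_mass(one, m), 76)
  ten <- modifyList(one, list(n_rip1 = 10, n_fadd = 1))
  expect_equal(platform_mass(ten, m), 10 * 76 + 23)
  big <- modifyList(one, list(n_rip1 = 27))
  expect_gte(platform_mass(big, m), 2000)   # a 27-RIP1 filament tops 2 MDa
  capped <- modifyList(one, list(cap = 1))
  expect_equal(platform_mass(capped, m), 76 + 55)
})

test_that("the R reference simulator conserves every species", {
  cfg <- generate_fixtures("tiny_network")$config
  cfg$initial_nm$rip1 <- 4
  cfg$initial_nm$fadd <- 3
  cfg$initial_nm$procasp8 <- 4
  cfg <- validate_model_config(cfg)
  rates <- stochastic_rates(cfg)
  set.seed(5)
  cl <- assign_clusters(1L, cfg$clustering$size_trimers,
                        cfg$clustering$probability, TRUE)
  st <- new_stochastic_state(cfg, cl)
  totals <- initial_totals(st, rates)
  for (i in 1:200) {
    ch <- build_propensities(st, rates)
    out <- gillespie_step(st, ch)
    if (!is.finite(out$dt)) break
    st <- out$state
    expect_silent(check_conservation(st, totals))
  }
  expect_gt(st$cum_casp8_dimers, 0)  # the tiny cascade does fire
})

test_that("no Casp8 activates without ProCasp8 or filament growth", {
  cfg <- generate_fixtures("tiny_network")$config
  cfg$initial_nm$procasp8 <- 0
  cfg <- validate_model_config(cfg)
  tr <- simulate_assembly(cfg, 50, TRUE, seed = 1, t_max = 30)
  expect_true(all(tr$series$cum_casp8_dimers == 0))
})
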