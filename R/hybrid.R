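# Single-cell simulators: hybrid (SSA assembly + deterministic cascade),
# full SSA (everything discrete) and the mean-field deterministic model.

series_column_names <- function() {
  c("cum_casp8_dimers", "cum_ded12_released", "cum_heterodimers",
    "n_dim_pend", "free_rip1", "free_rip3", "free_fadd", "free_procasp8",
    "free_cflip_l", "free_cflip_s", "free_ded12", "bound_fadd",
    "bound_procasp8", "mean_fadd_per_origin", "mean_procasp8_per_origin",
    "max_mass_kda", "n_platforms_ge_2mda", "mean_rip1_per_origin",
    "mean_rip3_per_origin", "mean_cflipl_per_origin",
    "mean_cflips_per_origin", "mean_ded12_per_origin",
    cascade_state_names, "fret_rate_nm_min")
}

# derive a reproducible per-cell seed from a master seed and cell index
derive_cell_seed <- function(master_seed, cell_index = 1L) {
  s <- (as.double(master_seed) %% 2147483647) + 1
  (s * 48271 + as.double(cell_index) * 16807) %% 2147483647
}

engine_pools <- function(cfg, n_origins) {
  geom <- cell_geometry(cfg$geometry$volume_l)
  pools <- vapply(cfg$initial_nm[c("rip1", "rip3", "fadd", "procasp8",
                                   "cflip_l", "cflip_s")],
                  concentration_to_copies, numeric(1), geom = geom)
  names(pools) <- c("rip1", "rip3", "fadd", "procasp8", "cflip_l", "cflip_s")
  pools <- c(pools, ded12 = 0)
  if (pools[["rip1"]] < n_origins) {
    config_error("bad_value", "RIP1 pool smaller than the number of origins")
  }
  pools[["rip1"]] <- pools[["rip1"]] - n_origins
  pools
}

run_engine <- function(cfg, cluster_id, mode, seed, t_max, dt_sync,
                       record_dt, threshold = NULL, record_origins = FALSE,
                       validate = FALSE) {
  if (is.null(threshold)) {
    threshold <- cfg$simulation$death_threshold_rate_nm_min
  }
  # keep the record grid commensurate with the sync cadence
  if (mode != 0) record_dt <- max(round(record_dt / dt_sync), 1) * dt_sync
  spec <- list(
    rates = stochastic_rates(cfg),
    ode_params = cfg$rates,
    xiap_regenerated = isTRUE(cfg$simulation$xiap_regenerated),
    pools = engine_pools(cfg, length(cluster_id)),
    cluster_id = as.integer(cluster_id),
    masses = as.numeric(unlist(cfg$masses_kda[c("rip1", "rip3", "fadd",
                                                "procasp8", "cflip_l",
                                                "cflip_s", "ded12")])),
    y0 = cascade_initial_state(cfg),
    mode = as.integer(mode), t_max = t_max, dt_sync = dt_sync,
    record_dt = record_dt, threshold = threshold,
    record_origins = isTRUE(record_origins), validate = isTRUE(validate),
    seed = as.double(seed))
  res <- .engine_simulate_cell(spec)
  series <- as.data.frame(res$series)
  names(series) <- series_column_names()
  res$series <- series
  res
}

new_cell_trajectory <- function(res, cfg, dose_ng_ml, clustering, seed,
                                module) {
  traj <- structure(list(
    time_min = as.numeric(res$time),
    series = res$series,
    death = structure(list(died = isTRUE(res$died),
                           death_time_min = res$death_time,
                           threshold_rate = cfg$simulation$death_threshold_rate_nm_min),
                      class = "death_event"),
    platforms = res$platforms,
    origins = res$origins,
    scenario = list(dose_ng_ml = dose_ng_ml, clustering = clustering,
                    module = module),
    seed = seed,
    n_events = res$n_events,
    clamp_events = res$clamp_events,
    volume_l = cfg$geometry$volume_l
  ), class = "cell_trajectory")
  traj
}

#' @export
print.cell_trajectory <- function(x, ...) {
  d <- x$death
  cat(sprintf(
    "<cell_trajectory> %s, dose %g ng/mL, clustering %s\n  t = 0..%g min, %s (%.0f SSA events)\n",
    x$scenario$module, x$scenario$dose_ng_ml,
    if (x$scenario$clustering) "on" else "off", max(x$time_min),
    if (d$died) sprintf("death at %.1f min", d$death_time_min) else "no death",
    x$n_events))
  invisible(x)
}

#' @export
plot.cell_trajectory <- function(x, y, ...) {
  graphics::plot(x$time_min, x$series$fret_rate_nm_min, type = "l",
                 xlab = "time (min)", ylab = "FRET cleavage rate (nM/min)",
                 main = sprintf("dose %g ng/mL (%s)", x$scenario$dose_ng_ml,
                                x$scenario$module), ...)
  graphics::abline(h = x$death$threshold_rate, lty = 2, col = "red")
  invisible(x)
}

#' Simulate one cell with the semi-stochastic hybrid model
#'
#' Fixed-step operator splitting: over each synchronisation window the
#' platform-assembly SSA advances with the cascade frozen; active Casp8
#' dimers released in the window become a piecewise-constant source for the
#' deterministic cascade, which is then advanced over the same window
#' (embedded RK45). The shared free ProCasp8 pool is reconciled each window:
#' ProCasp8 cleaved by Casp6* is debited from the stochastic pool (clamped at
#' zero with a logged warning if a debit overshoots). The simulation stops at
#' death -- the first window boundary where the FRET cleavage rate meets the
#' configured threshold, with linear interpolation inside the window -- or at
#' `t_max`.
#'
#' @param cfg a `riposim_config`.
#' @param dose_ng_ml death-ligand dose in ng/mL.
#' @param clustering logical; FALSE simulates disrupted receptor clustering
#'   (all clusters singleton, trans-activation impossible).
#' @param seed integer seed (drives cluster assignment and the SSA stream).
#' @param t_max simulation horizon in minutes.
#' @param dt_sync operator-splitting window in minutes.
#' @param record_dt output grid spacing in minutes.
#' @param validate run species-conservation ledgers during the simulation
#'   (slower; used by tests).
#' @return a `cell_trajectory` with the recorded series, a `death_event`, the
#'   final platform table and provenance (seed, scenario, event counts).
#' @export
#' @examples
#' \donttest{
#' cfg <- default_model_config()
#' tr <- simulate_cell_hybrid(cfg, dose_ng_ml = 50, seed = 1, t_max = 120)
#' tr$death$died
#' }
simulate_cell_hybrid <- function(cfg, dose_ng_ml, clustering = TRUE, seed = 1,
                                 t_max = cfg$simulation$t_max_min,
                                 dt_sync = cfg$simulation$dt_sync_min,
                                 record_dt = cfg$simulation$record_dt_min,
                                 validate = FALSE) {
  if (t_max <= 0 || dt_sync <= 0) {
    config_error("bad_value", "t_max and dt_sync must be > 0")
  }
  panel <- receptor_panel(cfg, dose_ng_ml)
  set.seed(derive_cell_seed(seed))
  clusters <- assign_clusters(panel$n_trimers, cfg$clustering$size_trimers,
                              cfg$clustering$probability, clustering)
  res <- run_engine(cfg, clusters$cluster_id, mode = 1L, seed = seed,
                    t_max = t_max, dt_sync = dt_sync, record_dt = record_dt,
                    validate = validate)
  new_cell_trajectory(res, cfg, dose_ng_ml, clustering, seed, "hybrid")
}

#' Simulate one cell with every reaction stochastic (full SSA)
#'
#' Reference implementation in which the caspase cascade is simulated in
#' molecule counts alongside platform assembly, with no deterministic
#' approximation. Observables match [simulate_cell_hybrid()]; used to
#' validate the hybrid partition at reduced scale.
#'
#' @inheritParams simulate_cell_hybrid
#' @return a `cell_trajectory`.
#' @export
simulate_cell_full_ssa <- function(cfg, dose_ng_ml, clustering = TRUE,
                                   seed = 1,
                                   t_max = cfg$simulation$t_max_min,
                                   record_dt = cfg$simulation$record_dt_min,
                                   validate = FALSE) {
  if (t_max <= 0) config_error("bad_value", "t_max must be > 0")
  panel <- receptor_panel(cfg, dose_ng_ml)
  set.seed(derive_cell_seed(seed))
  clusters <- assign_clusters(panel$n_trimers, cfg$clustering$size_trimers,
                              cfg$clustering$probability, clustering)
  res <- run_engine(cfg, clusters$cluster_id, mode = 2L, seed = seed,
                    t_max = t_max, dt_sync = cfg$simulation$dt_sync_min,
                    record_dt = record_dt, validate = validate)
  new_cell_trajectory(res, cfg, dose_ng_ml, clustering, seed, "full_ssa")
}

#' Stochastic platform assembly without the downstream cascade
#'
#' Runs the Gillespie assembly module alone and records platform composition
#' and cumulative outputs (active Casp8 dimers, released DED1-DED2,
#' RIP1-RIP3 heterodimers) on a grid.
#'
#' @inheritParams simulate_cell_hybrid
#' @param record_origins record the full per-origin composition at every grid
#'   time (memory grows with origins x grid; meant for short runs).
#' @param engine `"cpp"` (production) or `"r"` (pure-R reference, small
#'   networks only).
#' @return a `cell_trajectory` (no death event is ever recorded).
#' @export
simulate_assembly <- function(cfg, dose_ng_ml, clustering = TRUE, seed = 1,
                              t_max = 120,
                              record_dt = cfg$simulation$record_dt_min,
                              record_origins = FALSE, validate = FALSE,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (t_max <= 0) config_error("bad_value", "t_max must be > 0")
  panel <- receptor_panel(cfg, dose_ng_ml)
  set.seed(derive_cell_seed(seed))
  clusters <- assign_clusters(panel$n_trimers, cfg$clustering$size_trimers,
                              cfg$clustering$probability, clustering)
  if (engine == "r") {
    cfg2 <- cfg
    cfg2$clustering$enabled <- clustering
    state <- new_stochastic_state(cfg2, clusters)
    rates <- stochastic_rates(cfg2)
    sim <- simulate_assembly_r(state, rates, t_max,
                               seq(0, t_max, by = record_dt))
    return(structure(list(time_min = sim$series$time_min, series = sim$series,
                          state = sim$state,
                          scenario = list(dose_ng_ml = dose_ng_ml,
                                          clustering = clustering,
                                          module = "assembly_r"),
                          seed = seed), class = "cell_trajectory"))
  }
  res <- run_engine(cfg, clusters$cluster_id, mode = 0L, seed = seed,
                    t_max = t_max, dt_sync = cfg$simulation$dt_sync_min,
                    record_dt = record_dt, threshold = 0,
                    record_origins = record_origins, validate = validate)
  new_cell_trajectory(res, cfg, dose_ng_ml, clustering, seed, "assembly")
}

#' Detect the death event on a trajectory
#'
#' The death time is the first crossing of the FRET cleavage-rate series over
#' the threshold, linearly interpolated between grid points; a trace touching
#' the threshold exactly at a grid point dies at that point (`>=`).
#'
#' @param traj a `cell_trajectory`, or a data.frame with columns `time_min`
#'   and `fret_rate_nm_min`.
#' @param threshold_rate threshold in nM/min (> 0).
#' @return a `death_event` (fields `died`, `death_time_min`,
#'   `threshold_rate`).
#' @export
detect_death <- function(traj, threshold_rate) {
  if (threshold_rate <= 0) {
    config_error("bad_value", "threshold_rate must be > 0")
  }
  if (inherits(traj, "cell_trajectory")) {
    tt <- traj$time_min
    rr <- traj$series$fret_rate_nm_min
  } else {
    tt <- traj$time_min
    rr <- traj$fret_rate_nm_min
  }
  if (is.null(tt) || is.null(rr) || !length(tt)) {
    config_error("bad_value", "empty trajectory")
  }
  hit <- which(rr >= threshold_rate)
  if (!length(hit)) {
    return(structure(list(died = FALSE, death_time_min = NA_real_,
                          threshold_rate = threshold_rate),
                     class = "death_event"))
  }
  k <- hit[1]
  if (k == 1L || rr[k] == threshold_rate) {
    td <- tt[k]
  } else {
    frac <- (threshold_rate - rr[k - 1]) / (rr[k] - rr[k - 1])
    td <- tt[k - 1] + frac * (tt[k] - tt[k - 1])
  }
  structure(list(died = TRUE, death_time_min = td,
                 threshold_rate = threshold_rate), class = "death_event")
}

#' @export
print.death_event <- function(x, ...) {
  if (x$died) {
    cat(sprintf("<death_event> death at %.2f min (threshold %.3g nM/min)\n",
                x$death_time_min, x$threshold_rate))
  } else {
    cat("<death_event> no death\n")
  }
  invisible(x)
}

#' Fully deterministic (mean-field) model
#'
#' Mean-field rate equations for the platform-assembly network -- free pools
#' plus the composition of the average platform, with trans-activation
#' entering through the size-biased mean cluster size -- chained into the
#' caspase cascade ODEs. Used for parameter scans and as the large-copy-number
#' reference for the stochastic ensemble mean.
#'
#' @inheritParams simulate_cell_hybrid
#' @param t_max horizon in minutes.
#' @param record_dt output grid in minutes.
#' @return list with `series` (data.frame, assembly means + cascade states +
#'   `fret_rate_nm_min`), `death` (a `death_event`) and `scenario`.
#' @export
deterministic_full_model <- function(cfg, dose_ng_ml, clustering = TRUE,
                                     t_max = cfg$simulation$t_max_min,
                                     record_dt = 1) {
  if (dose_ng_ml < 0) config_error("bad_value", "dose must be >= 0")
  panel <- receptor_panel(cfg, dose_ng_ml)
  N <- panel$n_trimers
  r <- stochastic_rates(cfg)
  conv <- r$conv
  pr <- cfg$rates
  # size-biased mean cluster size: expected size of the cluster containing a
  # randomly chosen platform
  if (clustering) {
    sz <- cfg$clustering$size_trimers
    pb <- cfg$clustering$probability
    mbar2 <- sum(sz^2 * pb) / sum(sz * pb)
    k_trans <- r$k_trans
  } else {
    mbar2 <- 1
    k_trans <- 0
  }
  pools0 <- engine_pools(cfg, N)
  y0 <- c(R1f = unname(pools0[["rip1"]]), R3f = unname(pools0[["rip3"]]),
          Ff = unname(pools0[["fadd"]]), C8f = unname(pools0[["procasp8"]]),
          FLlf = unname(pools0[["cflip_l"]]),
          FLsf = unname(pools0[["cflip_s"]]), DEDf = 0,
          r1 = if (N > 0) 1 else 0, r3 = 0, f = 0, c8 = 0, fll = 0, fls = 0,
          ded = 0, capc8 = 0, capded = 0, D = 0, cumC8 = 0, cumHet = 0,
          cascade_initial_state(cfg))
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    if (N == 0) return(list(numeric(length(y))))
    e <- as.list(y)
    o <- max(1 - e$capc8 - e$capded, 0)
    fr <- max(e$f - (e$c8 + e$fll + e$fls + e$ded), 0)
    v_el <- r$c_el * e$R1f * o
    v_r1off <- r$k_r1off * o * as.numeric(e$r1 > 1)
    v_r3 <- r$c_r3 * e$R3f * max(e$r1 - e$r3, 0)
    v_r3off <- r$k_r3off * e$r3
    v_f <- r$c_f * e$Ff * max(e$r1 - e$f, 0)
    v_foff <- r$k_foff * fr
    v_c8 <- r$c_c8 * e$C8f * fr
    v_c8off <- r$k_c8off * e$c8
    v_fll <- r$c_fll * e$FLlf * fr
    v_flloff <- r$k_flloff * e$fll
    v_fls <- r$c_fls * e$FLsf * fr
    v_flsoff <- r$k_flsoff * e$fls
    v_ded <- r$c_ded * e$DEDf * fr
    v_dedoff <- r$k_dedoff * e$ded
    v_capc8 <- r$c_cap * e$C8f * o
    v_capded <- r$c_cap * e$DEDf * o
    v_capoffc8 <- r$k_capoff * e$capc8
    v_capoffd <- r$k_capoff * e$capded
    v_cis <- r$k_cis * e$c8^2 / 2
    v_trans <- k_trans * e$c8^2 * (mbar2 - 1) / 2
    v_het <- r$k_het * e$c8 * (e$fll + e$fls + e$ded)
    v_act <- r$k_act * e$D
    v_dimoff <- r$k_dimoff * e$D
    # cascade (nM); ProCasp8 pool is shared with the assembly free pool
    cs <- setNames(y[cascade_state_names], cascade_state_names)
    cs[["procasp8_free"]] <- e$C8f / conv
    src <- r$k_act * e$D / conv   # dimer release, counts/min -> nM/min
    dcs <- cascade_rhs(cs, pr, src, isTRUE(cfg$simulation$xiap_regenerated))
    v_c6cl <- pr$k_casp6_casp8_nm_min * cs[["casp6_active"]] *
      cs[["procasp8_free"]]      # nM/min cleaved from the shared pool
    dcs[["procasp8_free"]] <- 0  # bookkept through C8f
    d <- c(
      R1f = -N * v_el + N * v_r1off,
      R3f = -N * v_r3 + N * v_r3off,
      Ff = -N * v_f + N * v_foff,
      C8f = N * (-v_c8 + v_c8off - v_capc8 + v_capoffc8) + 2 * v_dimoff -
        v_c6cl * conv,
      FLlf = N * (-v_fll + v_flloff),
      FLsf = N * (-v_fls + v_flsoff),
      DEDf = N * (-v_ded + v_dedoff - v_capded + v_capoffd) + v_act,
      r1 = v_el - v_r1off,
      r3 = v_r3 - v_r3off,
      f = v_f - v_foff,
      c8 = v_c8 - v_c8off - 2 * v_cis - 2 * v_trans - v_het,
      fll = v_fll - v_flloff - r$k_het * e$c8 * e$fll,
      fls = v_fls - v_flsoff - r$k_het * e$c8 * e$fls,
      ded = v_ded - v_dedoff - r$k_het * e$c8 * e$ded,
      capc8 = v_capc8 - v_capoffc8,
      capded = v_capded - v_capoffd,
      D = N * (v_cis + v_trans) - v_act - v_dimoff,
      cumC8 = v_act,
      cumHet = N * v_r3)
    list(c(d, unlist(dcs)))
  }
  times <- seq(0, t_max, by = record_dt)
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = 1e-8,
                        atol = 1e-10, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("deterministic model integrator failed at t = %.2f min",
                 max(out[, "time"])), call. = FALSE)
  }
  df <- as.data.frame(out)
  names(df)[1] <- "time_min"
  df$procasp8_free <- df$C8f / conv
  df$fret_rate_nm_min <- pr$k_fret_cleave_nm_min * df$casp8_dimer_active *
    df$fret_intact
  death <- detect_death(df, cfg$simulation$death_threshold_rate_nm_min)
  list(series = df, death = death,
       scenario = list(dose_ng_ml = dose_ng_ml, clustering = clustering,
                       module = "deterministic", n_origins = N))
}
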