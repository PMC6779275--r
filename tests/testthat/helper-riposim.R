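# Shared fixtures for the test suite. Ensembles used by several acceptance
# blocks are computed once per session and cached.

.riposim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .riposim_cache)) {
    assign(key, force(expr), envir = .riposim_cache)
  }
  get(key, envir = .riposim_cache)
}

default_cfg <- function() cached("cfg", default_model_config())

tiny_cfg <- function() cached("tiny", generate_fixtures("tiny_network")$config)

# the four study scenarios at full horizon (100 cells each, master seed 1)
scenario_ensemble <- function(dose, clustering) {
  key <- sprintf("ens_%g_%d", dose, clustering)
  cached(key, run_ensemble(default_cfg(), dose, clustering, n_cells = 100,
                           master_seed = 1, t_max = 1440,
                           keep_columns = "fret_rate_nm_min"))
}

# assembly-only ensembles over the first two hours (platform composition)
assembly_ensemble <- function(dose) {
  key <- sprintf("asm_%g", dose)
  cached(key, run_ensemble(default_cfg(), dose, TRUE, n_cells = 100,
                           master_seed = 1, t_max = 120, module = "assembly",
                           keep_columns = c("mean_fadd_per_origin",
                                            "max_mass_kda",
                                            "cum_casp8_dimers")))
}

# synthetic cell_trajectory carrying a given rate series (population tests)
fake_trajectory <- function(rate, dt = 1) {
  structure(list(time_min = seq(0, by = dt, length.out = length(rate)),
                 series = data.frame(fret_rate_nm_min = rate),
                 death = structure(list(died = FALSE,
                                        death_time_min = NA_real_,
                                        threshold_rate = 1),
                                   class = "death_event")),
            class = "cell_trajectory")
}
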