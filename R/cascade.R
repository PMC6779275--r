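# Deterministic effector-caspase feedback module. State lives in nM; time in
# minutes. Casp8 activated on the platforms enters as a source term (nM/min).

cascade_state_names <- c("casp8_dimer_active", "casp8_mono_cleaved",
                         "procasp3", "casp3_active", "procasp6",
                         "casp6_active", "xiap_free", "xiap_casp3_complex",
                         "casp3_degraded_cum", "fret_intact", "fret_cleaved",
                         "procasp8_free")

#' Initial deterministic cascade state
#'
#' All active species start at zero; pro-forms, XIAP and the FRET substrate
#' start at their configured concentrations. `procasp8_free` mirrors the
#' cytosolic ProCasp8 pool shared with the stochastic module.
#'
#' @param cfg a `riposim_config`.
#' @param procasp8_nm optional override of the free ProCasp8 concentration
#'   (used by the hybrid coupling); defaults to the configured value.
#' @return named numeric vector (nM).
#' @export
cascade_initial_state <- function(cfg, procasp8_nm = cfg$initial_nm$procasp8) {
  setNames(c(0, 0, cfg$initial_nm$procasp3, 0, cfg$initial_nm$procasp6, 0,
             cfg$initial_nm$xiap, 0, 0, cfg$initial_nm$fret_substrate, 0,
             procasp8_nm),
           cascade_state_names)
}

#' Time derivatives of the caspase cascade
#'
#' Mass-action rates: (i) external Casp8-dimer source; (ii) Casp8*-dimer
#' cleavage of ProCasp3; (iii) Casp3* autocatalysis on ProCasp3; (iv) Casp3*
#' cleavage of ProCasp6; (v) Casp6* cleavage of free ProCasp8 to the cleaved
#' monomer; (vi) slow second-order monomer dimerization to the active dimer,
#' with first-order dimer dissociation back to monomers; (vii) reversible
#' XIAP-Casp3 binding; (viii) kcat_ub-driven degradation of the complex
#' (XIAP regenerated by default); (ix) Casp8*-dimer cleavage of the intact
#' FRET substrate; basal ubiquitin-dependent degradation acts on free active
#' Casp3. Only the active dimer is catalytic; the cleaved monomer is inert
#' until it dimerizes.
#'
#' @param state named numeric vector as [cascade_initial_state()] (all >= 0).
#' @param params the `rates` section of a `riposim_config`.
#' @param casp8_source Casp8-dimer source in nM/min.
#' @param xiap_regenerated logical: return XIAP to the free pool on Casp3
#'   degradation (catalytic-inhibitor cycle).
#' @return named numeric vector of derivatives (nM/min).
#' @export
cascade_rhs <- function(state, params, casp8_source = 0,
                        xiap_regenerated = TRUE) {
  if (any(state < -1e-9)) {
    stop("cascade state must be nonnegative", call. = FALSE)
  }
  s <- as.list(pmax(state, 0))
  names(s) <- cascade_state_names
  v_dim <- params$k_casp8_mono_dimer_nm_min * s$casp8_mono_cleaved^2
  v_undim <- params$koff_casp8_dimer_min * s$casp8_dimer_active
  v_c3 <- (params$k_casp8_casp3_nm_min * s$casp8_dimer_active +
             params$k_casp3_auto_nm_min * s$casp3_active) * s$procasp3
  v_c6 <- params$k_casp3_casp6_nm_min * s$casp3_active * s$procasp6
  v_c8cl <- params$k_casp6_casp8_nm_min * s$casp6_active * s$procasp8_free
  v_xon <- params$kon_xiap_casp3_nm_min * s$xiap_free * s$casp3_active
  v_xoff <- params$koff_xiap_casp3_min * s$xiap_casp3_complex
  v_ub <- params$kcat_ub_min * s$xiap_casp3_complex
  v_fret <- params$k_fret_cleave_nm_min * s$casp8_dimer_active * s$fret_intact
  v_bas <- params$k_basal_deg_min * s$casp3_active
  c(casp8_dimer_active = casp8_source + v_dim - v_undim,
    casp8_mono_cleaved = 2 * v_undim - 2 * v_dim + v_c8cl,
    procasp3 = -v_c3,
    casp3_active = v_c3 - v_xon + v_xoff - v_bas,
    procasp6 = -v_c6,
    casp6_active = v_c6,
    xiap_free = -v_xon + v_xoff + if (xiap_regenerated) v_ub else 0,
    xiap_casp3_complex = v_xon - v_xoff - v_ub,
    casp3_degraded_cum = v_ub + v_bas,
    fret_intact = -v_fret,
    fret_cleaved = v_fret,
    procasp8_free = -v_c8cl)
}

#' Integrate the caspase cascade
#'
#' Stiff-capable integration (deSolve, `lsoda`) of [cascade_rhs()] under a
#' time-dependent Casp8 source, with dense output on the requested grid.
#'
#' @param state0 initial state, as [cascade_initial_state()].
#' @param params the `rates` section of a `riposim_config`.
#' @param source_fn function of time (min) returning the Casp8-dimer source in
#'   nM/min.
#' @param t_span numeric vector of output times (min), first element is t0.
#' @param tol relative tolerance (> 0); absolute tolerance is `tol * 1e-3`.
#' @param xiap_regenerated see [cascade_rhs()].
#' @return data.frame: `time_min` plus one column per state variable.
#' @export
integrate_cascade <- function(state0, params, source_fn = function(t) 0,
                              t_span = seq(0, 60, by = 1), tol = 1e-8,
                              xiap_regenerated = TRUE) {
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  rhs <- function(t, y, p) {
    list(cascade_rhs(pmax(y, 0), params, source_fn(t), xiap_regenerated))
  }
  out <- deSolve::lsoda(y = state0, times = t_span, func = rhs, parms = NULL,
                        rtol = tol, atol = tol * 1e-3)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("cascade integrator failed at t = %.4f min",
                 max(out[, "time"])), call. = FALSE)
  }
  df <- as.data.frame(out)
  names(df)[1] <- "time_min"
  df
}

#' Instantaneous FRET-probe cleavage rate
#'
#' `k_fret * [Casp8* dimer] * [intact FRET substrate]`; this is the quantity
#' compared against the death threshold.
#'
#' @param state named state vector or data.frame with columns
#'   `casp8_dimer_active` and `fret_intact`.
#' @param params the `rates` section of a `riposim_config`.
#' @return cleavage rate(s) in nM/min.
#' @export
fret_cleavage_rate <- function(state, params) {
  if (is.data.frame(state)) {
    params$k_fret_cleave_nm_min * state$casp8_dimer_active * state$fret_intact
  } else {
    params$k_fret_cleave_nm_min * state[["casp8_dimer_active"]] *
      state[["fret_intact"]]
  }
}
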