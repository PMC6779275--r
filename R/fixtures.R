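# Test-fixture generator: reduced configurations with known properties.

#' Generate test fixtures
#'
#' Three reduced configurations with known properties:
#' * `tiny_network` -- a one-origin, few-molecule configuration (unit volume
#'   conversion: 1 molecule = 1 nM) with irreversible binding only, small
#'   enough that its chemical master equation can be solved exactly.
#' * `default_like` -- the full network at one tenth of the default copy
#'   numbers (volume and receptor counts scaled together), for fast ensemble
#'   tests.
#' * `two_mode_delays` -- synthetic death-time samples from a well-separated
#'   two-component Gaussian mixture, for bimodality-analysis tests.
#'
#' @param kind fixture name.
#' @param seed seed for any sampling the fixture needs.
#' @return list with `config` (a `riposim_config`, or NULL for pure-data
#'   fixtures), `data` (fixture data, if any) and `expected` (named list of
#'   properties the fixture is guaranteed to have).
#' @export
generate_fixtures <- function(kind = c("tiny_network", "default_like",
                                       "two_mode_delays"), seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    tiny_network = {
      cfg <- default_model_config()
      # volume such that 1 nM corresponds to exactly one molecule
      cfg$geometry$volume_l <- 1 / (6.02214076e23 * 1e-9)
      cfg$receptors$tnfr1 <- list(count = 4, kd_nm = 1e-3)
      cfg$receptors$dr4 <- list(count = 0, kd_nm = 1)
      cfg$receptors$dr5 <- list(count = 0, kd_nm = 1)
      cfg$clustering$size_trimers <- 1L
      cfg$clustering$probability <- 1
      cfg$initial_nm <- list(fadd = 2, rip1 = 2, rip3 = 0, procasp8 = 2,
                             cflip_l = 0, cflip_s = 0, procasp3 = 0,
                             procasp6 = 0, xiap = 63, fret_substrate = 0)
      cfg$rates <- modifyList(cfg$rates, list(
        kon_rip1_elong_nm_min = 1, koff_rip1_term_min = 0,
        kon_rip3_nm_min = 0, koff_rip3_min = 0,
        kon_fadd_nm_min = 1, koff_fadd_min = 0,
        kon_procasp8_ded_nm_min = 1, koff_procasp8_ded_min = 0,
        kon_cflipl_ded_nm_min = 0, kon_cflips_ded_nm_min = 0,
        kon_ded12_ded_nm_min = 0, kon_cap_nm_min = 0, koff_cap_min = 0,
        k_cis_dimer_min = 1, k_trans_dimer_min = 0, k_het_dimer_min = 0,
        k_dimer_activation_min = 1, k_dimer_dissoc_min = 0))
      cfg <- validate_model_config(cfg)
      list(config = cfg, data = NULL,
           expected = list(n_origins = 1L, max_states = 32L,
                           irreversible = TRUE))
    },
    default_like = {
      cfg <- default_model_config()
      cfg$geometry$volume_l <- cfg$geometry$volume_l / 10
      cfg$receptors$tnfr1$count <- 90
      cfg$receptors$dr4$count <- 77
      cfg$receptors$dr5$count <- 93
      cfg <- validate_model_config(cfg)
      list(config = cfg, data = NULL,
           expected = list(copy_scale = 0.1))
    },
    two_mode_delays = {
      set.seed(seed)
      n <- 200
      comp <- rbinom(n, 1, 0.6)
      x <- ifelse(comp == 1, rnorm(n, 500, 50), rnorm(n, 90, 20))
      x <- pmax(x, 1)
      list(config = NULL, data = x,
           expected = list(bimodal = TRUE, modes = c(90, 500)))
    })
}

#' Exact chemical-master-equation solution for the tiny network
#'
#' Enumerates the reachable state space of the `tiny_network` fixture (one
#' origin; pools of RIP1, FADD and ProCasp8; irreversible elongation, FADD
#' binding, ProCasp8 binding, cis-dimerization and activation) and integrates
#' the master equation \eqn{dp/dt = Q^T p} exactly. Used as a brute-force
#' oracle for the stochastic engine.
#'
#' @param cfg the `tiny_network` configuration.
#' @param t time (min) at which to report the distribution.
#' @return list: `states` (data.frame of state tuples), `p` (probabilities at
#'   `t`), `released_dist` (probability mass over released active Casp8
#'   dimers).
#' @export
tiny_network_cme <- function(cfg, t) {
  r <- stochastic_rates(cfg)
  pool0 <- c(rip1 = cfg$initial_nm$rip1, fadd = cfg$initial_nm$fadd,
             pc8 = cfg$initial_nm$procasp8)  # conv == 1 by construction
  # state: (nR1, nF, nC8, nDim, released); origin seeded with 1 RIP1
  key <- function(s) paste(s, collapse = "/")
  start <- c(nR1 = 1, nF = 0, nC8 = 0, nDim = 0, rel = 0)
  states <- list(start)
  index <- new.env()
  assign(key(start), 1L, envir = index)
  transitions <- list()  # list of (from, to, rate)
  frontier <- list(start)
  while (length(frontier)) {
    nxt <- list()
    for (s in frontier) {
      from <- get(key(s), envir = index)
      # one RIP1 of the configured pool seeds the origin itself
      rip1_free <- pool0[["rip1"]] - s[["nR1"]]
      fadd_free <- pool0[["fadd"]] - s[["nF"]]
      pc8_free <- pool0[["pc8"]] - s[["nC8"]] - 2 * s[["nDim"]] -
        2 * s[["rel"]]
      moves <- list()
      if (rip1_free > 0) {
        moves <- c(moves, list(list(d = c(1, 0, 0, 0, 0),
                                    rate = r$c_el * rip1_free)))
      }
      if (fadd_free > 0 && s[["nF"]] < s[["nR1"]]) {
        moves <- c(moves, list(list(
          d = c(0, 1, 0, 0, 0),
          rate = r$c_f * fadd_free * (s[["nR1"]] - s[["nF"]]))))
      }
      if (pc8_free > 0 && s[["nC8"]] < s[["nF"]]) {
        moves <- c(moves, list(list(
          d = c(0, 0, 1, 0, 0),
          rate = r$c_c8 * pc8_free * (s[["nF"]] - s[["nC8"]]))))
      }
      if (s[["nC8"]] >= 2) {
        moves <- c(moves, list(list(
          d = c(0, 0, -2, 1, 0),
          rate = r$k_cis * s[["nC8"]] * (s[["nC8"]] - 1) / 2)))
      }
      if (s[["nDim"]] >= 1) {
        moves <- c(moves, list(list(d = c(0, 0, 0, -1, 1),
                                    rate = r$k_act * s[["nDim"]])))
      }
      for (mv in moves) {
        s2 <- s + setNames(mv$d, names(start))
        k2 <- key(s2)
        if (!exists(k2, envir = index)) {
          states[[length(states) + 1L]] <- s2
          assign(k2, length(states), envir = index)
          nxt[[length(nxt) + 1L]] <- s2
        }
        transitions[[length(transitions) + 1L]] <-
          c(from = from, to = get(k2, envir = index), rate = mv$rate)
      }
    }
    frontier <- nxt
  }
  ns <- length(states)
  Q <- matrix(0, ns, ns)
  for (tr in transitions) {
    Q[tr[["from"]], tr[["to"]]] <- Q[tr[["from"]], tr[["to"]]] + tr[["rate"]]
    Q[tr[["from"]], tr[["from"]]] <- Q[tr[["from"]], tr[["from"]]] -
      tr[["rate"]]
  }
  p0 <- c(1, rep(0, ns - 1))
  sol <- deSolve::lsoda(p0, c(0, t), function(tt, p, parms) list(p %*% Q),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  p <- pmax(sol[nrow(sol), -1], 0)
  p <- p / sum(p)
  st <- as.data.frame(do.call(rbind, states))
  rel_levels <- sort(unique(st$rel))
  released_dist <- vapply(rel_levels, function(k) sum(p[st$rel == k]),
                          numeric(1))
  list(states = st, p = as.numeric(p),
       released_dist = setNames(released_dist, rel_levels))
}
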