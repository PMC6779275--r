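# Population analytics: ensembles of hybrid cells, ramp-noise statistics,
# death-delay distributions, survival and deterministic parameter scans.

#' Run an ensemble of hybrid single-cell simulations
#'
#' Cells are independent: each gets its own RNG stream derived from the
#' master seed and the cell index, so the ensemble is reproducible and the
#' per-cell results do not depend on execution order.
#'
#' @param cfg a `riposim_config`.
#' @param dose_ng_ml death-ligand dose in ng/mL.
#' @param clustering logical; FALSE = disrupted receptor clustering.
#' @param n_cells ensemble size (>= 1).
#' @param master_seed integer master seed.
#' @param t_max horizon in minutes (deaths after this are censored).
#' @param module `"hybrid"` (default), `"full_ssa"` or `"assembly"`.
#' @param keep_columns trajectory columns stored per cell (the summary table
#'   is always complete); NULL stores none.
#' @param record_dt output grid in minutes.
#' @return an `ensemble_result`: `summary` data.frame (cell, seed,
#'   death_time_min, censored, ramp_cv, n_events, clamp_events), `cells`
#'   (list of kept series), `scenario`, `n`, `master_seed`, `t_max`.
#' @export
run_ensemble <- function(cfg, dose_ng_ml, clustering = TRUE, n_cells = 100,
                         master_seed = 1, t_max = cfg$simulation$t_max_min,
                         module = c("hybrid", "full_ssa", "assembly"),
                         keep_columns = c("fret_rate_nm_min",
                                          "cum_casp8_dimers",
                                          "mean_fadd_per_origin",
                                          "max_mass_kda"),
                         record_dt = cfg$simulation$record_dt_min) {
  module <- match.arg(module)
  if (n_cells < 1) config_error("bad_value", "n_cells must be >= 1")
  cells <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    seed_i <- derive_cell_seed(master_seed, i)
    tr <- tryCatch(
      switch(module,
             hybrid = simulate_cell_hybrid(cfg, dose_ng_ml, clustering,
                                           seed = seed_i, t_max = t_max,
                                           record_dt = record_dt),
             full_ssa = simulate_cell_full_ssa(cfg, dose_ng_ml, clustering,
                                               seed = seed_i, t_max = t_max,
                                               record_dt = record_dt),
             assembly = simulate_assembly(cfg, dose_ng_ml, clustering,
                                          seed = seed_i, t_max = t_max,
                                          record_dt = record_dt)),
      error = function(e) {
        stop(sprintf("cell %d (seed %.0f) failed: %s", i, seed_i,
                     conditionMessage(e)), call. = FALSE)
      })
    cv <- ramp_cv(tr, tr$death)
    rows[[i]] <- data.frame(
      cell = i, seed = seed_i,
      death_time_min = if (isTRUE(tr$death$died)) tr$death$death_time_min
                       else NA_real_,
      censored = !isTRUE(tr$death$died),
      ramp_cv = cv,
      n_events = if (is.null(tr$n_events)) NA_real_ else tr$n_events,
      clamp_events = if (is.null(tr$clamp_events)) 0L else tr$clamp_events)
    if (!is.null(keep_columns)) {
      keep <- intersect(keep_columns, names(tr$series))
      cells[[i]] <- cbind(time_min = tr$time_min, tr$series[, keep,
                                                            drop = FALSE])
    }
  }
  structure(list(summary = do.call(rbind, rows), cells = cells,
                 scenario = list(dose_ng_ml = dose_ng_ml,
                                 clustering = clustering, module = module),
                 n = n_cells, master_seed = master_seed, t_max = t_max),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$summary
  ndied <- sum(!s$censored)
  cat(sprintf(
    "<ensemble_result> %d cells, dose %g ng/mL, clustering %s (%s)\n",
    x$n, x$scenario$dose_ng_ml, if (x$scenario$clustering) "on" else "off",
    x$scenario$module))
  cat(sprintf("  deaths: %d/%d by %g min; median delay %.1f min\n", ndied,
              x$n, x$t_max,
              if (ndied) median(s$death_time_min, na.rm = TRUE) else NA))
  invisible(x)
}

#' @export
summary.ensemble_result <- function(object, ...) {
  s <- object$summary
  died <- s$death_time_min[!s$censored]
  out <- list(
    scenario = object$scenario, n = object$n,
    n_deaths = length(died),
    median_delay_min = if (length(died)) median(died) else NA_real_,
    iqr_delay_min = if (length(died)) unname(diff(quantile(died,
                                                           c(.25, .75))))
                    else NA_real_,
    survival_10h = survival_fraction(object, 600),
    median_ramp_cv = median(s$ramp_cv),
    spearman_cv_delay = if (length(died) >= 3)
      suppressWarnings(stats::cor(s$ramp_cv[!s$censored], died,
                                  method = "spearman")) else NA_real_)
  class(out) <- "summary.ensemble_result"
  out
}

#' @export
print.summary.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble: dose %g ng/mL, clustering %s, n = %d\n",
              x$scenario$dose_ng_ml,
              if (x$scenario$clustering) "on" else "off", x$n))
  cat(sprintf("  deaths %d; median delay %.0f min (IQR %.0f); survival(10 h) %.2f\n",
              x$n_deaths, x$median_delay_min, x$iqr_delay_min,
              x$survival_10h))
  cat(sprintf("  median ramp CV %.2f; Spearman rho(CV, delay) %.2f\n",
              x$median_ramp_cv, x$spearman_cv_delay))
  invisible(x)
}

#' Ramp-noise coefficient of variation
#'
#' CV (= sd/mean) of the FRET cleavage-rate series over the ramp window
#' `[0, death)` -- or the whole recorded trace for censored cells. A zero-mean
#' trace has CV 0 by convention.
#'
#' @param traj a `cell_trajectory`.
#' @param death a `death_event` (defaults to the trajectory's own).
#' @return dimensionless CV (>= 0).
#' @export
ramp_cv <- function(traj, death = traj$death) {
  tt <- traj$time_min
  rr <- traj$series$fret_rate_nm_min
  if (is.null(rr) || !length(rr)) return(0)
  if (!is.null(death) && isTRUE(death$died) &&
      is.finite(death$death_time_min)) {
    keep <- tt < death$death_time_min
    if (any(keep)) rr <- rr[keep]
  }
  m <- mean(rr)
  if (m <= 0) return(0)
  stats::sd(rr) / m
}

#' Death-delay histogram with a bimodality report
#'
#' Bins the uncensored death delays and reports (i) a dip-test p-value --
#' the dip-type statistic of the sample against Monte-Carlo draws from the
#' uniform null -- and (ii) Ashman's D separation score from a two-component
#' Gaussian mixture fit. The distribution is flagged bimodal when the dip
#' p-value is below 0.05.
#'
#' @param result an `ensemble_result`, or a numeric vector of death times.
#' @param bin_width_min histogram bin width in minutes.
#' @param n_boot Monte-Carlo replicates for the dip null.
#' @param seed seed for the Monte-Carlo null draws.
#' @return list: `histogram` (breaks/counts), `dip`, `dip_p`, `ashman_d`,
#'   `bimodal`, `n`.
#' @export
delay_histogram <- function(result, bin_width_min = 30, n_boot = 500,
                            seed = 1) {
  x <- if (inherits(result, "ensemble_result")) {
    result$summary$death_time_min[!result$summary$censored]
  } else {
    as.numeric(result[is.finite(result)])
  }
  if (length(x) < 10) {
    config_error("bad_value",
                 sprintf("need >= 10 uncensored cells, got %d", length(x)))
  }
  breaks <- seq(floor(min(x) / bin_width_min) * bin_width_min,
                ceiling(max(x) / bin_width_min) * bin_width_min +
                  bin_width_min, by = bin_width_min)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  dp <- dip_test(x, n_boot = n_boot, seed = seed)
  ad <- ashman_d(x)
  list(histogram = list(breaks = h$breaks, counts = h$counts,
                        mids = h$mids),
       dip = dp$statistic, dip_p = dp$p_value, ashman_d = ad,
       bimodal = is.finite(dp$p_value) && dp$p_value < 0.05, n = length(x))
}

#' Dip-type test of unimodality
#'
#' Statistic: the L-infinity distance between the empirical CDF and the
#' nearest convex-concave (unimodal-density) CDF, minimised over the mode
#' position; the p-value is calibrated against samples from the uniform
#' distribution, the null of Hartigan's dip test.
#'
#' @param x numeric sample.
#' @param n_boot Monte-Carlo replicates.
#' @param seed RNG seed for the null draws.
#' @return list with `statistic` and `p_value`.
#' @export
dip_test <- function(x, n_boot = 500, seed = 1) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) < 4 || stats::sd(x) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  d <- .dip_stat(x)
  null <- .dip_null_quantiles(length(x), as.integer(n_boot), as.double(seed))
  list(statistic = d, p_value = (1 + sum(null >= d)) / (n_boot + 1))
}

# Ashman's D from a two-component Gaussian mixture (mclust); D > 2 indicates
# clean separation
ashman_d <- function(x) {
  if (length(unique(x)) < 3) return(0)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(0)
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  sqrt(2) * abs(mu[1] - mu[2]) / sqrt(sg[1]^2 + sg[2]^2)
}

#' Surviving fraction at a horizon
#'
#' @param result an `ensemble_result`.
#' @param horizon_min horizon in minutes (> 0; a zero horizon returns 1).
#' @return fraction of cells with no death by the horizon, in `[0, 1]`.
#' @export
survival_fraction <- function(result, horizon_min) {
  if (horizon_min < 0) config_error("bad_value", "horizon must be >= 0")
  s <- result$summary
  dead_by <- !s$censored & s$death_time_min <= horizon_min
  mean(!dead_by)
}

#' Population mean and across-cell CV of a trajectory variable
#'
#' @param result an `ensemble_result` whose cells retain `variable`, or a
#'   list of `cell_trajectory` objects. All grids must be aligned.
#' @param variable column name (default cumulative active Casp8 dimers).
#' @return data.frame: `time_min`, `mean`, `cv` (sd/mean; 0 where mean is 0).
#' @export
population_average <- function(result, variable = "cum_casp8_dimers") {
  cells <- if (inherits(result, "ensemble_result")) result$cells
           else lapply(result, function(tr) cbind(time_min = tr$time_min,
                                                  tr$series))
  cells <- Filter(Negate(is.null), cells)
  if (length(cells) < 2) config_error("bad_value", "need >= 2 cells")
  tt <- cells[[1]]$time_min
  for (c in cells) {
    if (length(c$time_min) != length(tt) || any(c$time_min != tt)) {
      config_error("bad_value", "trajectory grids are not aligned")
    }
    if (!variable %in% names(c)) {
      config_error("bad_value", paste0("variable not retained: ", variable))
    }
  }
  m <- vapply(cells, function(c) c[[variable]], numeric(length(tt)))
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  data.frame(time_min = tt, mean = mu, cv = cv)
}

#' Deterministic death-delay parameter scan
#'
#' Runs [deterministic_full_model()] over a grid of values for one scannable
#' parameter and reports the death delay per value with a monotonicity
#' summary.
#'
#' @param cfg a `riposim_config`.
#' @param parameter one of `"kcat_ub"`, `"xiap_total"`, `"procasp6_total"`.
#' @param values numeric vector of parameter values (> 0, nonempty).
#' @param dose_ng_ml dose in ng/mL.
#' @param clustering logical.
#' @param t_max scan horizon in minutes.
#' @return data.frame (`value`, `death_time_min`, `died`) with attribute
#'   `monotone` (`"increasing"`, `"decreasing"` or `"none"`, on delays).
#' @export
parameter_scan <- function(cfg, parameter, values, dose_ng_ml = 5,
                           clustering = TRUE, t_max = 2880) {
  if (!parameter %in% c("kcat_ub", "xiap_total", "procasp6_total")) {
    config_error("bad_value", paste0("not a scannable parameter: ", parameter))
  }
  if (!length(values) || any(values < 0)) {
    config_error("bad_value", "values must be a nonempty nonnegative vector")
  }
  res <- lapply(values, function(v) {
    cfg2 <- switch(parameter,
      kcat_ub = config_update(cfg, rates = list(kcat_ub_min = v)),
      xiap_total = config_update(cfg, initial_nm = list(xiap = v)),
      procasp6_total = config_update(cfg, initial_nm = list(procasp6 = v)))
    det <- deterministic_full_model(cfg2, dose_ng_ml, clustering,
                                    t_max = t_max)
    data.frame(value = v,
               death_time_min = if (det$death$died) det$death$death_time_min
                                else NA_real_,
               died = det$death$died)
  })
  out <- do.call(rbind, res)
  d <- out$death_time_min[order(out$value)]
  d <- d[is.finite(d)]
  attr(out, "monotone") <-
    if (length(d) >= 2 && all(diff(d) >= 0)) "increasing"
    else if (length(d) >= 2 && all(diff(d) <= 0)) "decreasing"
    else "none"
  out
}
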