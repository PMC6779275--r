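#' Ligand-bound receptors at rapid equilibrium
#'
#' Receptor-ligand association is much faster than the downstream platform
#' chemistry, so the number of bound receptors is taken at the fixed point of
#' the mass-action binding kinetics: `RL = R_total / (Kd/L + 1)`. The value is
#' kept real-valued; discretisation happens once, in [trimer_count()].
#'
#' @param r_total total surface receptors per cell (monomers, >= 0).
#' @param ligand_nm free ligand concentration in nM (>= 0).
#' @param kd_nm dissociation constant in nM (> 0).
#' @return bound receptor monomers (real), in `[0, r_total]`, monotone
#'   nondecreasing in `ligand_nm`.
#' @export
#' @examples
#' bound_receptor_count(905, 0, 1)          # 0
#' bound_receptor_count(905, 1, 1)          # half saturation: 452.5
bound_receptor_count <- function(r_total, ligand_nm, kd_nm) {
  if (any(kd_nm <= 0)) stop("kd_nm must be > 0", call. = FALSE)
  if (any(r_total < 0) || any(ligand_nm < 0)) {
    stop("r_total and ligand_nm must be >= 0", call. = FALSE)
  }
  ifelse(ligand_nm == 0, 0, r_total / (kd_nm / ligand_nm + 1))
}

#' Trimeric receptor-ligand complexes
#'
#' The minimal signalling-competent unit is the receptor trimer; each trimer
#' nucleates exactly one platform origin seeded with one RIP1.
#'
#' @param rl bound receptor monomers (real, >= 0).
#' @return `floor(rl / 3)` as integer.
#' @export
trimer_count <- function(rl) {
  if (any(rl < 0)) stop("rl must be >= 0", call. = FALSE)
  as.integer(floor(rl / 3))
}

#' Receptor panel engagement for a given dose
#'
#' Applies rapid-equilibrium binding per receptor species (TNFR1, DR4, DR5,
#' each with its own Kd) and pools the resulting trimeric complexes into one
#' common origin pool; DISC and RIPoptosome origins are treated identically
#' downstream.
#'
#' @param cfg a [default_model_config()].
#' @param dose_ng_ml death-ligand dose in ng/mL.
#' @return list with per-species bound counts (`rl`), per-species trimers and
#'   `n_trimers`, the pooled origin count.
#' @export
#' @examples
#' receptor_panel(default_model_config(), 5)$n_trimers
receptor_panel <- function(cfg, dose_ng_ml) {
  if (dose_ng_ml < 0) config_error("bad_value", "dose must be >= 0")
  ligand_nm <- dose_to_nm(dose_ng_ml, cfg$receptors$ligand_mass_kda)
  species <- c("tnfr1", "dr4", "dr5")
  rl <- vapply(species, function(r) {
    bound_receptor_count(cfg$receptors[[r]]$count, ligand_nm,
                         cfg$receptors[[r]]$kd_nm)
  }, numeric(1))
  trimers <- trimer_count(rl)
  list(ligand_nm = ligand_nm, rl = rl, trimers = trimers,
       n_trimers = sum(trimers))
}

#' Validate a cluster-size distribution
#'
#' @param size_trimers integer cluster sizes in trimer units (>= 1).
#' @param probability probability mass per size (>= 0, sums to 1 within 1e-9).
#' @return invisibly TRUE; signals `riposim_bad_value` otherwise.
#' @export
validate_cluster_distribution <- function(size_trimers, probability) {
  if (length(size_trimers) != length(probability) || !length(size_trimers)) {
    config_error("bad_value", "cluster sizes and probabilities must be equal-length, nonempty")
  }
  if (any(size_trimers < 1) || any(size_trimers != round(size_trimers))) {
    config_error("bad_value", "cluster sizes must be integers >= 1")
  }
  if (any(probability < 0) || abs(sum(probability) - 1) > 1e-9) {
    config_error("bad_value", "cluster probabilities must be >= 0 and sum to 1")
  }
  invisible(TRUE)
}

#' Read a cluster-size distribution from CSV
#'
#' Two columns: `size_trimers`, `probability`.
#'
#' @param path CSV path.
#' @return list with `size_trimers` and `probability`.
#' @export
read_cluster_distribution <- function(path) {
  df <- read.csv(path)
  if (!all(c("size_trimers", "probability") %in% names(df))) {
    config_error("malformed", "cluster CSV needs columns size_trimers, probability")
  }
  validate_cluster_distribution(df$size_trimers, df$probability)
  list(size_trimers = as.integer(df$size_trimers), probability = df$probability)
}

#' Assign platform origins to receptor clusters
#'
#' Trimeric complexes organise into higher-order membrane clusters; ProCasp8
#' trans-activation is only possible between platforms of the same cluster.
#' Cluster sizes are drawn i.i.d. from the calibrated size distribution until
#' the trimer budget is exhausted; a remainder that cannot fill the last
#' sampled size forms one final smaller cluster. With clustering disrupted
#' every origin is a singleton, which zeroes all trans-activation propensity.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param n_trimers number of trimeric complexes (= platform origins).
#' @param size_trimers,probability the cluster-size distribution.
#' @param clustering_enabled logical; FALSE gives singletons ("disrupted").
#' @return object of class `cluster_assignment`: list with `cluster_id`
#'   (integer vector, one entry per origin) and `sizes` (per-cluster sizes).
#' @export
assign_clusters <- function(n_trimers, size_trimers, probability,
                            clustering_enabled = TRUE) {
  validate_cluster_distribution(size_trimers, probability)
  if (n_trimers < 0 || n_trimers != round(n_trimers)) {
    config_error("bad_value", "n_trimers must be a nonnegative integer")
  }
  n_trimers <- as.integer(n_trimers)
  if (n_trimers == 0L) {
    out <- list(cluster_id = integer(0), sizes = integer(0),
                clustering_enabled = clustering_enabled)
    class(out) <- "cluster_assignment"
    return(out)
  }
  if (!clustering_enabled) {
    sizes <- rep(1L, n_trimers)
  } else {
    sizes <- integer(0)
    remaining <- n_trimers
    while (remaining > 0L) {
      s <- sample(size_trimers, 1L, prob = probability)
      if (s >= remaining) {        # remainder forms one final smaller cluster
        sizes <- c(sizes, remaining)
        remaining <- 0L
      } else {
        sizes <- c(sizes, s)
        remaining <- remaining - s
      }
    }
  }
  out <- list(cluster_id = rep(seq_along(sizes), times = sizes),
              sizes = sizes, clustering_enabled = clustering_enabled)
  class(out) <- "cluster_assignment"
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d origins in %d clusters (%s)\n",
              length(x$cluster_id), length(x$sizes),
              if (x$clustering_enabled) "clustering" else "disrupted"))
  invisible(x)
}
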