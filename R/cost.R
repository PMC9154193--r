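#' Spatial-pattern statistics of a target field
#'
#' Normalizes a raw target (image intensity or counts) and computes the
#' (mu, sigma2, C(r)) triple used by the fitting cost.
#'
#' @param raw_field Nonnegative matrix on the chamber grid.
#' @param l0 Chamber edge, um.
#' @return List `mu`, `sigma2`, `correlation`.
#' @export
target_statistics <- function(raw_field, l0 = 0.5) {
  S <- normalize_field(raw_field)
  if (attr(S, "zero")) stop("target field is identically zero")
  spatial_statistics(unclass(S), l0)
}

#' Pattern-matching cost between simulated and target statistics
#'
#' The cost is the equally weighted squared relative mismatch of mean,
#' standard deviation, and normalized correlation profile:
#' `C = 1/3 [(mu_I - mu_n)/mu_I]^2 + 1/3 [(sigma_I - sigma_n)/sigma_I]^2 +
#' 1/3 sum_r [C_I(r)/C_I(0) - C_n(r)/C_n(0)]^2`, where `sigma` denotes the
#' standard deviation (square root of the variance entry). Both statistics
#' bundles must be computed on the identical r-grid. The cost is invariant
#' to rescaling the raw simulated counts (normalization cancels).
#'
#' @param sim_stats,target_stats Lists as returned by [target_statistics()].
#' @return List with `cost` and the three `components`.
#' @export
cost_from_stats <- function(sim_stats, target_stats) {
  if (target_stats$mu == 0 || target_stats$sigma2 == 0)
    stop("cost undefined: target mean or variance is zero")
  if (nrow(sim_stats$correlation) != nrow(target_stats$correlation) ||
      any(abs(sim_stats$correlation$r - target_stats$correlation$r) > 1e-9))
    stop("simulation and target statistics use different r grids")
  sI <- sqrt(target_stats$sigma2)
  sN <- sqrt(sim_stats$sigma2)
  term_mu <- ((target_stats$mu - sim_stats$mu) / target_stats$mu)^2 / 3
  term_sd <- ((sI - sN) / sI)^2 / 3
  cI <- target_stats$correlation$C_over_C0
  cN <- sim_stats$correlation$C_over_C0
  if (anyNA(cN)) cN[is.na(cN)] <- 0
  term_C <- sum((cI - cN)^2) / 3
  list(cost = term_mu + term_sd + term_C,
       components = c(mean = term_mu, sd = term_sd, correlation = term_C))
}

#' Evaluate the fitting cost for one parameter vector
#'
#' Runs one stochastic trajectory with intrinsic-noise realization `eta` and
#' initial-configuration seed `n0`, extracts the NKG2D-moiety field at the
#' fitting time, and scores it against the target statistics. One (eta, n0)
#' pair per evaluation; ensemble averaging is deliberately left to the
#' post-hoc uncertainty analysis.
#'
#' @param theta Named numeric vector of varied parameters.
#' @param target_stats Output of [target_statistics()].
#' @param simulate_fn Function `(theta, eta, n0) -> raw count field` on the
#'   chamber grid (see [make_simulator()]).
#' @param eta Integer intrinsic-noise seed.
#' @param n0 Integer initial-configuration seed.
#' @param l0 Chamber edge, um.
#' @return Object of class `"nk_cost"`: list with `theta`, `eta`, `n0`,
#'   `cost`, `components`.
#' @export
cost_evaluation <- function(theta, target_stats, simulate_fn, eta = 1L,
                            n0 = 1L, l0 = 0.5) {
  field <- simulate_fn(theta, eta, n0)
  S <- normalize_field(field)
  sim_stats <- if (attr(S, "zero")) {
    list(mu = 0, sigma2 = 0,
         correlation = transform(target_stats$correlation, C = 0,
                                 C_over_C0 = 0))
  } else spatial_statistics(unclass(S), l0)
  cv <- if (sim_stats$mu == 0) {
    list(cost = Inf, components = c(mean = Inf, sd = Inf, correlation = Inf))
  } else cost_from_stats(sim_stats, target_stats)
  structure(list(theta = theta, eta = eta, n0 = n0, cost = cv$cost,
                 components = cv$components), class = "nk_cost")
}

#' Build a simulator closure for parameter fitting
#'
#' Returns a function `(theta, eta, n0)` that constructs an initial
#' configuration (homogeneous receptors/kinases plus ULBP3 seeding with the
#' probability implied by `theta["ulbp3_total"]`, if varied), applies the
#' parameter overrides in `theta` to the rate and spatial-parameter tables,
#' runs the model to `t_fit`, and returns the NKG2D-moiety count field.
#'
#' @param variant [nk_variant()].
#' @param geometry [nk_geometry()].
#' @param densities [nk_densities()].
#' @param t_fit Fitting time, s.
#' @param rates,params Baseline tables; entries named in `theta` are
#'   overridden per evaluation.
#' @return Function `(theta, eta, n0) -> integer matrix`.
#' @export
make_simulator <- function(variant = nk_variant(2),
                           geometry = nk_geometry(),
                           densities = nk_densities(),
                           t_fit = 60,
                           rates = nk_rates(variant$model),
                           params = nk_params(variant$model,
                                              l0 = geometry$l0,
                                              box_side_um = geometry$box_side_um)) {
  spatial_names <- c("beta", "k_cluster_move", "K", "w", "k_influx")
  function(theta, eta = 1L, n0 = 1L) {
    r <- rates
    p <- params
    f <- densities$ulbp3_f
    for (nm in names(theta)) {
      if (nm %in% spatial_names) p[[nm]] <- theta[[nm]]
      else if (nm == "ulbp3_total") {
        n_ch <- geometry$nx^2 + geometry$n_rim
        f <- min(1, theta[[nm]] / (n_ch * densities$ulbp3_per_seed))
      } else if (nm %in% names(r)) r[[nm]] <- theta[[nm]]
      else stop("unknown fitted parameter: ", nm)
    }
    cfg <- init_homogeneous(geometry, densities, variant, seed = n0,
                            params = p)
    cfg <- seed_ulbp3(cfg, f = f, seed = n0 + 1L,
                      per_seed = densities$ulbp3_per_seed)
    traj <- run_kmc(cfg, r, p, variant, t_end = t_fit,
                    snapshot_times = t_fit, seed = eta,
                    keep_snapshots = TRUE)
    nkg2d_field(traj$snapshots[[length(traj$snapshots)]])
  }
}
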