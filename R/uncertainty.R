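#' Intrinsic-noise spread of the cost at the fitted optimum
#'
#' Re-evaluates the cost at `theta_min` under `n_reps` distinct
#' intrinsic-noise seeds (fixed initial configuration) and returns the sample
#' standard deviation `sigma_C`. The acceptance band for the parameter cloud
#' is `C <= C_min + 2 sigma_C`.
#'
#' @param theta_min Named parameter vector.
#' @param cost_fn Function `(theta, eta) -> cost`.
#' @param n_reps Ensemble size (>= 30).
#' @param seed Base seed for the eta ensemble.
#' @return List with `sigma_C`, `mean_C`, and the cost sample `costs`.
#' @export
noise_sigma <- function(theta_min, cost_fn, n_reps = 100, seed = 1L) {
  if (n_reps < 30) stop("n_reps must be at least 30")
  etas <- seed * 100000L + seq_len(n_reps)
  costs <- vapply(etas, function(e) cost_fn(theta_min, e), 0)
  list(sigma_C = stats::sd(costs), mean_C = mean(costs), costs = costs)
}

#' Density-peak clustering of an accepted parameter cloud
#'
#' Implements decision-graph clustering: the cutoff `d_c` is chosen so the
#' average number of neighbors within `d_c` is `dc_neighbor_fraction` of the
#' point count; the local density `rho_i` is the neighbor count within
#' `d_c`; `delta_i` is the distance to the nearest point of higher density
#' (the global density peak takes the maximum distance). Cluster centers are
#' the decision-graph outliers (large `rho` and `delta`); remaining points
#' follow their nearest higher-density neighbor chain.
#'
#' @param points Numeric matrix, points x dimensions, each coordinate scaled
#'   to \[0, 1\].
#' @param dc_neighbor_fraction Target mean neighbor fraction for `d_c`.
#' @param delta_factor Centers must have `delta` exceeding
#'   `delta_factor * d_c`, at least half of the largest `delta`, and a local
#'   density above half the peak density (decision-graph outliers in both
#'   coordinates); a structureless cloud therefore yields a single center.
#' @return List with `assignments` (integer cluster ids), `centers` (row
#'   indices), `n_clusters`, `d_c`, and `decision_graph` (data.frame with
#'   `rho`, `delta`).
#' @export
density_peak_cluster <- function(points, dc_neighbor_fraction = 0.02,
                                 delta_factor = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5) stop("need at least 5 points for the d_c neighbor rule")
  dm <- as.matrix(stats::dist(points))
  off <- dm[upper.tri(dm)]
  d_c <- stats::quantile(off, probs = dc_neighbor_fraction, names = FALSE)
  if (d_c <= 0) d_c <- min(off[off > 0], 1e-12)
  # Gaussian-kernel local density (the small-sample variant of the
  # neighbor-count rho; less tie-prone than a hard cutoff)
  rho <- rowSums(exp(-(dm / d_c)^2)) - 1
  ord <- order(rho, decreasing = TRUE)
  delta <- numeric(n)
  nn_higher <- integer(n)
  delta[ord[1]] <- max(dm[ord[1], ])
  nn_higher[ord[1]] <- ord[1]
  for (k in 2:n) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1)]
    j <- higher[which.min(dm[i, higher])]
    delta[i] <- dm[i, j]
    nn_higher[i] <- j
  }
  centers <- which(delta > pmax(delta_factor * d_c, 0.5 * max(delta)) &
                     rho > 0.5 * max(rho))
  if (length(centers) == 0) centers <- ord[1]
  assignments <- rep(NA_integer_, n)
  assignments[centers] <- seq_along(centers)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (is.na(assignments[i])) assignments[i] <- assignments[nn_higher[i]]
  }
  list(assignments = assignments, centers = centers,
       n_clusters = length(centers), d_c = d_c,
       decision_graph = data.frame(rho = rho, delta = delta))
}

#' Parameter-uncertainty report from a swarm history
#'
#' Collects the evaluations whose cost lies within
#' `[0, C_min + 2 sigma_C]`, scales each parameter to \[0, 1\] by its search
#' bounds, clusters the accepted cloud by density peaks, and reports the
#' per-parameter standard deviation within the main cluster (the one
#' containing the optimum) both in scaled log10 coordinates and
#' back-transformed.
#'
#' @param pso_result An `nk_pso_result`.
#' @param sigma_C Intrinsic-noise s.d. from [noise_sigma()].
#' @param dc_neighbor_fraction Passed to [density_peak_cluster()].
#' @return Object of class `"nk_uncertainty"`: `C_thres`, `accepted`
#'   (data.frame), `n_clusters`, `main_cluster_size`, `sd_scaled`,
#'   `sd_log10`, `theta_table` (value, s.d., s.d./value on the natural
#'   scale), `clustering`.
#' @export
uncertainty_report <- function(pso_result, sigma_C,
                               dc_neighbor_fraction = 0.02) {
  h <- pso_result$history
  stopifnot(nrow(h) > 0)
  C_thres <- pso_result$cost_min + 2 * sigma_C
  pn <- names(pso_result$bounds$lower)
  cols <- paste0("log10_", pn)
  acc <- h[is.finite(h$cost) & h$cost <= C_thres, , drop = FALSE]
  lo <- log10(pso_result$bounds$lower)
  hi <- log10(pso_result$bounds$upper)
  theta_min_log <- log10(pso_result$theta_min)
  if (nrow(acc) < 5) {
    # too few accepted points to cluster: report the optimum alone
    sd_log10 <- stats::setNames(rep(0, length(pn)), pn)
    clustering <- NULL
    n_clusters <- 1L
    main_size <- nrow(acc)
    scaled <- NULL
  } else {
    scaled <- sweep(sweep(as.matrix(acc[, cols, drop = FALSE]), 2, lo), 2,
                    hi - lo, "/")
    clustering <- density_peak_cluster(scaled, dc_neighbor_fraction)
    n_clusters <- clustering$n_clusters
    best_row <- which.min(acc$cost)
    main <- clustering$assignments == clustering$assignments[best_row]
    main_size <- sum(main)
    sd_scaled <- apply(scaled[main, , drop = FALSE], 2, stats::sd)
    sd_log10 <- stats::setNames(sd_scaled * (hi - lo), pn)
  }
  if (is.null(scaled)) sd_scaled <- stats::setNames(rep(0, length(pn)), pn)
  # back-transformed spread: s.d. of the natural-scale values in the cloud
  sd_natural <- if (!is.null(scaled) && main_size > 1) {
    apply(10^as.matrix(acc[clustering$assignments ==
                             clustering$assignments[which.min(acc$cost)],
                           cols, drop = FALSE]), 2, stats::sd)
  } else rep(0, length(pn))
  theta_table <- data.frame(parameter = pn,
                            value = unname(pso_result$theta_min),
                            sd = unname(sd_natural),
                            sd_over_value = unname(sd_natural) /
                              unname(pso_result$theta_min))
  structure(list(C_thres = C_thres, sigma_C = sigma_C,
                 accepted = acc, n_clusters = n_clusters,
                 main_cluster_size = main_size,
                 sd_scaled = sd_scaled, sd_log10 = sd_log10,
                 theta_table = theta_table, clustering = clustering),
            class = "nk_uncertainty")
}

#' @export
print.nk_uncertainty <- function(x, ...) {
  cat(sprintf("<nk_uncertainty> C_thres = %.4g, %d accepted point(s), %d cluster(s)\n",
              x$C_thres, nrow(x$accepted), x$n_clusters))
  print(x$theta_table, row.names = FALSE)
  invisible(x)
}
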