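#' Place molecules uniformly at random over the box
#'
#' Multinomial placement of `total_count` molecules of one species over all
#' box chambers with equal weights (a spatially homogeneous dose).
#'
#' @param config An `nk_lattice`.
#' @param species Species name.
#' @param total_count Molecules to add.
#' @param seed RNG seed.
#' @return Updated configuration.
#' @export
place_homogeneous <- function(config, species, total_count, seed = 1L) {
  set.seed(seed)
  nch <- config$geometry$nx * config$geometry$ny
  add <- tabulate(sample.int(nch, total_count, replace = TRUE), nbins = nch)
  slice <- config$counts[, , species]
  config$counts[, , species] <- slice +
    matrix(as.integer(add), config$geometry$nx, config$geometry$ny)
  config$pvav1_total <- pvav1_total(config)
  config
}

#' Ligand-rebinding decay assay
#'
#' Tracks the decay of an initial population of receptor-ligand complexes
#' when binding/unbinding is the only reaction, receptors are immobile, and
#' no free ligand exists at t = 0: released ligands diffuse and may rebind.
#' With `kon = 0` the complex count decays as `exp(-koff t)`; rebinding
#' produces a slower, non-exponential decay. Receptors are laid out
#' uniformly or proportionally to a supplied field (a clustered snapshot).
#'
#' @param layout `"uniform"` or a nonnegative `nx x ny` matrix.
#' @param bound_fraction Fraction of receptors ligand-bound at t = 0.
#' @param kon Association rate, 1/(uM s) (0 disables rebinding).
#' @param koff Dissociation rate, 1/s.
#' @param t_end End time, s.
#' @param replicates Independent initial configurations.
#' @param seed Base seed.
#' @param geometry [nk_geometry()] (the influx rim is not used).
#' @param nkg2d_density Receptor areal density, molecules/um^2.
#' @return List with `decay` (data.frame: time, mean_fraction, se),
#'   `fitted_rate` (log-linear slope magnitude on t < 10 s), `koff`, and
#'   `replicates`.
#' @export
run_rebinding_decay <- function(layout = "uniform", bound_fraction = 0.9,
                                kon = nk_rates(2)$kon_NKG2D_ULBP3,
                                koff = 0.023, t_end = 60, replicates = 50,
                                seed = 1L, geometry = NULL,
                                nkg2d_density = 8) {
  stopifnot(bound_fraction >= 0, bound_fraction <= 1)
  if (is.null(geometry))
    geometry <- nk_geometry(rim_width_chambers = 0L)
  variant <- nk_variant(1, "A")
  rates <- nk_rates(1, l0 = geometry$l0, kon_NKG2D_ULBP3 = kon,
                    koff_NKG2D_ULBP3 = koff)
  params <- nk_params(1, l0 = geometry$l0, box_side_um = geometry$box_side_um,
                      k_influx = 0, receptors_immobile = TRUE)
  channels <- build_channels(rates, variant)
  channels$rate[!channels$id %in% c("r1f", "r1b_C0")] <- 0
  total_n <- round(nkg2d_density * geometry$box_side_um^2)
  times <- sort(unique(c(seq(0, min(10, t_end), by = 1),
                         seq(0, t_end, by = 5))))
  nch <- geometry$nx * geometry$ny
  frac <- matrix(NA_real_, replicates, length(times))
  for (rep_i in seq_len(replicates)) {
    s <- seed + rep_i * 101L
    set.seed(s)
    cfg <- init_homogeneous(geometry, nk_densities(NKG2D = 0, SFK = 0,
                                                   Vav1 = 0, SHP1 = 0,
                                                   KIR2DL2 = 0, HLAC = 0),
                            variant, seed = s, params = params)
    field <- if (is.matrix(layout)) layout else matrix(1, geometry$nx,
                                                       geometry$ny)
    cfg <- place_clusters_from_field(cfg, "N", field,
                                     total_count = total_n,
                                     threshold = Inf,
                                     coclustered_SFK_fraction = 0,
                                     seed = s)
    # bind the initial fraction in place: N -> C0, no free ligand
    n_slice <- cfg$counts[, , "N"]
    n_bind <- round(bound_fraction * sum(n_slice))
    bind <- drain_counts(as.vector(n_slice), n_bind)
    cfg$counts[, , "N"] <- matrix(as.integer(as.vector(n_slice) - bind),
                                  geometry$nx, geometry$ny)
    cfg$counts[, , "C0"] <- matrix(as.integer(bind), geometry$nx,
                                   geometry$ny)
    traj <- run_kmc(cfg, rates, params, variant, t_end = t_end,
                    snapshot_times = times, seed = s,
                    channels = channels, keep_snapshots = FALSE)
    n0c <- traj$totals[1, "C0"]
    frac[rep_i, ] <- if (n0c > 0) traj$totals[, "C0"] / n0c else 0
  }
  decay <- data.frame(time = times,
                      mean_fraction = colMeans(frac),
                      se = apply(frac, 2, stats::sd) / sqrt(replicates))
  early <- decay[decay$time < 10 & decay$mean_fraction > 0, ]
  fitted_rate <- if (nrow(early) >= 2) {
    -unname(stats::coef(stats::lm(log(mean_fraction) ~ time,
                                  data = early))[2])
  } else NA_real_
  list(decay = decay, fitted_rate = fitted_rate, koff = koff,
       replicates = replicates)
}

#' pVav1 dose response with and without microcluster formation
#'
#' Compares total pVav1 at the evaluation time across ULBP3 doses between
#' Case A (no microcluster formation, transport, or co-clustering) and Case
#' B (full rule set) for one model variant.
#'
#' @param model Model variant (1 or 2).
#' @param ulbp3_doses Total ULBP3 molecules (box + rim) per dose.
#' @param t_eval Evaluation time, s.
#' @param replicates Configurations per (case, dose).
#' @param seed Base seed.
#' @param geometry [nk_geometry()].
#' @return data.frame: model, case, dose, mean_pvav1, se, n.
#' @export
run_case_AB <- function(model = 2, ulbp3_doses = c(1200, 2400, 3462),
                        t_eval = 60, replicates = 20, seed = 1L,
                        geometry = nk_geometry()) {
  rates <- nk_rates(model, l0 = geometry$l0)
  params <- nk_params(model, l0 = geometry$l0,
                      box_side_um = geometry$box_side_um)
  densities <- nk_densities()
  n_sites <- (geometry$nx^2 + geometry$n_rim) * densities$ulbp3_per_seed
  rows <- list()
  for (case in c("A", "B")) {
    variant <- nk_variant(model, case)
    for (dose in ulbp3_doses) {
      f <- min(1, dose / n_sites)
      pv <- vapply(seq_len(replicates), function(rep_i) {
        s <- seed + rep_i * 313L
        cfg <- init_homogeneous(geometry, densities, variant, seed = s,
                                params = params)
        cfg <- seed_ulbp3(cfg, f = f, seed = s + 1L,
                          per_seed = densities$ulbp3_per_seed)
        traj <- run_kmc(cfg, rates, params, variant, t_end = t_eval,
                        snapshot_times = t_eval, seed = s,
                        keep_snapshots = FALSE)
        traj$series$pvav1_total[nrow(traj$series)]
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(model = model, case = case, dose = dose,
                   mean_pvav1 = mean(pv),
                   se = stats::sd(pv) / sqrt(replicates), n = replicates)
    }
  }
  do.call(rbind, rows)
}

#' Inhibition of NKG2D signaling by stationary KIR2DL2 microclusters
#'
#' Runs the full model with the inhibitory arm enabled, KIR2DL2 placed as
#' immobile microclusters from an intensity field (with co-clustered SFK),
#' and HLA-C present or absent, recording the total pVav1 and the
#' NKG2D-moiety count in the central 3 um x 3 um region over time.
#'
#' @param model Model variant.
#' @param kir_field KIR2DL2 intensity field; default a synthetic
#'   periphery-biased clustered pattern.
#' @param with_hlac Logical; include the inhibitory ligand.
#' @param t_end End time, s.
#' @param replicates Configurations.
#' @param seed Base seed.
#' @param geometry [nk_geometry()].
#' @param snapshot_times Recording times, s.
#' @return List with `series` (data.frame: time, mean_pvav1, se_pvav1,
#'   mean_central_nkg2d, se_central_nkg2d), `with_hlac`, `replicates`.
#' @export
run_inhibition <- function(model = 2, kir_field = NULL, with_hlac = TRUE,
                           t_end = 60, replicates = 20, seed = 1L,
                           geometry = nk_geometry(),
                           snapshot_times = seq(0, 60, by = 15)) {
  variant <- nk_variant(model, "B", inhibition = TRUE)
  rates <- nk_rates(model, l0 = geometry$l0)
  params <- nk_params(model, l0 = geometry$l0,
                      box_side_um = geometry$box_side_um)
  densities <- nk_densities(HLAC = if (with_hlac) nk_densities()$HLAC else 0)
  if (is.null(kir_field))
    kir_field <- unclass(generate_synthetic_target(
      n_clusters = 25, radius_chambers = 1, background = 0.02,
      noise_sd = 0.01, radial_bias = 0.1, geometry = geometry, seed = seed))
  snapshot_times <- sort(unique(pmin(snapshot_times, t_end)))
  pv <- ce <- matrix(NA_real_, replicates, length(snapshot_times))
  for (rep_i in seq_len(replicates)) {
    s <- seed + rep_i * 517L
    cfg <- init_homogeneous(geometry, densities, variant, seed = s,
                            params = params)
    cfg <- place_clusters_from_field(cfg, "K", kir_field,
                                     total_count = round(densities$KIR2DL2 *
                                                           geometry$box_side_um^2),
                                     seed = s)
    cfg <- seed_ulbp3(cfg, seed = s + 1L)
    traj <- run_kmc(cfg, rates, params, variant, t_end = t_end,
                    snapshot_times = snapshot_times, seed = s,
                    keep_snapshots = FALSE)
    pv[rep_i, ] <- traj$series$pvav1_total
    ce[rep_i, ] <- traj$series$central_nkg2d
  }
  list(series = data.frame(
    time = snapshot_times,
    mean_pvav1 = colMeans(pv),
    se_pvav1 = apply(pv, 2, stats::sd) / sqrt(replicates),
    mean_central_nkg2d = colMeans(ce),
    se_central_nkg2d = apply(ce, 2, stats::sd) / sqrt(replicates)),
    with_hlac = with_hlac, replicates = replicates)
}

#' pVav1 suppression by inhibitory ligand dose and spatial pattern
#'
#' Varies the total HLA-C dose, distributed homogeneously or in a ring
#' (empty at the center), for the pVav1-coupled (Model 2) and uncoupled
#' (Model 3) transport variants, and reports mean total pVav1 at the
#' evaluation time.
#'
#' @param models Model variants to compare.
#' @param patterns `"homogeneous"` and/or `"ring"`.
#' @param doses Total HLA-C molecules in the box.
#' @param t_eval Evaluation time, s.
#' @param replicates Configurations per condition.
#' @param seed Base seed.
#' @param geometry [nk_geometry()].
#' @param ring_radii Inner/outer ring radii, um.
#' @return data.frame: model, pattern, dose, mean_pvav1, se, n.
#' @export
dose_response <- function(models = c(2, 3),
                          patterns = c("homogeneous", "ring"),
                          doses = c(1000, 4000), t_eval = 60,
                          replicates = 20, seed = 1L,
                          geometry = nk_geometry(),
                          ring_radii = c(3.5, 7)) {
  densities <- nk_densities(HLAC = 0)
  rows <- list()
  for (model in models) {
    variant <- nk_variant(model, "B", inhibition = TRUE)
    rates <- nk_rates(model, l0 = geometry$l0)
    params <- nk_params(model, l0 = geometry$l0,
                        box_side_um = geometry$box_side_um)
    for (pattern in patterns) {
      for (dose in doses) {
        pv <- vapply(seq_len(replicates), function(rep_i) {
          s <- seed + rep_i * 719L
          cfg <- init_homogeneous(geometry, densities, variant, seed = s,
                                  params = params)
          if (dose > 0) {
            cfg <- if (pattern == "homogeneous")
              place_homogeneous(cfg, "H", dose, seed = s)
            else place_ring(cfg, "H", inner_radius = ring_radii[1],
                            outer_radius = ring_radii[2],
                            total_count = dose, seed = s)
          }
          cfg <- seed_ulbp3(cfg, seed = s + 1L)
          traj <- run_kmc(cfg, rates, params, variant, t_end = t_eval,
                          snapshot_times = t_eval, seed = s,
                          keep_snapshots = FALSE)
          traj$series$pvav1_total[nrow(traj$series)]
        }, 0)
        rows[[length(rows) + 1L]] <-
          data.frame(model = model, pattern = pattern, dose = dose,
                     mean_pvav1 = mean(pv),
                     se = stats::sd(pv) / sqrt(replicates), n = replicates)
      }
    }
  }
  do.call(rbind, rows)
}
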