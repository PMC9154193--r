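AVOGADRO <- 6.02214076e23
UM3_TO_L <- 1e-15  # 1 um^3 = 1e-15 liter

#' Convert a bimolecular rate constant to a per-pair propensity rate
#'
#' Binding propensities on the lattice are `k' * n_x * n_y` per chamber, with
#' `k' = k_on / (N_A * v)` where `v` is the reaction volume of the encounter
#' (receptor-ligand gap, receptor-kinase layer, or the cytosolic chamber
#' volume) expressed in liters.
#'
#' @param k_on Bimolecular rate in 1/(uM s).
#' @param volume_um3 Reaction volume factor in um^3.
#' @return Per-pair rate in 1/s.
#' @examples
#' to_per_pair_rate(27.7, 5e-4)  # ~92 per second per pair
#' @export
to_per_pair_rate <- function(k_on, volume_um3) {
  stopifnot(k_on >= 0)
  if (any(volume_um3 <= 0)) stop("volume factor must be positive")
  (k_on * 1e6) / (AVOGADRO * volume_um3 * UM3_TO_L)
}

#' Reconstruct an association rate from an equilibrium constant
#'
#' `k_on = k_off / K_D`, the identity used to pin association rates from
#' measured dissociation constants (e.g. KIR2DL2:HLA-C with K_D = 0.036 uM and
#' k_off = 1/s gives 27.7 1/(uM s)).
#'
#' @param k_off Dissociation rate, 1/s.
#' @param kd Dissociation constant, uM.
#' @return Association rate in 1/(uM s).
#' @export
kon_from_kd <- function(k_off, kd) {
  stopifnot(k_off >= 0, kd > 0)
  k_off / kd
}

#' Complex half-life from its dissociation rate
#'
#' @param k_off Dissociation rate, 1/s.
#' @return `ln(2)/k_off` in seconds (~30 s for the NKG2D·ULBP3 complex at
#'   `k_off = 0.023`/s).
#' @export
half_life <- function(k_off) {
  stopifnot(k_off > 0)
  log(2) / k_off
}

#' Kinetic rate table
#'
#' All kinetic rates of the reaction rules with units, volume factors, and the
#' bounds within which the fitted subset is varied during particle swarm
#' optimization. Defaults are the fitted values for the chosen model variant;
#' the inhibitory-arm rates are fixed literature-derived values.
#'
#' Units: `kon_*` in 1/(uM s); `koff_*`, `kphos_*`, `kdephos_*` in 1/s.
#' Volume factors in um^3: `v_recep_lig = l0^2 * 2 nm`,
#' `v_recep_SFK = l0^2 * 10 nm`, `v_cytosol = l0^2 * 2*l0`,
#' `v_Vav1_plasma = l0^3`.
#'
#' @param model 1 or 2; selects the fitted default column (Model 3 reuses the
#'   Model 2 rates).
#' @param l0 Chamber edge, um.
#' @param ... Named overrides for any rate entry.
#' @return Object of class `"nk_rates"`: named list of rates plus
#'   `volume_factors` and `pso_bounds`.
#' @export
nk_rates <- function(model = 2, l0 = 0.5, ...) {
  model <- as.integer(model)
  if (model == 3L) model <- 2L
  stopifnot(model %in% 1:2)
  fit <- if (model == 1L) {
    list(kon_NKG2D_ULBP3 = 5.631e-2, kon_DAP10_SFK = 47.14,
         koff_DAP10_SFK = 1.831, kphos_DAP10 = 0.452,
         kon_pDAP10_Vav1 = 35.4, koff_pDAP10_Vav1 = 5.069,
         kon_pDAP10_Vav1_SFK = 1.023e-2, koff_pDAP10_Vav1_SFK = 0.042,
         kphos_Vav1 = 0.922, kdephos_pDAP10 = 0.127, kdephos_pVav1 = 0.048)
  } else {
    list(kon_NKG2D_ULBP3 = 2.387e-2, kon_DAP10_SFK = 1.054,
         koff_DAP10_SFK = 0.006, kphos_DAP10 = 2.189,
         kon_pDAP10_Vav1 = 0.6112, koff_pDAP10_Vav1 = 0.01,
         kon_pDAP10_Vav1_SFK = 7.528, koff_pDAP10_Vav1_SFK = 0.028,
         kphos_Vav1 = 0.776, kdephos_pDAP10 = 2.0, kdephos_pVav1 = 1.0)
  }
  r <- c(fit, list(
    koff_NKG2D_ULBP3 = 0.023,
    # free-pVav1 dephosphorylation: same background-phosphatase rate as the
    # complex-bound form (no separate value is established)
    kdephos_pVav1_free = fit$kdephos_pVav1,
    # inhibitory arm, fixed
    kon_KIR_HLAC = 27.7, koff_KIR_HLAC = 1.0,
    kon_pITIM_SHP1 = 36.1e-2, koff_pITIM_SHP1 = 5.09e-4,
    kon_SHP1_pVav1 = 6.11, koff_SHP1_pVav1 = 0.01,
    kdephos_SHP1_pVav1 = 3.0
  ))
  vf <- list(v_recep_lig = l0 * l0 * 0.002,
             v_recep_SFK = l0 * l0 * 0.010,
             v_cytosol = l0 * l0 * 2 * l0,
             v_Vav1_plasma = l0^3)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(r))
    if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
    r[names(ov)] <- ov
  }
  if (any(unlist(r) < 0)) stop("all rates must be nonnegative")
  out <- c(r, list(volume_factors = vf, pso_bounds = rate_pso_bounds()))
  class(out) <- "nk_rates"
  out
}

#' Bounds within which rates and spatial parameters are fitted
#'
#' @return data.frame with columns `parameter`, `lower`, `upper`, `unit`.
#' @export
rate_pso_bounds <- function() {
  data.frame(
    parameter = c("kon_NKG2D_ULBP3", "kon_DAP10_SFK", "koff_DAP10_SFK",
                  "kphos_DAP10", "kon_pDAP10_Vav1", "koff_pDAP10_Vav1",
                  "kon_pDAP10_Vav1_SFK", "koff_pDAP10_Vav1_SFK",
                  "kphos_Vav1", "kdephos_pDAP10", "kdephos_pVav1",
                  "beta", "k_cluster_move", "K", "w", "k_influx",
                  "ulbp3_total"),
    lower = c(6e-5, 1.1, 0.006, 0.01, 0.6, 0.01, 7.6e-3, 0.01, 0.01, 0.02,
              0.01, 0.01, 0.1, 102, 0.79, 1e-5, 1075),
    upper = c(6e-2, 110, 6, 10, 60, 10, 7.6, 10, 10, 2, 1, 0.1, 5, 1581, 1,
              1e-2, 3468),
    unit = c("1/(uM s)", "1/(uM s)", "1/s", "1/s", "1/(uM s)", "1/s",
             "1/(uM s)", "1/s", "1/s", "1/s", "1/s", "", "1/s", "count", "",
             "1/s", "count"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.nk_rates <- function(x, ...) {
  nm <- setdiff(names(x), c("volume_factors", "pso_bounds"))
  cat("<nk_rates>\n")
  for (n in nm) cat(sprintf("  %-22s %g\n", n, x[[n]]))
  invisible(x)
}

#' Spatial-rule parameters
#'
#' Parameters governing microcluster formation (rule 15), centripetal /
#' random cluster hops (rule 16), NKG2D influx (rule 17), diffusion (rules
#' 18-19), the homogenization interval for cytosolic species, and the
#' excluded-volume capacities.
#'
#' @param model 1 or 2 (Model 3 reuses Model 2 values); selects fitted
#'   defaults for `beta`, `k_cluster_move`, `K`, `w`, `k_influx`.
#' @param l0 Chamber edge, um.
#' @param box_side_um Box side, um (sets the homogenization interval).
#' @param ... Named overrides.
#' @return Object of class `"nk_params"`.
#' @export
nk_params <- function(model = 2, l0 = 0.5, box_side_um = 15, ...) {
  model <- as.integer(model)
  if (model == 3L) model <- 2L
  stopifnot(model %in% 1:2)
  fit <- if (model == 1L) {
    list(beta = 0.013, k_cluster_move = 0.899, K = 102.086, w = 0.802,
         k_influx = 6.6e-5)
  } else {
    list(beta = 0.01, k_cluster_move = 1.157, K = 102.086, w = 1.0,
         k_influx = 0.0044)
  }
  D_cytosol <- 10
  p <- c(fit, list(
    D_membrane = 0.01, D_cytosol = D_cytosol,
    base_formation_rate = 0.01 / l0^2,   # membrane hop attempt rate
    tau_h = box_side_um^2 / (4 * D_cytosol),
    N_thres = 400L, N_NKG2D_max = 50L,
    receptors_immobile = FALSE
  ))
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$w >= 0, p$w <= 1, p$beta > 0, p$K > 0,
            p$k_cluster_move >= 0, p$k_influx >= 0, p$tau_h > 0)
  class(p) <- "nk_params"
  p
}

#' @export
print.nk_params <- function(x, ...) {
  cat("<nk_params>\n")
  for (n in names(x)) cat(sprintf("  %-20s %g\n", n, as.numeric(x[[n]])))
  invisible(x)
}

#' Write / read the full model configuration as a flat YAML file
#'
#' Serializes rates, spatial parameters, densities and geometry as one flat
#' key-value mapping (units documented in a comment header), and restores
#' them.
#'
#' @param rates,params,densities,geometry Model configuration objects.
#' @param path File path.
#' @return `read_config()` returns a list with elements `rates`, `params`,
#'   `densities`, `geometry`.
#' @export
write_config <- function(path, rates = nk_rates(), params = nk_params(),
                         densities = nk_densities(), geometry = nk_geometry()) {
  flat <- list(
    rates = unclass(rates)[setdiff(names(rates), c("volume_factors", "pso_bounds"))],
    params = lapply(unclass(params), function(v) if (is.logical(v)) v else as.numeric(v)),
    densities = unclass(densities),
    geometry = list(box_side_um = geometry$box_side_um, l0 = geometry$l0,
                    rim_width_chambers = geometry$rim_width_chambers)
  )
  header <- paste(
    "# nksynapse model configuration",
    "# units: kon_* 1/(uM s); koff_*, k*phospho*, k_cluster_move, k_influx 1/s;",
    "#        D_* um^2/s; densities molecules/um^2 (membrane) or /um^3 (cytosol);",
    "#        beta, w, ulbp3_f dimensionless; K a pVav1 copy number; lengths um.",
    sep = "\n")
  writeLines(c(header, yaml::as.yaml(flat)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- do.call(nk_geometry, y$geometry)
  rates <- do.call(nk_rates, c(list(l0 = geometry$l0), y$rates[
    setdiff(names(y$rates), "kdephos_pVav1_free")]))
  rates$kdephos_pVav1_free <- y$rates$kdephos_pVav1_free
  params <- do.call(nk_params,
                    c(list(l0 = geometry$l0, box_side_um = geometry$box_side_um),
                      y$params[setdiff(names(y$params), c("tau_h", "base_formation_rate",
                                                          "D_membrane", "D_cytosol"))]))
  params$tau_h <- y$params$tau_h
  params$base_formation_rate <- y$params$base_formation_rate
  params$D_membrane <- y$params$D_membrane
  params$D_cytosol <- y$params$D_cytosol
  densities <- do.call(nk_densities, y$densities)
  list(rates = rates, params = params, densities = densities,
       geometry = geometry)
}
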