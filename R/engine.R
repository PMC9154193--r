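#' Run a spatial kinetic Monte Carlo trajectory
#'
#' Exact event-driven stochastic simulation of all reaction and movement
#' channels: waiting times are exponential in the total propensity and events
#' are chosen proportionally to their propensities (state-dependent hop
#' directions, formation acceptance and excluded-volume checks are applied by
#' exact thinning). Cytosolic species are homogenized every `tau_h` seconds
#' of simulated time as a scheduled deterministic event. Fully reproducible
#' for a given seed.
#'
#' @param config Initial `nk_lattice` configuration.
#' @param rates [nk_rates()].
#' @param params [nk_params()].
#' @param variant [nk_variant()].
#' @param t_end End time, s.
#' @param snapshot_times Times (s) at which the full lattice and observables
#'   are recorded; clipped to `[0, t_end]`.
#' @param seed Integer RNG seed.
#' @param channels Optional `nk_channels` override (e.g. a reduced rule set);
#'   default `build_channels(rates, variant)`.
#' @param keep_snapshots Keep full lattice snapshots (else only observable
#'   series).
#' @return An `nk_trajectory`: list with `times`, `snapshots` (list of
#'   `nk_lattice`), `series` (data.frame: time, pvav1_total, central_nkg2d),
#'   `totals` (snapshots x species matrix), `events` (event counts by kind),
#'   `final` (final `nk_lattice`), `seed`, `variant`, and the engine's
#'   cached-vs-recomputed total propensity (`cached_total`,
#'   `recomputed_total`).
#' @export
run_kmc <- function(config, rates = nk_rates(), params = nk_params(),
                    variant = nk_variant(), t_end = 60,
                    snapshot_times = c(0, 30, 60, 120, 180), seed = 1L,
                    channels = NULL, keep_snapshots = TRUE) {
  stopifnot(t_end > 0)
  g <- config$geometry
  sp <- species_names()
  ns <- length(sp)
  if (is.null(channels)) channels <- build_channels(rates, variant)

  # per-direction diffusion rates by species and variant
  dmem <- diffusion_hop_rate(params$D_membrane, g$l0)
  dr <- stats::setNames(numeric(ns), sp)
  dr[c("N", "SFK", "K", "L", "H")] <- dmem
  if (variant$vav1_membrane) dr[c("Vav1", "pVav1")] <- dmem
  if (!variant$clustering) dr[paste0("C", 0:5)] <- dmem
  if (isTRUE(params$receptors_immobile))
    dr[c("N", paste0("C", 0:5))] <- 0

  m <- moiety_matrix()
  # capacity counts membrane/bilayer-layer molecules; the cytosolic pool
  # (SHP1 always, Vav1/pVav1 in Model 1) lives in the thicker layer
  is_cap <- as.integer(!(sp %in% c("SHP1",
                                   if (!variant$vav1_membrane) c("Vav1", "pVav1"))))

  snapshot_times <- sort(unique(pmin(snapshot_times, t_end)))
  central_k <- min(6L, g$nx)

  par <- list(l0 = g$l0, R = g$R,
              base_formation_rate = params$base_formation_rate,
              k_cluster_move = if (variant$clustering) params$k_cluster_move else 0,
              K = params$K, w = params$w, beta = params$beta,
              k_influx = params$k_influx, tau_h = params$tau_h,
              N_thres = as.integer(params$N_thres),
              N_NKG2D_max = as.integer(params$N_NKG2D_max),
              clustering = as.integer(variant$clustering),
              coclustering = as.integer(variant$coclustering),
              s_const1 = as.integer(!variant$pvav1_dependent_transport),
              rim_bind_rate = to_per_pair_rate(rates$kon_NKG2D_ULBP3,
                                               rates$volume_factors$v_recep_lig),
              rim_koff = rates$koff_NKG2D_ULBP3,
              vav1_index = match("Vav1", sp) - 1L,
              pvav1_index = match("pVav1", sp) - 1L,
              central_chambers = central_k)

  ri <- config$rim_index
  rim_dest <- if (nrow(ri) > 0) {
    di <- pmin(pmax(ri$i, 0L), g$nx - 1L)
    dj <- pmin(pmax(ri$j, 0L), g$ny - 1L)
    as.integer(di + g$nx * dj)
  } else integer()

  prods <- lapply(seq_along(channels$id), function(k) {
    as.integer(rep(seq_len(ns), channels$products[k, ]) - 1L)
  })
  reac_idx <- t(apply(channels$reactants, 1, function(r) {
    ix <- rep(seq_along(r), r)
    c(ix[1], if (length(ix) > 1) ix[2] else 0L)
  }))

  res <- .kmc_run(
    counts = as.integer(config$counts),
    nx = g$nx, ny = g$ny,
    rimN = as.integer(config$rim_counts[, "N"]),
    rimL = as.integer(config$rim_counts[, "L"]),
    rimC0 = as.integer(config$rim_counts[, "C0"]),
    rimDest = rim_dest,
    flags = as.integer(config$flags),
    chanRate = channels$rate,
    chanReac1 = as.integer(reac_idx[, 1] - 1L),
    chanReac2 = as.integer(reac_idx[, 2] - 1L),
    chanProds = prods,
    diffRate = unname(dr),
    isCap = is_cap,
    nkMoiety = as.integer(m[, "NKG2D"]),
    pvMoiety = as.integer(sp %in% pvav1_species()),
    clustSpecies = as.integer(match(paste0("C", 0:5), sp) - 1L),
    homogSpecies = as.integer(which(sp %in% cytosolic_free_species(variant)) - 1L),
    frozenFlagged = as.integer(sp %in% c("K", "SFKc")),
    par = par, tEnd = t_end, snapTimes = snapshot_times,
    seed = as.integer(seed), keepSnapshots = keep_snapshots)

  wrap <- function(v, time) {
    cnt <- array(v, dim = dim(config$counts), dimnames = dimnames(config$counts))
    new_lattice(g, cnt,
                cbind(N = res$rim_N, L = res$rim_L, C0 = res$rim_C0),
                ri, config$flags, time)
  }
  snaps <- if (keep_snapshots)
    lapply(seq_along(res$times),
           function(i) wrap(res$snapshots[[i]], res$times[i]))
  else list()
  totals <- res$totals
  colnames(totals) <- sp
  out <- list(
    times = res$times,
    snapshots = snaps,
    series = data.frame(time = res$times, pvav1_total = res$pvav1,
                        central_nkg2d = res$central_nkg2d),
    totals = totals,
    events = res$events,
    final = wrap(res$final_counts, t_end),
    seed = seed, variant = variant,
    cached_total = res$cached_total,
    recomputed_total = res$recomputed_total
  )
  class(out) <- "nk_trajectory"
  out
}

#' @export
print.nk_trajectory <- function(x, ...) {
  cat(sprintf("<nk_trajectory> Model %d Case %s, %d snapshots to t = %g s\n",
              x$variant$model, x$variant$case, length(x$times),
              max(x$times)))
  print(utils::tail(x$series, 3))
  cat("events:\n")
  print(x$events)
  invisible(x)
}
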