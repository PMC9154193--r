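new_lattice <- function(geometry, counts, rim_counts, rim_index, flags, time = 0) {
  stopifnot(all(counts >= 0), all(rim_counts >= 0))
  cfg <- list(geometry = geometry, counts = counts,
              rim_counts = rim_counts, rim_index = rim_index,
              flags = flags, time = time)
  class(cfg) <- "nk_lattice"
  cfg$pvav1_total <- pvav1_total(cfg)
  cfg
}

#' @export
print.nk_lattice <- function(x, ...) {
  tot <- species_totals(x)
  cat(sprintf("<nk_lattice> %d x %d chambers (+%d rim), t = %g s, pVav1 total = %d\n",
              x$geometry$nx, x$geometry$ny, nrow(x$rim_index), x$time,
              x$pvav1_total))
  print(tot[tot > 0])
  invisible(x)
}

# Rim chamber integer coordinates (0-based, in the extended frame around the
# box; box chambers span 0..nx-1).
rim_coordinates <- function(geometry) {
  w <- geometry$rim_width_chambers
  if (w == 0L) return(data.frame(i = integer(), j = integer()))
  rng <- seq.int(-w, geometry$nx + w - 1L)
  g <- expand.grid(i = rng, j = rng)
  inside <- g$i >= 0 & g$i < geometry$nx & g$j >= 0 & g$j < geometry$ny
  g[!inside, , drop = FALSE]
}

# floor + Bernoulli stochastic rounding: ensemble mean equals the target.
stochastic_round <- function(x, n) {
  base <- floor(x)
  as.integer(base + (stats::runif(n) < (x - base)))
}

#' Homogeneous initial configuration
#'
#' Populates every chamber with the deterministic integer part of the expected
#' per-chamber copy number (density x chamber area or volume) and places the
#' fractional remainder by independent seeded Bernoulli draws, so ensemble
#' means match the densities exactly. The influx rim receives free NKG2D at
#' the same areal density. ULBP3 is not placed here (see [seed_ulbp3()]).
#' Inhibitory-arm species (KIR2DL2, HLA-C) are placed only when the variant
#' enables inhibition.
#'
#' @param geometry [nk_geometry()].
#' @param densities [nk_densities()].
#' @param variant [nk_variant()].
#' @param seed Integer RNG seed.
#' @param params [nk_params()] (capacity check).
#' @return An `nk_lattice` configuration at `time = 0`.
#' @export
init_homogeneous <- function(geometry = nk_geometry(),
                             densities = nk_densities(),
                             variant = nk_variant(), seed = 1L,
                             params = nk_params(variant$model)) {
  set.seed(seed)
  sp <- species_names()
  nch <- geometry$nx * geometry$ny
  counts <- array(0L, dim = c(geometry$nx, geometry$ny, length(sp)),
                  dimnames = list(NULL, NULL, sp))
  area <- geometry$l0^2
  vol <- geometry$l0^2 * geometry$z_cytosol
  expected <- c(N = densities$NKG2D * area,
                SFK = densities$SFK * area,
                Vav1 = densities$Vav1 * vol,
                SHP1 = densities$SHP1 * vol)
  if (variant$inhibition) {
    expected <- c(expected, K = densities$KIR2DL2 * area,
                  H = densities$HLAC * area)
  }
  membrane_like <- c("N", "SFK", "K", "H", if (variant$vav1_membrane) "Vav1")
  membrane_budget <- 0
  for (s in names(expected)) {
    counts[, , s] <- stochastic_round(rep(expected[[s]], nch), nch)
    if (s %in% membrane_like)
      membrane_budget <- membrane_budget + ceiling(expected[[s]])
  }
  if (membrane_budget > params$N_thres)
    stop("chamber capacity N_thres (", params$N_thres,
         ") smaller than required initial membrane counts (", membrane_budget, ")")
  rim_index <- rim_coordinates(geometry)
  rim_counts <- matrix(0L, nrow = nrow(rim_index), ncol = 3,
                       dimnames = list(NULL, c("N", "L", "C0")))
  if (nrow(rim_index) > 0)
    rim_counts[, "N"] <- stochastic_round(
      rep(densities$NKG2D * area, nrow(rim_index)), nrow(rim_index))
  flags <- matrix(FALSE, geometry$nx, geometry$ny)
  new_lattice(geometry, counts, rim_counts, rim_index, flags)
}

#' Seed ULBP3 over box and rim chambers
#'
#' Each chamber (box and influx rim) independently receives
#' `densities$ulbp3_per_seed` free ULBP3 molecules with probability `f`.
#'
#' @param config An `nk_lattice`.
#' @param f Seeding probability in \[0, 1\].
#' @param seed RNG seed.
#' @param per_seed Molecules per seeded chamber.
#' @return Updated configuration.
#' @export
seed_ulbp3 <- function(config, f = nk_densities()$ulbp3_f, seed = 1L,
                       per_seed = 3L) {
  stopifnot(f >= 0, f <= 1)
  set.seed(seed)
  nch <- config$geometry$nx * config$geometry$ny
  config$counts[, , "L"] <- config$counts[, , "L"] +
    as.integer(stats::runif(nch) < f) * as.integer(per_seed)
  nr <- nrow(config$rim_index)
  if (nr > 0)
    config$rim_counts[, "L"] <- config$rim_counts[, "L"] +
      as.integer(stats::runif(nr) < f) * as.integer(per_seed)
  config$pvav1_total <- pvav1_total(config)
  config
}

#' Place molecules in an annulus (ring pattern)
#'
#' Distributes `total_count` molecules of one species uniformly at random over
#' the chambers whose center lies at distance `[inner_radius, outer_radius)`
#' from `ring_center`; the interior of the ring stays empty. `inner_radius =
#' 0` degenerates to a disc. Used for ring-patterned inhibitory ligands.
#'
#' @param config An `nk_lattice`.
#' @param species Species name (e.g. `"H"`, or `"K0"` for pre-formed
#'   co-localized KIR2DL2·HLA-C complexes).
#' @param ring_center Numeric (x, y) in um; default the box center.
#' @param inner_radius,outer_radius Annulus radii in um.
#' @param total_count Molecules to place.
#' @param seed RNG seed.
#' @return Updated configuration.
#' @export
place_ring <- function(config, species, ring_center = NULL,
                       inner_radius = 3, outer_radius = 7,
                       total_count = 1000L, seed = 1L) {
  g <- config$geometry
  if (is.null(ring_center)) ring_center <- c(g$R, g$R)
  stopifnot(inner_radius < outer_radius, outer_radius <= g$R + g$l0,
            total_count >= 0, species %in% species_names())
  set.seed(seed)
  cc <- chamber_centers(g)
  d <- sqrt(outer((cc$x - ring_center[1])^2, (cc$y - ring_center[2])^2, `+`))
  sel <- which(d >= inner_radius & d < outer_radius)
  if (length(sel) == 0) stop("annulus contains no chambers")
  pick <- sample(sel, total_count, replace = TRUE)
  add <- tabulate(match(pick, sel), nbins = length(sel))
  slice <- config$counts[, , species]
  slice[sel] <- slice[sel] + as.integer(add)
  config$counts[, , species] <- slice
  config$pvav1_total <- pvav1_total(config)
  config
}

#' Place a species from an intensity field and flag immobile microclusters
#'
#' Assigns `total_count` molecules proportionally to a nonnegative intensity
#' field on the chamber grid (largest-remainder apportionment, so the total is
#' exact), flags chambers whose resulting count exceeds `threshold` as
#' immobile microclusters, and converts a fraction of the free SFK pool into
#' immobile co-clustered SFK distributed over the flagged chambers
#' proportionally to the placed counts. Used to build the stationary KIR2DL2
#' microcluster layouts.
#'
#' @param config An `nk_lattice`.
#' @param species Species to place (typically `"K"`).
#' @param field Nonnegative matrix of dim `nx x ny`.
#' @param total_count Total molecules to distribute.
#' @param threshold Microcluster flagging threshold (counts). `NULL` uses
#'   mean + 2 s.d. of the nonzero placed counts.
#' @param coclustered_SFK_fraction Fraction of free SFK made immobile in the
#'   flagged chambers (0 disables).
#' @param seed RNG seed.
#' @return Updated configuration (with `flags` set).
#' @export
place_clusters_from_field <- function(config, species, field,
                                      total_count = NULL, threshold = NULL,
                                      coclustered_SFK_fraction = 0.25,
                                      seed = 1L) {
  g <- config$geometry
  if (!all(dim(field) == c(g$nx, g$ny))) stop("field shape must match the grid")
  if (any(field < 0)) stop("field must be nonnegative")
  tot_field <- sum(field)
  if (tot_field == 0) stop("all-zero field")
  set.seed(seed)
  if (is.null(total_count))
    total_count <- sum(config$counts[, , species])
  total_count <- as.integer(total_count)
  share <- as.vector(field) / tot_field * total_count
  n <- floor(share)
  rem <- total_count - sum(n)
  if (rem > 0) {
    ord <- order(share - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  placed <- matrix(as.integer(n), g$nx, g$ny)
  config$counts[, , species] <- placed
  if (is.null(threshold)) {
    nz <- placed[placed > 0]
    threshold <- if (length(nz)) mean(nz) + 2 * stats::sd(nz) else Inf
    if (is.na(threshold)) threshold <- Inf
  }
  config$flags <- placed > threshold
  if (coclustered_SFK_fraction > 0 && any(config$flags)) {
    free_sfk <- sum(config$counts[, , "SFK"])
    n_move <- as.integer(round(coclustered_SFK_fraction * free_sfk))
    wts <- placed * config$flags
    pick <- sample.int(length(wts), n_move, replace = TRUE,
                       prob = as.vector(wts))
    add <- tabulate(pick, nbins = length(wts))
    # drain free SFK uniformly across chambers
    pool <- as.vector(config$counts[, , "SFK"])
    drain <- drain_counts(pool, n_move)
    config$counts[, , "SFK"] <- matrix(as.integer(pool - drain), g$nx, g$ny)
    config$counts[, , "SFKc"] <- config$counts[, , "SFKc"] +
      matrix(as.integer(add), g$nx, g$ny)
  }
  config$pvav1_total <- pvav1_total(config)
  config
}

# remove n_move molecules from a count vector, proportionally at random
drain_counts <- function(pool, n_move) {
  if (n_move == 0 || sum(pool) == 0) return(rep(0L, length(pool)))
  n_move <- min(n_move, sum(pool))
  idx <- sample(rep.int(seq_along(pool), pool), n_move)
  tabulate(idx, nbins = length(pool))
}

#' Total pVav1 (free plus complex-bound)
#'
#' @param config An `nk_lattice`.
#' @return Integer total over `pVav1`, `C5`, `K4f`, `K4c` (box chambers).
#' @export
pvav1_total <- function(config) {
  as.integer(sum(config$counts[, , pvav1_species()]))
}

#' Per-species and conserved-moiety totals
#'
#' `species_totals()` sums every species over box and rim;
#' `conserved_totals()` maps them onto the conserved moieties (SFK, Vav1,
#' SHP1, KIR2DL2, HLA-C, ULBP3, NKG2D) which are invariant along any
#' trajectory (NKG2D/ULBP3 only grow via rim influx, and the rim is included
#' here).
#'
#' @param config An `nk_lattice`.
#' @return Named integer vector.
#' @export
species_totals <- function(config) {
  tot <- apply(config$counts, 3, sum)
  tot["N"] <- tot["N"] + sum(config$rim_counts[, "N"])
  tot["L"] <- tot["L"] + sum(config$rim_counts[, "L"])
  tot["C0"] <- tot["C0"] + sum(config$rim_counts[, "C0"])
  v <- as.integer(tot)
  names(v) <- names(tot)
  v
}

#' @rdname species_totals
#' @export
conserved_totals <- function(config) {
  tot <- species_totals(config)
  m <- moiety_matrix()
  v <- as.integer(t(m) %*% tot)
  names(v) <- colnames(m)
  v
}

#' NKG2D-moiety field on the chamber grid
#'
#' Sums all NKG2D-containing species per chamber; this is the simulated
#' counterpart of the imaged receptor intensity.
#'
#' @param config An `nk_lattice`.
#' @return Integer `nx x ny` matrix.
#' @export
nkg2d_field <- function(config) {
  f <- apply(config$counts[, , nkg2d_species(), drop = FALSE], c(1, 2), sum)
  matrix(as.integer(f), config$geometry$nx, config$geometry$ny)
}

#' Receptor count in a centered square region
#'
#' Counts NKG2D-moiety molecules in a `side_um x side_um` block centered on
#' the box (the central-accumulation observable).
#'
#' @param config An `nk_lattice`.
#' @param side_um Side of the region, an even multiple of `l0`.
#' @return Integer count.
#' @export
central_count <- function(config, side_um = 3) {
  g <- config$geometry
  k <- side_um / g$l0
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 0)
    stop("side_um must be an even multiple of l0")
  k <- as.integer(round(k))
  if (k > g$nx) stop("region exceeds the simulation box")
  lo <- g$nx / 2 - k / 2 + 1
  idx <- seq.int(lo, lo + k - 1)
  sum(nkg2d_field(config)[idx, idx])
}
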