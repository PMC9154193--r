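#' Simulation-box geometry
#'
#' The synapse is represented by a quasi-3D box of area `box_side_um` x
#' `box_side_um` discretized into square chambers of edge `l0` (membrane layer
#' thickness `l0`, cytosolic layer `2*l0`). An outer rim of thickness `2*l0`
#' (two chamber rings) surrounds the box and feeds the NKG2D influx. The box
#' corners sit at (0,0), (0,2R), (2R,0), (2R,2R) and the center at (R,R) with
#' `R = box_side_um/2`.
#'
#' @param box_side_um Side of the square simulation box in micrometers.
#' @param l0 Chamber edge in micrometers. `box_side_um` must be an integer
#'   multiple of `l0`.
#' @param rim_width_chambers Width of the influx rim, in chambers.
#' @return An object of class `"nk_geometry"`: a list with `box_side_um`,
#'   `l0`, `nx`, `ny`, `R`, `z_membrane`, `z_cytosol`, `rim_width_chambers`,
#'   and `n_rim` (number of rim chambers).
#' @examples
#' g <- nk_geometry()
#' g$nx          # 30 chambers per side
#' g$R           # 7.5 um
#' @export
nk_geometry <- function(box_side_um = 15, l0 = 0.5, rim_width_chambers = 2L) {
  stopifnot(box_side_um > 0, l0 > 0, rim_width_chambers >= 0)
  nx <- box_side_um / l0
  if (abs(nx - round(nx)) > 1e-9)
    stop("box_side_um must be an integer multiple of l0")
  nx <- as.integer(round(nx))
  w <- as.integer(rim_width_chambers)
  g <- list(box_side_um = box_side_um, l0 = l0,
            nx = nx, ny = nx,
            R = box_side_um / 2,
            z_membrane = l0, z_cytosol = 2 * l0,
            rim_width_chambers = w,
            n_rim = (nx + 2L * w)^2 - nx^2)
  class(g) <- "nk_geometry"
  g
}

#' @export
print.nk_geometry <- function(x, ...) {
  cat(sprintf("<nk_geometry> %g x %g um box, l0 = %g um (%d x %d chambers), rim %d chambers (%d rim chambers)\n",
              x$box_side_um, x$box_side_um, x$l0, x$nx, x$ny,
              x$rim_width_chambers, x$n_rim))
  invisible(x)
}

# Chamber centers: chamber (i, j), 0-based, has center ((i+0.5) l0, (j+0.5) l0).
chamber_centers <- function(geometry) {
  i <- seq_len(geometry$nx) - 1L
  j <- seq_len(geometry$ny) - 1L
  list(x = (i + 0.5) * geometry$l0, y = (j + 0.5) * geometry$l0)
}

#' Protein surface/volume densities
#'
#' Copy-number densities used to populate the lattice homogeneously. Membrane
#' and bilayer species are areal densities (molecules/um^2); cytosolic species
#' are volumetric (molecules/um^3). ULBP3 is seeded separately: each chamber
#' independently receives `ulbp3_per_seed` molecules with probability `f`.
#'
#' @param NKG2D,SFK,KIR2DL2,HLAC Areal densities (molecules/um^2).
#' @param Vav1,SHP1 Volumetric densities (molecules/um^3).
#' @param ulbp3_f Seeding probability `f` for ULBP3.
#' @param ulbp3_per_seed Molecules placed per seeded chamber.
#' @return An object of class `"nk_densities"` (named list).
#' @export
nk_densities <- function(NKG2D = 8, SFK = 698, Vav1 = 114, SHP1 = 2090,
                         KIR2DL2 = 106, HLAC = 98,
                         ulbp3_f = 3462 / 3468, ulbp3_per_seed = 3L) {
  d <- list(NKG2D = NKG2D, SFK = SFK, Vav1 = Vav1, SHP1 = SHP1,
            KIR2DL2 = KIR2DL2, HLAC = HLAC,
            ulbp3_f = ulbp3_f, ulbp3_per_seed = as.integer(ulbp3_per_seed))
  if (any(unlist(d[1:6]) < 0) || ulbp3_f < 0 || ulbp3_f > 1)
    stop("densities must be nonnegative and 0 <= ulbp3_f <= 1")
  class(d) <- "nk_densities"
  d
}

#' Model variant flags
#'
#' Selects one of the three model hypotheses and the clustering ablation:
#' * Model 1: microcluster formation and pVav1-dependent centripetal
#'   transport, no NKG2D–Vav1 co-clustering (Vav1 stays cytosolic).
#' * Model 2: as Model 1 plus membrane-proximal Vav1 co-clustered and
#'   co-transported with NKG2D complexes.
#' * Model 3: as Model 2 but centripetal transport independent of pVav1
#'   (saturation factor fixed at 1).
#' * Case A disables microcluster formation, cluster hops, and co-clustering
#'   (diffusion and influx remain); Case B is the full rule set.
#'
#' @param model 1, 2 or 3.
#' @param case `"A"` or `"B"`.
#' @param inhibition Logical; include the KIR2DL2/HLA-C inhibitory arm.
#' @return An object of class `"nk_variant"`.
#' @export
nk_variant <- function(model = 2, case = "B", inhibition = FALSE) {
  model <- as.integer(model)
  if (!model %in% 1:3) stop("unknown model variant: ", model)
  case <- toupper(as.character(case))
  if (!case %in% c("A", "B")) stop("case must be 'A' or 'B'")
  v <- list(model = model, case = case, inhibition = isTRUE(inhibition),
            # derived flags
            coclustering = model >= 2 && case == "B",
            vav1_membrane = model >= 2,
            pvav1_dependent_transport = model <= 2,
            clustering = case == "B")
  class(v) <- "nk_variant"
  v
}

#' @export
print.nk_variant <- function(x, ...) {
  cat(sprintf("<nk_variant> Model %d, Case %s, inhibitory arm %s\n",
              x$model, x$case, if (x$inhibition) "on" else "off"))
  invisible(x)
}
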