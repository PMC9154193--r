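#' Clustering potential of a chamber
#'
#' The microcluster-formation potential of chamber *i* is
#' `E_i = min(-x_i^2, -x_j1^2, ..., -x_j4^2)` over the chamber and its four
#' periodic nearest neighbors, where `x` is the local pVav1-moiety count.
#' Richer pVav1 neighborhoods have lower (more negative) potential, so
#' receptor complexes drift into them.
#'
#' @param counts Integer vector of length 5: pVav1 count at the chamber
#'   followed by its four neighbors.
#' @return The potential `E_i` (nonpositive).
#' @examples
#' chamber_potential(c(2, 1, 0, 3, 2))  # -9
#' @export
chamber_potential <- function(counts) {
  stopifnot(length(counts) == 5, all(counts >= 0))
  min(-(counts^2))
}

#' Acceptance probability of a microcluster-forming hop
#'
#' A receptor-complex hop from chamber *i* (potential `E_i`) to neighbor *j*
#' (`E_j`) is accepted with probability
#' `min(1, exp(beta (E_i - E_j)) / (1 + exp(beta (E_i - E_j))))`, a logistic
#' function that favors moves into lower-potential (pVav1-richer) chambers.
#'
#' @param E_i,E_j Potentials of source and destination.
#' @param beta Inverse-potential scale (> 0).
#' @return Probability in (0, 1\].
#' @export
formation_acceptance <- function(E_i, E_j, beta) {
  stopifnot(beta > 0)
  d <- beta * (E_i - E_j)
  # numerically stable logistic
  p <- ifelse(d > 0, 1 / (1 + exp(-d)), exp(d) / (1 + exp(d)))
  pmin(1, p)
}

#' Centripetal saturation factor
#'
#' `s = T / (K + T)` where `T` is the total pVav1 in the box: centripetal
#' transport switches on with pVav1 production and saturates at half-maximum
#' when `T = K`. With no pVav1 the centripetal component vanishes.
#'
#' @param pvav1_total Total pVav1 count `T`.
#' @param K Half-saturation count (> 0).
#' @return `s` in \[0, 1).
#' @export
saturation_s <- function(pvav1_total, K) {
  stopifnot(K > 0, pvav1_total >= 0)
  pvav1_total / (K + pvav1_total)
}

#' Directional hop probabilities for microcluster transport
#'
#' At position (x, y) with center (R, R), the hop distribution mixes a
#' centripetal component (weight `w`) with an unbiased random component
#' (weight `1 - w`):
#' `p_left  = (1 + s(x/R - 1)) w/4 + (1 - w)/4`,
#' `p_right = (1 - s(x/R - 1)) w/4 + (1 - w)/4`, and analogously for
#' down/up in y. The drift velocity components are `v_x = s w (x/R - 1)`
#' (restoring toward R), giving radial speed
#' `v_r = s w sqrt((x/R - 1)^2 + (y/R - 1)^2)` which decreases monotonically
#' from the periphery and vanishes at the center.
#'
#' @param x,y Position in um, inside `[0, 2R]`.
#' @param R Half box side, um.
#' @param s Saturation factor in \[0, 1\].
#' @param w Centripetal weight in \[0, 1\].
#' @return List with `p_left`, `p_right`, `p_down`, `p_up` (summing to 1) and
#'   the diagnostic radial speed `speed`.
#' @examples
#' centripetal_hop_probs(7.5/2, 7.5, 1, 1, R = 7.5)
#' @export
centripetal_hop_probs <- function(x, y, s, w, R) {
  if (x < 0 || x > 2 * R || y < 0 || y > 2 * R)
    stop("position outside the simulation box")
  stopifnot(s >= 0, s <= 1, w >= 0, w <= 1)
  gx <- s * (x / R - 1)
  gy <- s * (y / R - 1)
  list(p_left  = 0.25 * (1 + gx) * w + 0.25 * (1 - w),
       p_right = 0.25 * (1 - gx) * w + 0.25 * (1 - w),
       p_down  = 0.25 * (1 + gy) * w + 0.25 * (1 - w),
       p_up    = 0.25 * (1 - gy) * w + 0.25 * (1 - w),
       speed   = s * w * sqrt((x / R - 1)^2 + (y / R - 1)^2))
}

#' Excluded-volume admissibility of a move
#'
#' A hop is admitted iff the destination's membrane-layer total would stay at
#' or below `N_thres` and its NKG2D-moiety total at or below `N_NKG2D_max`.
#' Cytosolic free molecules occupy the thicker cytosolic layer and do not
#' count toward the membrane capacity.
#'
#' @param dest_total Current membrane-layer molecule count at the destination.
#' @param dest_nkg2d Current NKG2D-moiety count at the destination.
#' @param count_moved Membrane-layer molecules arriving.
#' @param nkg2d_moved NKG2D moieties arriving.
#' @param params [nk_params()].
#' @return Logical.
#' @export
excluded_volume_ok <- function(dest_total, dest_nkg2d, count_moved,
                               nkg2d_moved = 0L, params = nk_params()) {
  dest_total + count_moved <= params$N_thres &&
    dest_nkg2d + nkg2d_moved <= params$N_NKG2D_max
}

#' Homogenize cytosolic species
#'
#' Fast cytosolic diffusion is approximated by redistributing each cytosolic
#' free species' total equally over all box chambers at intervals `tau_h`,
#' with the integer remainder assigned to chambers chosen uniformly at
#' random. Totals are conserved exactly. Which species are cytosolic depends
#' on the variant (Vav1/pVav1 are membrane-proximal in Models 2-3).
#'
#' @param config An `nk_lattice`.
#' @param variant [nk_variant()].
#' @param seed RNG seed for the remainder placement.
#' @return Updated configuration.
#' @export
homogenize_cytosolic <- function(config, variant = nk_variant(1), seed = 1L) {
  set.seed(seed)
  sp <- cytosolic_free_species(variant)
  nch <- config$geometry$nx * config$geometry$ny
  for (s in sp) {
    tot <- sum(config$counts[, , s])
    base <- tot %/% nch
    rem <- tot %% nch
    slice <- rep(as.integer(base), nch)
    if (rem > 0) {
      extra <- sample.int(nch, rem)
      slice[extra] <- slice[extra] + 1L
    }
    config$counts[, , s] <- matrix(slice, config$geometry$nx,
                                   config$geometry$ny)
  }
  config$pvav1_total <- pvav1_total(config)
  config
}

cytosolic_free_species <- function(variant) {
  if (variant$vav1_membrane) "SHP1" else c("SHP1", "Vav1", "pVav1")
}

#' Per-direction diffusive hop rate
#'
#' Free molecules hop to each of the four nearest neighbors at rate
#' `D / l0^2`, giving a total hop rate `4 D / l0^2` and lattice mean-squared
#' displacement `4 D t`.
#'
#' @param D Diffusion constant, um^2/s.
#' @param l0 Chamber edge, um.
#' @return Rate in 1/s per molecule per direction.
#' @export
diffusion_hop_rate <- function(D, l0 = 0.5) D / l0^2
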