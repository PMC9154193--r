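#' Generate a synthetic clustered intensity field
#'
#' Produces a fitting target emulating a coarse-grained TIRF image of
#' clustered receptors: a sum of Gaussian bumps over a uniform background
#' plus truncated Gaussian noise, normalized to \[0, 1\]. Cluster centers are
#' drawn uniformly, optionally biased toward the box center
#' (`radial_bias` = fraction of clusters drawn from the central half-box).
#' Deterministic for a given seed.
#'
#' @param n_clusters Number of Gaussian clusters.
#' @param amplitude Peak amplitude of each cluster (arbitrary units).
#' @param radius_chambers Gaussian s.d. of a cluster, in chambers.
#' @param background Uniform background level.
#' @param noise_sd S.d. of additive noise (negative values truncated to 0).
#' @param radial_bias Fraction of clusters placed in the central half of the
#'   box.
#' @param geometry [nk_geometry()].
#' @param seed RNG seed.
#' @return Normalized `nk_field` matrix (`nx x ny`).
#' @export
generate_synthetic_target <- function(n_clusters = 12, amplitude = 1,
                                      radius_chambers = 1.5,
                                      background = 0.05, noise_sd = 0.02,
                                      radial_bias = 0.5,
                                      geometry = nk_geometry(), seed = 1L) {
  stopifnot(n_clusters >= 0, amplitude > 0, radius_chambers > 0,
            background >= 0, noise_sd >= 0, radial_bias >= 0,
            radial_bias <= 1)
  set.seed(seed)
  nx <- geometry$nx; ny <- geometry$ny
  field <- matrix(background, nx, ny)
  if (n_clusters > 0) {
    central <- stats::runif(n_clusters) < radial_bias
    cx <- ifelse(central, stats::runif(n_clusters, nx / 4, 3 * nx / 4),
                 stats::runif(n_clusters, 1, nx))
    cy <- ifelse(central, stats::runif(n_clusters, ny / 4, 3 * ny / 4),
                 stats::runif(n_clusters, 1, ny))
    ix <- seq_len(nx); iy <- seq_len(ny)
    for (q in seq_len(n_clusters)) {
      bump <- amplitude * exp(-(outer((ix - cx[q])^2, (iy - cy[q])^2, `+`)) /
                                (2 * radius_chambers^2))
      field <- field + bump
    }
  }
  if (noise_sd > 0)
    field <- pmax(field + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny), 0)
  normalize_field(field)
}
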