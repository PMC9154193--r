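#' Normalize an intensity or count field
#'
#' Divides a nonnegative field (TIRF intensity or simulated per-chamber
#' receptor counts) by its maximum, so simulation and imaging enter the cost
#' on the same dimensionless scale. An identically zero field maps to itself
#' and is flagged.
#'
#' @param raw_field Nonnegative numeric matrix.
#' @return Object of class `"nk_field"`: the normalized matrix with
#'   attributes `zero` (logical) and `source`.
#' @export
normalize_field <- function(raw_field) {
  raw_field <- as.matrix(raw_field)
  if (any(raw_field < 0)) stop("field must be nonnegative")
  mx <- max(raw_field)
  S <- if (mx > 0) raw_field / mx else raw_field
  structure(S, zero = (mx == 0), class = c("nk_field", class(S)))
}

#' Mean and variance of a normalized field
#'
#' Population conventions over the `N_chamber` chambers:
#' `mu = mean(S)` and `sigma2 = mean((S - mu)^2)`.
#'
#' @param S Numeric matrix (normalized field).
#' @return List with `mu` and `sigma2`.
#' @export
summary_stats <- function(S) {
  mu <- mean(S)
  list(mu = mu, sigma2 = mean((S - mu)^2))
}

#' Periodic two-point correlation function
#'
#' For a field on a square chamber grid,
#' `C(r) = (1/N_chamber) * sum_i sum_{(rx,ry): rx^2+ry^2 = r^2}
#' (S_i - mu)(S_{i+(rx,ry)} - mu)` with periodic wrap, evaluated at every
#' achievable lattice separation `r = l0 * sqrt(rx^2 + ry^2) <= L/2`. As
#' printed, the per-`r` sum is **not** divided by the number of displacement
#' vectors at that separation; set `normalize_multiplicity = TRUE` for the
#' per-pair-averaged variant. `C(0)` equals the field variance.
#'
#' @param S Numeric matrix, square.
#' @param l0 Chamber edge (um), used only to express `r` in physical units.
#' @param normalize_multiplicity Divide each `C(r)` by the number of
#'   displacement vectors at that `r`.
#' @return data.frame with columns `r` (um), `C`, `C_over_C0`,
#'   `multiplicity`.
#' @export
two_point_correlation <- function(S, l0 = 0.5, normalize_multiplicity = FALSE) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n) stop("two_point_correlation requires a square grid")
  mu <- mean(S)
  D <- S - mu
  half <- floor(n / 2)
  lo <- -half + (1 - n %% 2)  # unique displacements modulo the period
  shifts <- expand.grid(rx = lo:half, ry = lo:half)
  r2 <- shifts$rx^2 + shifts$ry^2
  keep <- sqrt(r2) <= n / 2 + 1e-12
  shifts <- shifts[keep, ]
  r2 <- r2[keep]
  cov_d <- vapply(seq_len(nrow(shifts)), function(q) {
    rx <- shifts$rx[q]; ry <- shifts$ry[q]
    ii <- ((seq_len(n) - 1 + rx) %% n) + 1
    jj <- ((seq_len(n) - 1 + ry) %% n) + 1
    sum(D * D[ii, jj])
  }, 0)
  agg <- rowsum(cbind(cov = cov_d, mult = 1), group = r2)
  r2u <- as.numeric(rownames(agg))
  C <- agg[, "cov"] / (n * n)
  if (normalize_multiplicity) C <- C / agg[, "mult"]
  out <- data.frame(r = l0 * sqrt(r2u), C = C,
                    multiplicity = as.integer(agg[, "mult"]))
  out$C_over_C0 <- if (out$C[1] != 0) out$C / out$C[1] else NA_real_
  out[order(out$r), c("r", "C", "C_over_C0", "multiplicity")]
}

#' Spatial statistics bundle of a field
#'
#' Convenience wrapper returning the mean, variance, and correlation table of
#' a normalized field, the triple entering the fitting cost.
#'
#' @param S Numeric matrix (normalized field).
#' @param l0 Chamber edge, um.
#' @return List `mu`, `sigma2`, `correlation` (data.frame).
#' @export
spatial_statistics <- function(S, l0 = 0.5) {
  ss <- summary_stats(S)
  list(mu = ss$mu, sigma2 = ss$sigma2,
       correlation = two_point_correlation(S, l0))
}

#' Block-average a fine image to the chamber grid
#'
#' Coarse-grains a fine-pixel intensity field to the simulation resolution
#' `l0` by averaging the pixels falling in each chamber. If `l0` is not an
#' integer multiple of the fine pixel size the field is first bilinearly
#' resampled to the nearest conforming resolution.
#'
#' @param fine_field Numeric matrix.
#' @param fine_pixel_size Pixel edge of `fine_field`, um.
#' @param l0 Target chamber edge, um.
#' @return Coarse matrix with pixel size `l0`.
#' @export
coarse_grain <- function(fine_field, fine_pixel_size, l0 = 0.5) {
  fine_field <- as.matrix(fine_field)
  if (length(fine_field) == 0) stop("empty field")
  k <- l0 / fine_pixel_size
  if (abs(k - round(k)) > 1e-9) {
    k <- max(1L, round(k))
    target <- round(dim(fine_field) * fine_pixel_size / (l0 / k))
    fine_field <- bilinear_resample(fine_field, target[1], target[2])
  }
  k <- as.integer(round(k))
  nxc <- nrow(fine_field) %/% k
  nyc <- ncol(fine_field) %/% k
  if (nxc == 0 || nyc == 0) stop("field smaller than one chamber")
  ff <- fine_field[seq_len(nxc * k), seq_len(nyc * k), drop = FALSE]
  # average k x k blocks
  m <- matrix(0, nxc, nyc)
  for (a in seq_len(k)) for (b in seq_len(k))
    m <- m + ff[seq(a, by = k, length.out = nxc),
                seq(b, by = k, length.out = nyc)]
  m / (k * k)
}

bilinear_resample <- function(m, nr, nc) {
  xi <- seq(1, nrow(m), length.out = nr)
  yi <- seq(1, ncol(m), length.out = nc)
  x0 <- pmin(floor(xi), nrow(m) - 1); fx <- xi - x0
  y0 <- pmin(floor(yi), ncol(m) - 1); fy <- yi - y0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    c0 <- m[, y0[j]] * (1 - fy[j]) + m[, y0[j] + 1] * fy[j]
    out[, j] <- c0[x0] * (1 - fx) + c0[x0 + 1] * fx
  }
  out
}
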