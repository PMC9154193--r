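# Shared fixtures: small geometries and quiet parameter sets for fast tests.

tiny_geometry <- function(side = 3, l0 = 0.5) {
  nk_geometry(box_side_um = side, l0 = l0, rim_width_chambers = 0L)
}

# parameters with the scheduled homogenization pushed beyond the horizon and
# influx off, for toy configurations that have no cytosolic species
quiet_params <- function(model = 1, l0 = 0.5, side = 15, ...) {
  nk_params(model, l0 = l0, box_side_um = side, k_influx = 0,
            tau_h = 1e9, ...)
}

empty_densities <- function() {
  nk_densities(NKG2D = 0, SFK = 0, Vav1 = 0, SHP1 = 0, KIR2DL2 = 0,
               HLAC = 0, ulbp3_f = 0)
}

# place n molecules of one species in chamber (i, j) (1-based)
put <- function(config, species, i, j, n) {
  config$counts[i, j, species] <- config$counts[i, j, species] + as.integer(n)
  config$pvav1_total <- pvav1_total(config)
  config
}

# zero every channel rate except the named ones
only_channels <- function(channels, keep) {
  channels$rate[!channels$id %in% keep] <- 0
  channels
}

# independent brute-force periodic two-point correlation (direct loops)
brute_force_correlation <- function(S, l0 = 0.5) {
  n <- nrow(S)
  mu <- mean(S)
  half <- floor(n / 2)
  lo <- -half + (1 - n %% 2)
  acc <- list()
  for (rx in lo:half) for (ry in lo:half) {
    r2 <- rx^2 + ry^2
    if (sqrt(r2) > n / 2 + 1e-12) next
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ii <- ((i - 1 + rx) %% n) + 1
      jj <- ((j - 1 + ry) %% n) + 1
      tot <- tot + (S[i, j] - mu) * (S[ii, jj] - mu)
    }
    key <- as.character(r2)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + tot
  }
  r2u <- as.numeric(names(acc))
  ord <- order(r2u)
  data.frame(r = l0 * sqrt(r2u[ord]), C = unlist(acc)[ord] / n^2,
             row.names = NULL)
}
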