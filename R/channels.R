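#' Build the chamber-local reaction channels
#'
#' Expands the biochemical rule set into elementary stochastic channels with
#' unit-correct per-pair rates. Binding propensities are
#' `k_on/(N_A v) * n_x * n_y` with the volume factor `v` appropriate to the
#' encounter; unary channels are `k * n_x`. Ligand unbinding implements
#' kinetic proofreading: it fully dissociates the complex, resetting the
#' receptor to its unphosphorylated state and releasing partners (released
#' Vav1 keeps its phospho-state, so a `C5` dissociation yields free pVav1).
#' Catalysis releases the enzyme (e.g. `C1 -> C2 + SFK`). Immobile
#' co-clustered SFK (`SFKc`) binds through twin channels at the same rate.
#' Inhibitory channels are emitted only when the variant enables the
#' KIR2DL2 arm. In Models 2-3 the membrane-proximal Vav1/pVav1 pool binds
#' through the plasma-membrane volume factor `l0^3`.
#'
#' @param rates [nk_rates()].
#' @param variant [nk_variant()].
#' @return An object of class `"nk_channels"`: list with `id` (channel
#'   names), `rate` (per-pair or unary rates, 1/s), and integer stoichiometry
#'   matrices `reactants` and `products` (channels x species).
#' @export
build_channels <- function(rates = nk_rates(), variant = nk_variant()) {
  sp <- species_names()
  vf <- rates$volume_factors
  v_vav <- if (variant$vav1_membrane) vf$v_Vav1_plasma else vf$v_cytosol
  pair <- function(k, v) to_per_pair_rate(k, v)

  ch <- list()
  add <- function(id, rate, from, to) {
    r <- integer(length(sp)); names(r) <- sp
    p <- r
    for (s in from) r[s] <- r[s] + 1L
    for (s in to) p[s] <- p[s] + 1L
    ch[[length(ch) + 1L]] <<- list(id = id, rate = rate, reac = r, prod = p)
  }

  add("r1f", pair(rates$kon_NKG2D_ULBP3, vf$v_recep_lig), c("N", "L"), "C0")
  koff1 <- rates$koff_NKG2D_ULBP3
  add("r1b_C0", koff1, "C0", c("N", "L"))
  add("r1b_C1", koff1, "C1", c("N", "L", "SFK"))
  add("r1b_C2", koff1, "C2", c("N", "L"))
  add("r1b_C3", koff1, "C3", c("N", "L", "Vav1"))
  add("r1b_C4", koff1, "C4", c("N", "L", "Vav1", "SFK"))
  add("r1b_C5", koff1, "C5", c("N", "L", "pVav1"))
  add("r2f", pair(rates$kon_DAP10_SFK, vf$v_recep_SFK), c("C0", "SFK"), "C1")
  add("r2f_c", pair(rates$kon_DAP10_SFK, vf$v_recep_SFK), c("C0", "SFKc"), "C1")
  add("r2b", rates$koff_DAP10_SFK, "C1", c("C0", "SFK"))
  add("r3", rates$kphos_DAP10, "C1", c("C2", "SFK"))
  add("r4f", pair(rates$kon_pDAP10_Vav1, v_vav), c("C2", "Vav1"), "C3")
  add("r4b", rates$koff_pDAP10_Vav1, "C3", c("C2", "Vav1"))
  add("r6f", pair(rates$kon_pDAP10_Vav1_SFK, vf$v_recep_SFK),
      c("C3", "SFK"), "C4")
  add("r6f_c", pair(rates$kon_pDAP10_Vav1_SFK, vf$v_recep_SFK),
      c("C3", "SFKc"), "C4")
  add("r6b", rates$koff_pDAP10_Vav1_SFK, "C4", c("C3", "SFK"))
  add("r5", rates$kphos_Vav1, "C4", c("C5", "SFK"))
  add("r7", rates$kdephos_pDAP10, "C2", "C0")
  add("r8", rates$kdephos_pVav1, "C5", "C3")
  add("rp", rates$kdephos_pVav1_free, "pVav1", "Vav1")

  if (variant$inhibition) {
    add("r9f", pair(rates$kon_KIR_HLAC, vf$v_recep_lig), c("K", "H"), "K0")
    koff9 <- rates$koff_KIR_HLAC
    add("r9b_K0", koff9, "K0", c("K", "H"))
    add("r9b_K1", koff9, "K1", c("K", "H", "SFK"))
    add("r9b_K2", koff9, "K2", c("K", "H"))
    add("r9b_K3", koff9, "K3", c("K", "H", "SHP1"))
    add("r9b_K4f", koff9, "K4f", c("K", "H", "SHP1", "pVav1"))
    add("r9b_K4c", koff9, "K4c", c("K", "H", "SHP1", "C5"))
    # ULBP3 unbinding from the receptor complex inside the ternary keeps the
    # SHP1-pVav1 bond
    add("r1b_K4c", koff1, "K4c", c("K4f", "N", "L"))
    add("r10f", pair(rates$kon_DAP10_SFK, vf$v_recep_SFK), c("K0", "SFK"), "K1")
    add("r10f_c", pair(rates$kon_DAP10_SFK, vf$v_recep_SFK),
        c("K0", "SFKc"), "K1")
    add("r10b", rates$koff_DAP10_SFK, "K1", c("K0", "SFK"))
    add("r11", rates$kphos_DAP10, "K1", c("K2", "SFK"))
    add("r12f", pair(rates$kon_pITIM_SHP1, vf$v_cytosol), c("K2", "SHP1"), "K3")
    add("r12b", rates$koff_pITIM_SHP1, "K3", c("K2", "SHP1"))
    add("r13f_f", pair(rates$kon_SHP1_pVav1, v_vav), c("K3", "pVav1"), "K4f")
    add("r13b_f", rates$koff_SHP1_pVav1, "K4f", c("K3", "pVav1"))
    add("r13f_c", pair(rates$kon_SHP1_pVav1, vf$v_recep_SFK),
        c("K3", "C5"), "K4c")
    add("r13b_c", rates$koff_SHP1_pVav1, "K4c", c("K3", "C5"))
    add("r14f", rates$kdephos_SHP1_pVav1, "K4f", c("K3", "Vav1"))
    add("r14c", rates$kdephos_SHP1_pVav1, "K4c", c("K3", "C3"))
  }

  out <- list(
    id = vapply(ch, `[[`, "", "id"),
    rate = vapply(ch, `[[`, 0, "rate"),
    reactants = do.call(rbind, lapply(ch, `[[`, "reac")),
    products = do.call(rbind, lapply(ch, `[[`, "prod"))
  )
  rownames(out$reactants) <- rownames(out$products) <- out$id
  class(out) <- "nk_channels"
  out
}

#' @export
print.nk_channels <- function(x, ...) {
  cat(sprintf("<nk_channels> %d channels\n", length(x$id)))
  sp <- colnames(x$reactants)
  for (k in seq_along(x$id)) {
    lhs <- rep(sp, x$reactants[k, ])
    rhs <- rep(sp, x$products[k, ])
    cat(sprintf("  %-8s %s -> %s   (%.4g /s)\n", x$id[k],
                paste(lhs, collapse = " + "),
                if (length(rhs)) paste(rhs, collapse = " + ") else "0",
                x$rate[k]))
  }
  invisible(x)
}

#' Propensity of one channel in one chamber
#'
#' @param channels An `nk_channels` table.
#' @param k Channel index.
#' @param n Named species count vector for the chamber.
#' @return Propensity in 1/s.
#' @export
channel_propensity <- function(channels, k, n) {
  channels$rate[k] * prod(n[colnames(channels$reactants)]^channels$reactants[k, ])
}

#' Apply one reaction channel to one chamber
#'
#' Reference (non-performance) state update: decrements reactants, increments
#' products. Errors if a reactant is absent, which would signal a propensity
#' bookkeeping bug in a caller.
#'
#' @param config An `nk_lattice`.
#' @param chamber Integer `c(i, j)`, 1-based.
#' @param channels An `nk_channels` table.
#' @param k Channel index or id.
#' @return Updated configuration (with `pvav1_total` cache refreshed).
#' @export
apply_reaction <- function(config, chamber, channels, k) {
  if (is.character(k)) k <- match(k, channels$id)
  i <- chamber[1]; j <- chamber[2]
  n <- config$counts[i, j, ]
  if (any(n < channels$reactants[k, ]))
    stop("reactant absent in chamber: propensity bookkeeping error")
  config$counts[i, j, ] <- n - channels$reactants[k, ] + channels$products[k, ]
  config$pvav1_total <- pvav1_total(config)
  config
}
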