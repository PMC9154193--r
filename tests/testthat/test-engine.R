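# helpers to build toy configurations ---------------------------------------

toy_channels <- function(keep, rates = nk_rates(1), variant = nk_variant(1, "A")) {
  only_channels(build_channels(rates, variant), keep)
}

test_that("trajectories are reproducible and empty lattices stay empty", {
  g <- nk_geometry(box_side_um = 5)
  densities <- nk_densities(ulbp3_f = 0.5)
  variant <- nk_variant(2)
  mk <- function(seed) {
    cfg <- init_homogeneous(g, densities, variant, seed = 3,
                            params = nk_params(2, box_side_um = 5))
    cfg <- seed_ulbp3(cfg, 0.5, seed = 4)
    run_kmc(cfg, nk_rates(2), nk_params(2, box_side_um = 5), variant,
            t_end = 3, snapshot_times = c(0, 3), seed = seed,
            keep_snapshots = FALSE)
  }
  a <- mk(11); b <- mk(11); c3 <- mk(12)
  expect_identical(a$final$counts, b$final$counts)
  expect_identical(a$series, b$series)
  expect_false(identical(a$final$counts, c3$final$counts))

  empty <- init_homogeneous(tiny_geometry(2), empty_densities(), nk_variant(1))
  tr <- run_kmc(empty, nk_rates(1), quiet_params(), nk_variant(1),
                t_end = 5, snapshot_times = c(0, 2.5, 5), seed = 1)
  expect_true(all(vapply(tr$snapshots, function(s) sum(s$counts), 0) == 0))
  expect_equal(tr$times, c(0, 2.5, 5))
})

test_that("cached propensity totals agree with full recomputation", {
  cfg <- seed_ulbp3(init_homogeneous(nk_geometry(box_side_um = 5),
                                     nk_densities(), nk_variant(2), seed = 6,
                                     params = nk_params(2, box_side_um = 5)),
                    0.9, seed = 7)
  tr <- run_kmc(cfg, nk_rates(2), nk_params(2, box_side_um = 5),
                nk_variant(2), t_end = 10, snapshot_times = 10, seed = 8,
                keep_snapshots = FALSE)
  expect_equal(tr$cached_total, tr$recomputed_total,
               tolerance = 1e-9)
})

test_that("conserved moieties are invariant along a full-model trajectory", {
  g <- nk_geometry(box_side_um = 6, rim_width_chambers = 0L)
  cfg <- init_homogeneous(g, nk_densities(), nk_variant(2, inhibition = TRUE),
                          seed = 9, params = nk_params(2, box_side_um = 6))
  cfg <- seed_ulbp3(cfg, 0.9, seed = 10)
  tr <- run_kmc(cfg, nk_rates(2), nk_params(2, box_side_um = 6,
                                            k_influx = 0),
                nk_variant(2, inhibition = TRUE), t_end = 20,
                snapshot_times = c(0, 10, 20), seed = 11)
  ref <- conserved_totals(cfg)
  for (s in tr$snapshots)
    expect_identical(conserved_totals(s), ref)
})

test_that("competing unary channels fire proportionally to their rates", {
  g <- tiny_geometry(0.5)  # single chamber
  cfg <- init_homogeneous(g, empty_densities(), nk_variant(1))
  cfg <- put(cfg, "C0", 1, 1, 3000)
  cfg <- put(cfg, "pVav1", 1, 1, 3000)
  k <- 0.01
  ch <- toy_channels(c("r1b_C0", "rp"),
                     nk_rates(1, koff_NKG2D_ULBP3 = k,
                              kdephos_pVav1_free = 3 * k))
  tr <- run_kmc(cfg, nk_rates(1), quiet_params(D_membrane = 0),
                nk_variant(1, "A"), t_end = 5, snapshot_times = 5,
                seed = 13, channels = ch, keep_snapshots = FALSE)
  d_slow <- 3000 - tr$totals[1, "C0"]
  d_fast <- 3000 - tr$totals[1, "pVav1"]
  n <- d_slow + d_fast
  phat <- d_fast / n
  p <- (3 * (1 - exp(-3 * k * 5)) / 3) /
    ((1 - exp(-3 * k * 5)) + (1 - exp(-k * 5)))  # per-event share
  expect_gt(n, 300)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a closed binding pair relaxes to the K_D equilibrium", {
  g <- tiny_geometry(0.5)
  cfg <- init_homogeneous(g, empty_densities(), nk_variant(1))
  cfg <- put(cfg, "N", 1, 1, 1000)
  cfg <- put(cfg, "L", 1, 1, 1000)
  kon <- 6.02e-4
  rates <- nk_rates(1, kon_NKG2D_ULBP3 = kon, koff_NKG2D_ULBP3 = 1)
  kb <- to_per_pair_rate(kon, rates$volume_factors$v_recep_lig)
  ch <- toy_channels(c("r1f", "r1b_C0"), rates)
  tr <- run_kmc(cfg, rates, quiet_params(D_membrane = 0), nk_variant(1, "A"),
                t_end = 200, snapshot_times = seq(5, 200, 0.5), seed = 17,
                channels = ch, keep_snapshots = FALSE)
  n_eq <- mean(tr$totals[, "C0"])
  # deterministic equilibrium: kb (1000-n)^2 = koff n
  n_star <- uniroot(function(n) kb * (1000 - n)^2 - n, c(0, 1000))$root
  expect_lt(abs(n_eq - n_star) / n_star, 0.01)
})

test_that("spontaneous complex decay is exponential at rate k_off", {
  g <- tiny_geometry(0.5)
  cfg <- put(init_homogeneous(g, empty_densities(), nk_variant(1)),
             "C0", 1, 1, 2000)
  ch <- toy_channels("r1b_C0", nk_rates(1, koff_NKG2D_ULBP3 = 0.1))
  tr <- run_kmc(cfg, nk_rates(1), quiet_params(D_membrane = 0),
                nk_variant(1, "A"), t_end = 30,
                snapshot_times = seq(0, 30, 2), seed = 19, channels = ch,
                keep_snapshots = FALSE)
  surv <- tr$totals[, "C0"] / 2000
  expect_true(all(abs(surv - exp(-0.1 * tr$times)) < 0.05))
  fit <- stats::lm(log(pmax(surv, 1e-6)) ~ tr$times)
  expect_equal(-unname(coef(fit)[2]), 0.1, tolerance = 0.05)
})

test_that("toy lattice occupancy matches the chemical master equation", {
  # one N and one L molecule on a periodic 2x2 grid with reversible binding
  # and hopping: 16 unbound states (N position x L position) + 4 bound.
  g <- nk_geometry(box_side_um = 1, rim_width_chambers = 0L)
  kon <- 1.806  # per-pair binding rate ~6/s over the receptor-ligand volume
  koff <- 3
  rates <- nk_rates(1, kon_NKG2D_ULBP3 = kon, koff_NKG2D_ULBP3 = koff)
  kb <- to_per_pair_rate(kon, rates$volume_factors$v_recep_lig)
  hop <- 5  # per-direction rate: D = 1.25 um^2/s
  ch <- toy_channels(c("r1f", "r1b_C0"), rates)
  cfg <- put(put(init_homogeneous(g, empty_densities(), nk_variant(1)),
                 "N", 1, 1, 1), "L", 2, 2, 1)
  tr <- run_kmc(cfg, rates, quiet_params(D_membrane = hop * g$l0^2),
                nk_variant(1, "A"), t_end = 30000,
                snapshot_times = seq(10, 30000, 0.5), seed = 23,
                channels = ch, keep_snapshots = TRUE)
  code <- vapply(tr$snapshots, function(s) {
    cc <- which(s$counts[, , "C0"] > 0)
    if (length(cc)) return(16 + cc)
    (which(s$counts[, , "N"] > 0) - 1) * 4 + which(s$counts[, , "L"] > 0)
  }, 0)
  emp <- tabulate(code, nbins = 20) / length(code)
  # dense generator; hop_to lists the 4 directional destinations (periodic
  # 2x2: left/right flip i, up/down flip j)
  hop_to <- function(c0) {
    i <- (c0 - 1) %% 2; j <- (c0 - 1) %/% 2
    rep(c((1 - i) + 2 * j + 1, i + 2 * (1 - j) + 1), each = 2)
  }
  Q <- matrix(0, 20, 20)
  for (np in 1:4) for (lp in 1:4) {
    s <- (np - 1) * 4 + lp
    for (d in hop_to(np)) Q[s, (d - 1) * 4 + lp] <- Q[s, (d - 1) * 4 + lp] + hop
    for (d in hop_to(lp)) Q[s, (np - 1) * 4 + d] <- Q[s, (np - 1) * 4 + d] + hop
    if (np == lp) Q[s, 16 + np] <- Q[s, 16 + np] + kb
  }
  for (cp in 1:4) {
    s <- 16 + cp
    Q[s, (cp - 1) * 4 + cp] <- Q[s, (cp - 1) * 4 + cp] + koff
    for (d in hop_to(cp)) Q[s, 16 + d] <- Q[s, 16 + d] + hop
  }
  diag(Q) <- -rowSums(Q)
  ev <- eigen(t(Q))
  ns <- Re(ev$vectors[, which.min(abs(ev$values))])
  pi_st <- ns / sum(ns)
  tv <- 0.5 * sum(abs(emp - pi_st))
  expect_lt(tv, 0.01)
})

test_that("free diffusion reproduces the 4Dt mean-squared displacement", {
  g <- nk_geometry(rim_width_chambers = 0L)
  msd_at <- function(tq) {
    tot <- 0; n <- 0
    for (seed in 1:3) {
      cfg <- put(init_homogeneous(g, empty_densities(), nk_variant(1)),
                 "N", 15, 15, 5000)
      tr <- run_kmc(cfg, nk_rates(1), quiet_params(
        N_thres = 1000000L, N_NKG2D_max = 1000000L),
        nk_variant(1, "A"), t_end = tq, snapshot_times = tq,
        seed = 30 + seed, channels = toy_channels(character(0)))
      f <- tr$snapshots[[1]]$counts[, , "N"]
      idx <- which(f > 0, arr.ind = TRUE)
      di <- (idx[, 1] - 15); dj <- (idx[, 2] - 15)
      di <- ifelse(di > 15, di - 30, ifelse(di < -15, di + 30, di))
      dj <- ifelse(dj > 15, dj - 30, ifelse(dj < -15, dj + 30, dj))
      tot <- tot + sum(f[idx] * (di^2 + dj^2) * g$l0^2)
      n <- n + sum(f[idx])
    }
    tot / n
  }
  for (tq in c(50, 100)) {
    expect_lt(abs(msd_at(tq) - 4 * 0.01 * tq) / (4 * 0.01 * tq), 0.05,
              label = sprintf("MSD at t = %g s within 5%%", tq))
  }
})

test_that("a lone microcluster drifts centripetally at full weight", {
  g <- nk_geometry(rim_width_chambers = 0L)
  params <- quiet_params(2, base_formation_rate = 0, D_membrane = 0,
                         w = 1)
  times <- seq(0, 20, 5)
  dist_t <- matrix(NA_real_, 200, length(times))
  for (rep_i in 1:200) {
    cfg <- put(init_homogeneous(g, empty_densities(), nk_variant(3)),
               "C0", 5, 5, 1)
    tr <- run_kmc(cfg, nk_rates(2), params, nk_variant(3), t_end = 20,
                  snapshot_times = times, seed = 400 + rep_i,
                  channels = toy_channels(character(0), nk_rates(2),
                                          nk_variant(3)))
    dist_t[rep_i, ] <- vapply(tr$snapshots, function(s) {
      ij <- which(s$counts[, , "C0"] > 0, arr.ind = TRUE)
      sqrt(sum(((ij[1, ] - 0.5) * g$l0 - g$R)^2))
    }, 0)
  }
  md <- colMeans(dist_t)
  expect_true(all(diff(md) < 0))
  # immobile K-species stay put: flagged chambers keep their KIR2DL2
  cfgK <- put(init_homogeneous(g, empty_densities(),
                               nk_variant(2, inhibition = TRUE)),
              "K", 10, 10, 30)
  cfgK$flags[10, 10] <- TRUE
  trK <- run_kmc(cfgK, nk_rates(2), quiet_params(2),
                 nk_variant(2, inhibition = TRUE), t_end = 10,
                 snapshot_times = 10, seed = 5)
  expect_equal(unname(trK$snapshots[[1]]$counts[10, 10, "K"]), 30L)
})
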