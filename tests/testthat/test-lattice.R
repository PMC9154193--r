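test_that("homogeneous initialization matches the stated densities", {
  g <- nk_geometry()
  cfg <- init_homogeneous(g, nk_densities(), nk_variant(1), seed = 5)
  # 8 molecules/um^2 over a (0.5 um)^2 chamber is exactly 2 per chamber
  expect_true(all(cfg$counts[, , "N"] == 2L))
  # fractional expectations: Vav1 at 114/um^3 in a 0.25 um^3 chamber
  v <- as.vector(cfg$counts[, , "Vav1"])
  expect_true(all(v %in% c(28L, 29L)))
  expect_lt(abs(sum(v) - 114 * 0.25 * 900), 4 * sqrt(900 * 0.25))
  # rim carries receptor at the box density, no inhibitory species placed
  expect_true(all(cfg$rim_counts[, "N"] == 2L))
  expect_equal(sum(cfg$counts[, , "K"]), 0L)
  expect_equal(cfg$pvav1_total, 0L)
  cfg_i <- init_homogeneous(g, nk_densities(), nk_variant(2, inhibition = TRUE),
                            seed = 5)
  expect_gt(sum(cfg_i$counts[, , "K"]), 0L)
})

test_that("all-zero densities give an empty lattice", {
  cfg <- init_homogeneous(tiny_geometry(), empty_densities(), nk_variant(1))
  expect_equal(sum(cfg$counts), 0L)
  expect_equal(cfg$pvav1_total, 0L)
})

test_that("ensemble means of initial totals track density x area/volume", {
  g <- nk_geometry(box_side_um = 5)
  target <- c(SFK = 698 * 0.25 * 100, Vav1 = 114 * 0.25 * 100,
              SHP1 = 2090 * 0.25 * 100)
  tot <- sapply(1:200, function(s) {
    cfg <- init_homogeneous(g, nk_densities(), nk_variant(1), seed = s)
    c(SFK = sum(cfg$counts[, , "SFK"]), Vav1 = sum(cfg$counts[, , "Vav1"]),
      SHP1 = sum(cfg$counts[, , "SHP1"]))
  })
  for (s in rownames(tot)) {
    se <- stats::sd(tot[s, ]) / sqrt(200)
    expect_lt(abs(mean(tot[s, ]) - target[[s]]), 3 * max(se, 1e-9),
              label = sprintf("%s ensemble mean within 3 s.e.", s))
  }
})

test_that("ULBP3 seeding follows the per-chamber Bernoulli rule", {
  g <- nk_geometry()
  cfg <- init_homogeneous(g, nk_densities(), nk_variant(1), seed = 2)
  all_on <- seed_ulbp3(cfg, f = 1, seed = 3)
  expect_true(all(all_on$counts[, , "L"] == 3L))
  expect_equal(sum(all_on$counts[, , "L"]), 2700L)
  none <- seed_ulbp3(cfg, f = 0, seed = 3)
  expect_equal(sum(none$counts[, , "L"]) + sum(none$rim_counts[, "L"]), 0L)
  # fitted box+rim total 3462 corresponds to f = 3462/3468 over 1156 chambers
  f <- 3462 / 3468
  tot <- sapply(1:50, function(s) {
    c2 <- seed_ulbp3(cfg, f = f, seed = s)
    sum(c2$counts[, , "L"]) + sum(c2$rim_counts[, "L"])
  })
  n_ch <- 900 + 256
  expect_lt(abs(mean(tot) - 3 * n_ch * f),
            3 * 3 * sqrt(n_ch * f * (1 - f) / 50))
})

test_that("ring placement conserves counts and leaves the interior empty", {
  g <- nk_geometry()
  cfg <- init_homogeneous(g, empty_densities(), nk_variant(1))
  rg <- place_ring(cfg, "H", inner_radius = 3, outer_radius = 7,
                   total_count = 1000L, seed = 9)
  expect_equal(sum(rg$counts[, , "H"]), 1000L)
  cc <- expand.grid(x = (seq_len(g$nx) - 0.5) * g$l0,
                    y = (seq_len(g$ny) - 0.5) * g$l0)
  d <- sqrt((cc$x - g$R)^2 + (cc$y - g$R)^2)
  h <- as.vector(rg$counts[, , "H"])
  expect_true(all(h[d < 3] == 0L))
  expect_true(all(h[d >= 7] == 0L))
  # disc degenerate case
  disc <- place_ring(cfg, "H", inner_radius = 0, outer_radius = 2,
                     total_count = 50L, seed = 9)
  expect_equal(sum(disc$counts[, , "H"]), 50L)
  expect_error(place_ring(cfg, "H", inner_radius = 0.01, outer_radius = 0.2,
                          total_count = 10L),
               "no chambers")
})

test_that("field-driven placement flags microclusters like a direct scan", {
  g <- nk_geometry(box_side_um = 6)
  cfg <- init_homogeneous(g, nk_densities(KIR2DL2 = 0, HLAC = 0),
                          nk_variant(1, inhibition = TRUE), seed = 4)
  field <- matrix(0, g$nx, g$ny)
  field[3, 3] <- 1; field[4, 3] <- 0.7      # blob 1
  field[9, 9] <- 0.9; field[9, 10] <- 0.6   # blob 2
  field <- field + 0.01
  out <- place_clusters_from_field(cfg, "K", field, total_count = 400L,
                                   threshold = 20, seed = 6,
                                   coclustered_SFK_fraction = 0.25)
  placed <- out$counts[, , "K"]
  expect_equal(sum(placed), 400L)
  expect_identical(out$flags, placed > 20)   # brute-force scan oracle
  # proportionality: the two blob peaks dominate
  expect_true(placed[3, 3] > 50 && placed[9, 9] > 50)
  # a quarter of free SFK moved to the immobile pool, on flagged chambers only
  sfk0 <- sum(init_homogeneous(g, nk_densities(KIR2DL2 = 0, HLAC = 0),
                               nk_variant(1, inhibition = TRUE),
                               seed = 4)$counts[, , "SFK"])
  expect_equal(sum(out$counts[, , "SFKc"]), round(0.25 * sfk0))
  expect_true(all(out$counts[, , "SFKc"][!out$flags] == 0L))
  expect_equal(sum(out$counts[, , "SFK"]) + sum(out$counts[, , "SFKc"]), sfk0)
})

test_that("degenerate fields are rejected or leave nothing flagged", {
  g <- tiny_geometry(3)
  cfg <- init_homogeneous(g, empty_densities(), nk_variant(1))
  expect_error(place_clusters_from_field(cfg, "K", matrix(0, g$nx, g$ny)),
               "all-zero")
  uni <- place_clusters_from_field(cfg, "K", matrix(1, g$nx, g$ny),
                                   total_count = 36L, threshold = 100,
                                   coclustered_SFK_fraction = 0.25)
  expect_false(any(uni$flags))
  expect_equal(sum(uni$counts[, , "SFKc"]), 0L)
  one <- place_clusters_from_field(cfg, "K", {
    f <- matrix(0, g$nx, g$ny); f[2, 2] <- 5; f
  }, total_count = 17L, threshold = 10, coclustered_SFK_fraction = 0)
  expect_equal(unname(one$counts[2, 2, "K"]), 17L)
  expect_true(one$flags[2, 2])
  expect_equal(sum(one$flags), 1L)
})

test_that("central region counting covers the centered block exactly", {
  g <- nk_geometry()
  cfg <- init_homogeneous(g, nk_densities(), nk_variant(1), seed = 1)
  expect_equal(central_count(cfg, 3), 72L)        # 36 chambers x 2
  empty <- init_homogeneous(g, empty_densities(), nk_variant(1))
  expect_equal(central_count(empty, 3), 0L)
  mid <- put(empty, "C0", 15, 16, 7)
  expect_equal(central_count(mid, 3), 7L)
  expect_error(central_count(cfg, 16), "exceeds")
  expect_error(central_count(cfg, 2.5), "even multiple")
})

test_that("moiety bookkeeping sums species into conserved totals", {
  g <- tiny_geometry(2)
  cfg <- init_homogeneous(g, empty_densities(), nk_variant(1))
  cfg <- put(cfg, "C5", 1, 1, 2)
  cfg <- put(cfg, "K4f", 2, 2, 1)
  cfg <- put(cfg, "SFK", 1, 2, 3)
  tot <- conserved_totals(cfg)
  expect_equal(tot[["NKG2D"]], 2L)
  expect_equal(tot[["ULBP3"]], 2L)
  expect_equal(tot[["Vav1"]], 3L)     # 2 bound in C5 + 1 in K4f
  expect_equal(tot[["SHP1"]], 1L)
  expect_equal(tot[["KIR2DL2"]], 1L)
  expect_equal(cfg$pvav1_total, 3L)
})
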