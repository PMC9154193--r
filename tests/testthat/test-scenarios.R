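test_that("synthetic targets are deterministic, normalized clustered fields", {
  g <- nk_geometry()
  a <- generate_synthetic_target(seed = 5, geometry = g)
  b <- generate_synthetic_target(seed = 5, geometry = g)
  expect_identical(unclass(a), unclass(b))
  expect_equal(max(a), 1)
  expect_true(all(a >= 0))
  flat <- generate_synthetic_target(n_clusters = 0, noise_sd = 0,
                                    background = 0.3, geometry = g)
  expect_true(all(flat == 1))
  # a single smooth cluster decorrelates over about its radius
  one <- generate_synthetic_target(n_clusters = 1, noise_sd = 0,
                                   background = 0, radius_chambers = 2,
                                   radial_bias = 1, geometry = g, seed = 2)
  ct <- two_point_correlation(unclass(one))
  near <- ct$C_over_C0[which.min(abs(ct$r - 0.5))] /
    ct$multiplicity[which.min(abs(ct$r - 0.5))]
  # Gaussian autocorrelation: at separation r the normalized per-pair
  # correlation is ~exp(-r^2 / (4 sd^2)) before mean subtraction
  expect_gt(near, 0.5)
  far <- which.min(abs(ct$r - 6))
  expect_lt(abs(ct$C_over_C0[far] / ct$multiplicity[far]), 0.1)
})

test_that("rebinding-off decay is exponential with ~30 s half-life", {
  rb <- run_rebinding_decay(kon = 0, koff = 0.023, t_end = 40,
                            replicates = 20, seed = 3,
                            geometry = nk_geometry(box_side_um = 8,
                                                   rim_width_chambers = 0L))
  expect_equal(rb$fitted_rate, 0.023, tolerance = 0.15)
  at30 <- rb$decay$mean_fraction[which.min(abs(rb$decay$time - 30))]
  expect_equal(at30, 0.5, tolerance = 0.12)
  none <- run_rebinding_decay(kon = 0, koff = 0.023, bound_fraction = 0,
                              t_end = 10, replicates = 2, seed = 3,
                              geometry = nk_geometry(box_side_um = 4,
                                                     rim_width_chambers = 0L))
  expect_true(all(none$decay$mean_fraction == 0))
})

test_that("zero ULBP3 produces no pVav1 in either clustering case", {
  g <- nk_geometry(box_side_um = 5)
  out <- run_case_AB(2, ulbp3_doses = 0, t_eval = 10, replicates = 2,
                     seed = 7, geometry = g)
  expect_true(all(out$mean_pvav1 == 0))
  expect_equal(nrow(out), 2)  # one row per case
})

test_that("an empty inhibitory arm leaves the activating dynamics unchanged", {
  g <- nk_geometry(box_side_um = 5)
  densities <- nk_densities(KIR2DL2 = 0, HLAC = 0, ulbp3_f = 0.9)
  mk <- function(variant) {
    cfg <- init_homogeneous(g, densities, variant, seed = 5,
                            params = nk_params(2, box_side_um = 5))
    cfg <- seed_ulbp3(cfg, 0.9, seed = 6)
    run_kmc(cfg, nk_rates(2), nk_params(2, box_side_um = 5), variant,
            t_end = 5, snapshot_times = c(0, 5), seed = 31,
            keep_snapshots = FALSE)
  }
  on <- mk(nk_variant(2, inhibition = TRUE))
  off <- mk(nk_variant(2, inhibition = FALSE))
  expect_identical(on$series, off$series)
  expect_identical(on$final$counts, off$final$counts)
})

test_that("VTK structured-points files round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".vtk")
  set.seed(17)
  nk <- matrix(stats::rpois(900, 2L), 30, 30)
  kir <- matrix(stats::rpois(900, 5L), 30, 30)
  write_vtk(list(NKG2D = nk, KIR2DL2 = kir), path)
  hdr <- readLines(path, n = 8)
  expect_equal(hdr[5], "DIMENSIONS 30 30 1")
  expect_equal(hdr[8], sprintf("POINT_DATA %d", 30 * 30))
  back <- read_vtk(path)
  expect_identical(back$NKG2D, nk)
  expect_identical(back$KIR2DL2, kir)
  expect_equal(attr(back, "spacing"), 0.5)
  # float fields round-trip to printed precision
  fl <- matrix(stats::runif(16), 4, 4)
  write_vtk(fl, path)
  expect_equal(read_vtk(path)$value, fl, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "x", "ASCII", "DATASET FOO"),
             bad)
  expect_error(read_vtk(bad), "line 4")
})

test_that("lattice exports carry chamber indices and species columns", {
  csv <- withr::local_tempfile(fileext = ".csv")
  vtk <- withr::local_tempfile(fileext = ".vtk")
  g <- tiny_geometry(2)
  cfg <- put(init_homogeneous(g, empty_densities(), nk_variant(1)),
             "C0", 2, 3, 4)
  export_lattice(cfg, vtk_path = vtk, csv_path = csv)
  df <- utils::read.csv(csv)
  expect_true(all(c("x_index", "y_index", "C0") %in% names(df)))
  expect_equal(sum(df$C0), 4)
  expect_equal(df$C0[df$x_index == 1 & df$y_index == 2], 4)
  expect_identical(read_vtk(vtk)$C0[2, 3], 4L)
})
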