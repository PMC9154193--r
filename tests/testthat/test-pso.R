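make_stats <- function(mu, sigma2, cc) {
  corr <- data.frame(r = seq(0, by = 0.5, length.out = length(cc)),
                     C = cc * sigma2, C_over_C0 = cc,
                     multiplicity = 1L)
  list(mu = mu, sigma2 = sigma2, correlation = corr)
}

test_that("the cost is zero at self-match and 1/3 for a doubled mean", {
  tgt <- make_stats(0.4, 0.02, c(1, 0.5, 0.1))
  expect_equal(cost_from_stats(tgt, tgt)$cost, 0)
  dbl <- make_stats(0.8, 0.02, c(1, 0.5, 0.1))
  expect_equal(cost_from_stats(dbl, tgt)$cost, 1 / 3)
  off <- make_stats(0.1, 0.5, c(1, -0.2, 0))
  expect_gte(cost_from_stats(off, tgt)$cost, 0)
  expect_error(cost_from_stats(tgt, make_stats(0, 0.02, c(1, 0.5, 0.1))),
               "undefined")
  expect_error(cost_from_stats(make_stats(0.4, 0.02, c(1, 0.5)), tgt),
               "different r grids")
})

test_that("the cost is invariant to rescaling the raw simulated counts", {
  set.seed(21)
  field <- matrix(stats::rpois(900, 3), 30, 30)
  tgt <- target_statistics(matrix(stats::runif(900), 30, 30))
  sim1 <- function(theta, eta, n0) field
  sim7 <- function(theta, eta, n0) 7 * field
  c1 <- cost_evaluation(c(a = 1), tgt, sim1)
  c7 <- cost_evaluation(c(a = 1), tgt, sim7)
  expect_equal(c1$cost, c7$cost, tolerance = 1e-12)
  # exact self-match through the full evaluation path
  tgt_self <- target_statistics(field)
  expect_equal(cost_evaluation(c(a = 1), tgt_self, sim1)$cost, 0)
})

test_that("the swarm recovers the optimum of a smooth bowl in log space", {
  optimum <- c(a = 1e-2, b = 3)
  bowl <- function(theta, eta) {
    sum((log10(theta) - log10(optimum))^2)
  }
  res <- pso_minimize(bowl, lower = c(a = 1e-4, b = 0.1),
                      upper = c(a = 1, b = 100),
                      pso_config(swarm_size = 20, max_iter = 50, seed = 5))
  expect_lt(max(abs(log10(res$theta_min) - log10(optimum))), 1e-3)
  expect_lt(res$cost_min, 1e-6)
  expect_lte(nrow(res$history), 20 * 51)
  expect_true(all(res$history$cost >= 0))
  expect_error(pso_minimize(bowl, c(a = 1e-4), c(a = 1),
                            pso_config(swarm_size = 1)), "at least 2")
})

test_that("noise ensembles quantify the cost spread", {
  expect_equal(noise_sigma(c(a = 1), function(theta, eta) 0.7,
                           n_reps = 30)$sigma_C, 0)
  gauss <- function(theta, eta) {
    set.seed(eta)
    stats::rnorm(1, mean = 5, sd = 0.3)
  }
  ns <- noise_sigma(c(a = 1), gauss, n_reps = 200, seed = 3)
  # chi-square CI for the s.d. of 200 normal draws
  expect_gt(ns$sigma_C, 0.3 * sqrt(stats::qchisq(0.001, 199) / 199))
  expect_lt(ns$sigma_C, 0.3 * sqrt(stats::qchisq(0.999, 199) / 199))
  expect_error(noise_sigma(c(a = 1), gauss, n_reps = 10), "at least 30")
})

test_that("density peaks find the right number of parameter clusters", {
  set.seed(31)
  blob <- function(cx, cy, n, s = 0.02)
    cbind(stats::rnorm(n, cx, s), stats::rnorm(n, cy, s))
  two <- rbind(blob(0.2, 0.2, 60), blob(0.8, 0.75, 60))
  dp2 <- density_peak_cluster(two)
  expect_equal(dp2$n_clusters, 2)
  truth <- rep(1:2, each = 60)
  tab <- table(dp2$assignments, truth)
  expect_equal(sum(apply(tab, 1, max)) / 120, 1)
  one <- blob(0.5, 0.5, 100, s = 0.08)
  expect_equal(density_peak_cluster(one)$n_clusters, 1)
  expect_error(density_peak_cluster(one[1:3, ]), "at least 5")
  # d_c honors the 2% mean-neighbor rule
  dp1 <- density_peak_cluster(one)
  mean_nb <- mean(rowSums(as.matrix(stats::dist(one)) < dp1$d_c) - 1)
  expect_equal(mean_nb / 100, 0.02, tolerance = 0.5)
})

test_that("uncertainty reports grow monotonically with the threshold", {
  set.seed(41)
  n <- 120
  hist <- data.frame(iteration = rep(1:10, each = 12), particle = 1:12,
                     log10_a = stats::rnorm(n, -2, 0.3),
                     log10_b = stats::rnorm(n, 1, 0.2),
                     eta = seq_len(n),
                     cost = stats::runif(n, 0.1, 2))
  res <- structure(list(theta_min = c(a = 10^-2, b = 10^1),
                        cost_min = 0.1, eta_min = 1L, history = hist,
                        bounds = list(lower = c(a = 1e-4, b = 0.1),
                                      upper = c(a = 1, b = 100))),
                   class = "nk_pso_result")
  narrow <- uncertainty_report(res, sigma_C = 0.05)
  wide <- uncertainty_report(res, sigma_C = 0.5)
  expect_gt(wide$C_thres, narrow$C_thres)
  expect_gte(nrow(wide$accepted), nrow(narrow$accepted))
  # s.d. of the (single-cluster) accepted cloud equals direct computation
  if (wide$n_clusters == 1) {
    keep <- hist$cost <= wide$C_thres
    expect_equal(unname(wide$sd_log10["a"]),
                 stats::sd(hist$log10_a[keep]), tolerance = 1e-9)
  }
  # only the optimum below threshold: singleton report
  res2 <- res
  res2$history$cost <- 10
  res2$history$cost[1] <- 0.1
  single <- uncertainty_report(res2, sigma_C = 0.01)
  expect_equal(nrow(single$accepted), 1L)
  expect_true(all(single$theta_table$sd == 0))
})
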