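#' Particle swarm optimizer settings
#'
#' Hyperparameters of the asynchronous, bound-constrained particle swarm:
#' inertia `omega = 0.5`, personal-best weight `phi_p = 2.5`, global-best
#' weight `phi_g = 1.5`. The production-scale search uses 200 particles and
#' 100 iterations; the desk-scale defaults here (24 particles, 20
#' iterations) are sized for a single CPU.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param max_iter Iterations.
#' @param omega,phi_p,phi_g Velocity-update coefficients.
#' @param seed RNG seed for particle initialization and updates.
#' @return Object of class `"nk_pso_config"`.
#' @export
pso_config <- function(swarm_size = 24, max_iter = 20, omega = 0.5,
                       phi_p = 2.5, phi_g = 1.5, seed = 1L) {
  if (swarm_size < 2) stop("swarm_size must be at least 2")
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter),
                 omega = omega, phi_p = phi_p, phi_g = phi_g,
                 seed = as.integer(seed)),
            class = "nk_pso_config")
}

#' Minimize a cost function by asynchronous particle swarm optimization
#'
#' Particles move in log10 parameter space within finite bounds. The
#' velocity update is `v <- omega v + phi_p r_p (pbest - x) +
#' phi_g r_g (gbest - x)` with elementwise uniform `r_p`, `r_g`; positions
#' are clipped to the bounds; the global best is updated asynchronously
#' after every single evaluation. Each evaluation draws a fresh
#' intrinsic-noise seed (`eta`) so the minimum is attained jointly over
#' parameters and one noise realization, as in a stochastic simulator fit.
#' Non-finite costs cause the particle to be re-sampled within bounds.
#'
#' @param cost_fn Function `(theta, eta) -> numeric cost`, `theta` a named
#'   vector on the natural scale.
#' @param lower,upper Named positive bounds (natural scale).
#' @param config [pso_config()].
#' @return Object of class `"nk_pso_result"`: `theta_min` (natural scale),
#'   `cost_min`, `eta_min`, and `history` (one row per evaluation with
#'   iteration, particle, the log10 coordinates, eta and cost).
#' @export
pso_minimize <- function(cost_fn, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            all(lower > 0), !is.null(names(lower)))
  set.seed(config$seed)
  d <- length(lower)
  lo <- log10(lower); hi <- log10(upper); rng <- hi - lo
  np <- config$swarm_size
  X <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
              np, d)
  V <- matrix(stats::runif(np * d, -rep(rng, each = np),
                           rep(rng, each = np)) / 10, np, d)
  P <- X
  pcost <- rep(Inf, np)
  gbest <- X[1, ]; gcost <- Inf; geta <- NA_integer_
  hist <- vector("list", np * (config$max_iter + 1L))
  hk <- 0L
  eval_counter <- 0L
  natural <- function(xrow) stats::setNames(10^xrow, names(lower))
  evaluate <- function(xrow) {
    eval_counter <<- eval_counter + 1L
    eta <- config$seed * 1000L + eval_counter
    cst <- cost_fn(natural(xrow), eta)
    list(cost = cst, eta = eta)
  }
  record <- function(iter, p, xrow, ev) {
    hk <<- hk + 1L
    hist[[hk]] <<- c(iteration = iter, particle = p, xrow,
                     eta = ev$eta, cost = ev$cost)
  }
  for (p in seq_len(np)) {
    ev <- evaluate(X[p, ])
    tries <- 0L
    while (!is.finite(ev$cost) && tries < 5L) {
      X[p, ] <- stats::runif(d, lo, hi)
      ev <- evaluate(X[p, ])
      tries <- tries + 1L
    }
    pcost[p] <- ev$cost
    P[p, ] <- X[p, ]
    if (ev$cost < gcost) { gcost <- ev$cost; gbest <- X[p, ]; geta <- ev$eta }
    record(0L, p, X[p, ], ev)
  }
  for (it in seq_len(config$max_iter)) {
    for (p in seq_len(np)) {
      rp <- stats::runif(d); rg <- stats::runif(d)
      V[p, ] <- config$omega * V[p, ] +
        config$phi_p * rp * (P[p, ] - X[p, ]) +
        config$phi_g * rg * (gbest - X[p, ])
      X[p, ] <- pmin(pmax(X[p, ] + V[p, ], lo), hi)
      ev <- evaluate(X[p, ])
      if (!is.finite(ev$cost)) {
        X[p, ] <- stats::runif(d, lo, hi)
        V[p, ] <- 0
        ev <- evaluate(X[p, ])
      }
      record(it, p, X[p, ], ev)
      if (is.finite(ev$cost) && ev$cost < pcost[p]) {
        pcost[p] <- ev$cost
        P[p, ] <- X[p, ]
        if (ev$cost < gcost) {  # asynchronous global-best update
          gcost <- ev$cost; gbest <- X[p, ]; geta <- ev$eta
        }
      }
    }
  }
  history <- as.data.frame(do.call(rbind, hist[seq_len(hk)]))
  names(history) <- c("iteration", "particle", paste0("log10_", names(lower)),
                      "eta", "cost")
  structure(list(theta_min = natural(gbest), cost_min = gcost,
                 eta_min = geta, history = history,
                 bounds = list(lower = lower, upper = upper)),
            class = "nk_pso_result")
}

#' @export
print.nk_pso_result <- function(x, ...) {
  cat(sprintf("<nk_pso_result> cost_min = %.4g after %d evaluations\n",
              x$cost_min, nrow(x$history)))
  print(x$theta_min)
  invisible(x)
}
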