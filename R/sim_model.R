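# Deterministic skeleton of the alarmone-GTP switch:
#   v_syn(P, G) = [beta0 + beta1 P^h/(K_P^h + P^h) + beta2 1_ind] G/(K_sub + G)
#   dP/dt = v_syn - delta_P P
#   dG/dt = alpha_G/(1 + P/K_i) - gamma v_syn - mu(G) G
#   mu(G) = mu_max G^m/(G_th^m + G^m)
#   dF/dt = a_F K_F^q/(K_F^q + G^q) - (mu + d_F) F
#   death hazard under antibiotic: k(mu) = k_min + (k_max - k_min) mu/mu_max

growth_rate_of_G <- function(G, p) {
  p$mu_max * G^p$m / (p$G_th^p$m + G^p$m)
}

synthesis_rate <- function(P, G, p, beta0 = p$beta0, induction = FALSE) {
  fb <- if (p$beta1 > 0) p$beta1 * P^p$h / (p$K_P^p$h + P^p$h) else 0
  (beta0 + fb + if (induction) p$beta2 else 0) * G / (p$K_sub + G)
}

# Quasi-steady-state GTP level given alarmone level P. dG/dt is strictly
# decreasing in G, so the root is unique; bracketed bisection via uniroot.
gtp_qss <- function(P, p, beta0 = p$beta0, induction = FALSE) {
  f <- function(G) {
    p$alpha_G / (1 + P / p$K_i) - p$gamma *
      synthesis_rate(P, G, p, beta0, induction) - growth_rate_of_G(G, p) * G
  }
  hi <- 10 * p$alpha_G / p$mu_max + 1
  if (f(hi) > 0) return(hi)
  if (f(0) <= 0) return(0)
  uniroot(f, c(0, hi), tol = 1e-12)$root
}

reporter_equilibrium <- function(G, p) {
  mu <- growth_rate_of_G(G, p)
  p$a_F * p$K_F^p$q / (p$K_F^p$q + G^p$q) / (mu + p$d_F)
}

#' Fixed points of the deterministic switch skeleton
#'
#' Finds the steady states of the noise-free alarmone dynamics with GTP at
#' quasi-steady state: roots of `dP/dt = 0` located by sign-change bracketing
#' on a dense alarmone grid, refined by bisection; stability is read from the
#' sign of the derivative of `dP/dt` at the root. With cooperative feedback
#' (`h = 3` at wildtype parameters) the skeleton has three fixed points
#' (growing-stable, threshold-unstable, dormant-stable); without cooperativity
#' (`h = 1`) it has one.
#'
#' @param params a [sim_params()] object (noise is ignored; skeleton only).
#' @param n_grid number of grid points for sign-change bracketing.
#' @param induction logical; include the antibiotic-induced synthesis rate.
#' @return A tibble with columns `P_star`, `G_star`, `mu_star`, `stability`
#'   (`"stable"`/`"unstable"`), ordered by `P_star`.
#' @export
deterministic_fixed_points <- function(params, n_grid = 2000,
                                       induction = FALSE) {
  p <- params
  rate <- function(P) {
    vapply(P, function(Pi) {
      G <- gtp_qss(Pi, p, induction = induction)
      synthesis_rate(Pi, G, p, induction = induction) - p$delta_P * Pi
    }, numeric(1))
  }
  B_max <- p$beta0 + p$beta1 + if (induction) p$beta2 else 0
  if (p$delta_P <= 0) stop("delta_P must be > 0 to have fixed points")
  P_max <- 1.5 * B_max / p$delta_P + 1e-6
  grid <- seq(0, P_max, length.out = n_grid)
  r <- rate(grid)
  roots <- numeric(0)
  if (abs(r[1]) < 1e-14) roots <- c(roots, grid[1])
  sgn <- sign(r)
  for (i in seq_len(n_grid - 1)) {
    if (sgn[i] != 0 && sgn[i + 1] != 0 && sgn[i] != sgn[i + 1]) {
      roots <- c(roots, uniroot(rate, c(grid[i], grid[i + 1]), tol = 1e-12)$root)
    } else if (sgn[i + 1] == 0 && i + 1 < n_grid) {
      roots <- c(roots, grid[i + 1])
    }
  }
  if (!length(roots)) stop("no fixed point found in search range [0, ",
                           signif(P_max, 3), "]")
  roots <- sort(unique(roots))
  eps <- max(P_max * 1e-6, 1e-9)
  stab <- vapply(roots, function(P0) {
    dr <- (rate(min(P0 + eps, P_max)) - rate(max(P0 - eps, 0))) /
      (min(P0 + eps, P_max) - max(P0 - eps, 0))
    if (dr < 0) "stable" else "unstable"
  }, character(1))
  G_star <- vapply(roots, gtp_qss, numeric(1), p = p, induction = induction)
  tibble::tibble(
    P_star = roots, G_star = G_star,
    mu_star = growth_rate_of_G(G_star, p),
    stability = stab
  )
}

#' Initialize a cell population
#'
#' Cells start at the growing (lowest-alarmone) stable fixed point with
#' stationary Ornstein-Uhlenbeck noise on the basal synthesis and supply
#' rates, lengths uniform over the division cycle. Optionally a fraction of
#' cells is placed at the dormant (highest-alarmone) fixed point, and a
#' `"stationary"` mode spreads alarmone levels around the unstable threshold
#' to mimic a culture exiting stationary phase.
#'
#' @param params a [sim_params()] object.
#' @param n number of cells.
#' @param dormant_fraction fraction of cells started at the dormant fixed
#'   point (requires a bistable parameter set).
#' @param mode `"growing"` (default) or `"stationary"`.
#' @return A list of state vectors `G, P, F, l, b, a` of length `n`.
#' @export
init_cells <- function(params, n, dormant_fraction = 0, mode = "growing") {
  p <- params
  fp <- deterministic_fixed_points(p)
  stable <- fp[fp$stability == "stable", ]
  grow <- stable[which.min(stable$P_star), ]
  state <- list(
    P = rep(grow$P_star, n), G = rep(grow$G_star, n),
    F = rep(reporter_equilibrium(grow$G_star, p), n),
    l = p$l_birth * 2^runif(n),
    b = clip0(rnorm(n, p$beta0, p$sigma)),
    a = clip0(rnorm(n, p$alpha_G, p$sigma_alpha))
  )
  if (mode == "stationary") {
    unst <- fp$P_star[fp$stability == "unstable"]
    centre <- if (length(unst)) max(unst) else grow$P_star + 1e-3
    state$P <- centre * exp(rnorm(n, 0, 0.6))
    state$G <- vapply(state$P, gtp_qss, numeric(1), p = p)
    state$F <- reporter_equilibrium(state$G, p)
  } else if (dormant_fraction > 0) {
    if (nrow(stable) < 2) {
      stop("dormant_fraction > 0 requires a bistable parameter set")
    }
    dorm <- stable[which.max(stable$P_star), ]
    idx <- seq_len(floor(dormant_fraction * n))
    if (length(idx)) {
      state$P[idx] <- dorm$P_star
      state$G[idx] <- dorm$G_star
      state$F[idx] <- reporter_equilibrium(dorm$G_star, p)
    }
  }
  state
}

#' Advance the stochastic cell-state one time step (reference implementation)
#'
#' Explicit Euler-Maruyama update of the per-cell state, vectorized over
#' cells. This is the R reference for the compiled integration kernel used by
#' the population-level simulators; both perform the identical update in the
#' identical random-number order, which the test suite verifies.
#'
#' @param state list of state vectors `G, P, F, l, b, a` (as from
#'   [init_cells()]), optionally `Lambda` (cumulative antibiotic hazard) and
#'   `logW` (log expected offspring).
#' @param params a [sim_params()] object.
#' @param induction logical; antibiotic-induced synthesis active this step.
#' @param antibiotic logical; accumulate the death hazard this step.
#' @return The updated state list; adds `mu` (specific growth rate used) and
#'   `divided` (logical division flags).
#' @export
sim_step <- function(state, params, induction = FALSE, antibiotic = FALSE) {
  p <- params
  n <- length(state$G)
  dt <- p$dt
  if (is.null(state$Lambda)) state$Lambda <- numeric(n)
  if (is.null(state$logW)) state$logW <- numeric(n)
  if (p$sigma > 0) {
    state$b <- clip0(state$b + (p$beta0 - state$b) * dt / p$tau +
                       p$sigma * sqrt(2 * dt / p$tau) * rnorm(n))
  }
  if (p$sigma_alpha > 0) {
    state$a <- clip0(state$a + (p$alpha_G - state$a) * dt / p$tau_alpha +
                       p$sigma_alpha * sqrt(2 * dt / p$tau_alpha) * rnorm(n))
  }
  G <- state$G; P <- state$P
  mu <- growth_rate_of_G(G, p)
  B <- state$b + p$beta1 * P^p$h / (p$K_P^p$h + P^p$h) +
    if (induction) p$beta2 else 0
  v <- B * G / (p$K_sub + G)
  Pn <- clip0(P + (v - p$delta_P * P) * dt)
  Gn <- clip0(G + (state$a / (1 + P / p$K_i) - p$gamma * v - mu * G) * dt)
  Fn <- clip0(state$F +
                (p$a_F * p$K_F^p$q / (p$K_F^p$q + G^p$q) -
                   (mu + p$d_F) * state$F) * dt)
  P_scale <- (p$beta0 + p$beta1 + p$beta2) / max(p$delta_P, 1e-9) + 1
  G_scale <- p$alpha_G / max(p$mu_max, 1e-9) + 1
  if (any(!is.finite(Pn)) || any(!is.finite(Gn)) ||
      any(Pn > 1e5) || any(Gn > 1e5) ||
      any(abs(Pn - P) > 0.5 * P_scale) || any(abs(Gn - G) > 0.5 * G_scale)) {
    stop("unstable integration (state change exceeds half its ",
         "characteristic scale); reduce dt")
  }
  state$P <- Pn; state$G <- Gn; state$F <- Fn
  state$l <- state$l + mu * state$l * dt
  state$logW <- state$logW + mu * dt
  if (antibiotic) {
    state$Lambda <- state$Lambda +
      (p$k_min + (p$k_max - p$k_min) * mu / p$mu_max) / 60 * dt
  }
  state$divided <- state$l >= 2 * p$l_birth
  state$l[state$divided] <- state$l[state$divided] / 2
  state$mu <- mu
  state
}

# Internal driver around the compiled kernel. times are in minutes.
run_kernel <- function(params, state, n_steps,
                       induction_on = logical(n_steps),
                       antibiotic_on = logical(n_steps),
                       record_ids = integer(0), record_every = 0L,
                       snapshot_steps = integer(0)) {
  stopifnot(length(induction_on) == n_steps, length(antibiotic_on) == n_steps)
  sim_core_run(state$G, state$P, state$F, state$l, state$b, state$a,
               params[sim_param_names], as.integer(n_steps), params$dt,
               induction_on, antibiotic_on,
               as.integer(record_ids - 1L), as.integer(record_every),
               as.integer(snapshot_steps))
}
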