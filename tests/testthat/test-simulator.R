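test_that("preset parameterization is anchored and validated", {
  p <- sim_params("wildtype")
  expect_equal(p$h, 3)
  expect_gte(p$G_th, 0.1)
  expect_lte(p$G_th, 0.2)
  p0 <- genotype_preset("ppGpp0")
  expect_equal(p0$beta0 + p0$beta1 + p0$beta2 + p0$sigma, 0)
  expect_error(sim_params("nonsense"), "unknown preset")
  expect_error(sim_params("wildtype", not_a_param = 1), "unknown parameter")
  expect_error(sim_params("wildtype", k_max = 0.01), "k_max")
  expect_length(carbon_panel(), 5)
})

test_that("deterministic skeleton: linear-balance limit and cooperativity-dependent count", {
  # no feedback, negligible substrate limitation: P* = beta0/delta_P
  p_lin <- sim_params("wildtype", beta1 = 0, K_sub = 1e-9, sigma = 0)
  fp <- deterministic_fixed_points(p_lin)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$P_star, p_lin$beta0 / p_lin$delta_P, tolerance = 1e-6)
  expect_equal(fp$stability, "stable")

  # shipped wildtype skeleton: 3 fixed points at h = 3, agreeing with the
  # dense-grid sign-change oracle
  p <- sim_params("wildtype")
  fp3 <- deterministic_fixed_points(p)
  orc <- oracle_fixed_points(p)
  expect_equal(nrow(fp3), 3)
  expect_length(orc, 3)
  expect_equal(fp3$P_star, orc, tolerance = 1e-3)
  expect_equal(fp3$stability, c("stable", "unstable", "stable"))

  # same parameters with h = 1: single fixed point
  fp1 <- deterministic_fixed_points(sim_params("wildtype", h = 1))
  expect_equal(nrow(fp1), 1)
  expect_length(oracle_fixed_points(sim_params("wildtype", h = 1)), 1)
})

test_that("R reference step and compiled kernel perform the identical update", {
  p <- sim_params("wildtype", dt = 0.1)
  n <- 50
  set.seed(99)
  st <- init_cells(p, n)
  # kernel path
  set.seed(123)
  out <- persistkit:::run_kernel(p, st, 40)
  # R reference path with the same RNG stream
  set.seed(123)
  st_r <- st
  for (i in 1:40) st_r <- sim_step(st_r, p)
  expect_equal(out$G, st_r$G, tolerance = 1e-12)
  expect_equal(out$P, st_r$P, tolerance = 1e-12)
  expect_equal(out$F, st_r$F, tolerance = 1e-12)
  expect_equal(out$l, st_r$l, tolerance = 1e-12)
  expect_equal(out$b, st_r$b, tolerance = 1e-12)
  expect_equal(out$logW, st_r$logW, tolerance = 1e-12)
})

test_that("a stable fixed point is stationary under the noise-free step", {
  p <- sim_params("wildtype", sigma = 0, sigma_alpha = 0)
  fp <- deterministic_fixed_points(p)
  grow <- fp[fp$stability == "stable", ][1, ]
  st <- list(G = grow$G_star, P = grow$P_star,
             F = persistkit:::reporter_equilibrium(grow$G_star, p),
             l = 2.5, b = p$beta0, a = p$alpha_G)
  st1 <- sim_step(st, p)
  expect_equal(st1$P, st$P, tolerance = 1e-6)
  expect_equal(st1$G, st$G, tolerance = 1e-6)
})

test_that("noise-free trajectory matches a high-accuracy reference integration", {
  skip_if_not_installed("deSolve")
  p <- sim_params("wildtype", sigma = 0, sigma_alpha = 0, dt = 0.02)
  # start displaced from equilibrium, above the switching threshold
  st <- list(G = 0.5, P = 0.15, F = 20, l = 2, b = p$beta0, a = p$alpha_G)
  n_steps <- round(500 / p$dt)
  out <- persistkit:::run_kernel(p, st, n_steps)
  rhs <- function(t, y, parms) {
    G <- y[1]; P <- y[2]; F <- y[3]
    mu <- p$mu_max * G^p$m / (p$G_th^p$m + G^p$m)
    v <- (p$beta0 + p$beta1 * P^p$h / (p$K_P^p$h + P^p$h)) * G / (p$K_sub + G)
    list(c(p$alpha_G / (1 + P / p$K_i) - p$gamma * v - mu * G,
           v - p$delta_P * P,
           p$a_F * p$K_F^p$q / (p$K_F^p$q + G^p$q) - (mu + p$d_F) * F))
  }
  ref <- deSolve::lsoda(c(G = 0.5, P = 0.15, F = 20), c(0, 500), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(out$G, unname(ref[2, "G"]), tolerance = 1e-3)
  expect_equal(out$P, unname(ref[2, "P"]), tolerance = 1e-3)
  expect_equal(out$F, unname(ref[2, "F"]), tolerance = 1e-3)
})

test_that("exponential growth limit: length doubles in ln(2)/mu_max", {
  # saturating GTP held by a high supply: mu ~ mu_max
  p <- sim_params("ppGpp0", alpha_G = 1.25, sigma_alpha = 0, dt = 0.05)
  G0 <- 50
  st <- list(G = G0, P = 0, F = 0, l = 1, b = 0, a = p$alpha_G)
  steps <- round(log(2) / p$mu_max / p$dt)
  out <- persistkit:::run_kernel(p, st, steps)
  expect_equal(out$l / 1, 2, tolerance = 0.01)
})

test_that("overflow protection advises a smaller step", {
  p <- sim_params("wildtype", dt = 5e4, sigma = 0, sigma_alpha = 0)
  st <- list(G = 1, P = 0.3, F = 1, l = 2, b = p$beta0, a = p$alpha_G)
  expect_error(persistkit:::run_kernel(p, st, 50), "reduce dt")
})

test_that("state stays non-negative and bounded across presets", {
  for (preset in c("wildtype", "ppGpp0", "ppGpp0_gmk", "sasB_null_or_F42A",
                   "rel_syn", "guaB_down", "sasA_induction")) {
    p <- sim_params(preset)
    pop <- simulate_population(p, n_cells = 200, t_end = 1e4 * p$dt,
                               seed = 17)
    for (v in c("G", "P", "F", "l")) {
      expect_true(all(is.finite(pop$states[[v]])), label = preset)
      expect_true(all(pop$states[[v]] >= 0), label = preset)
      expect_true(all(pop$states[[v]] < 1e5), label = preset)
    }
  }
})

test_that("no-feedback, noise-free populations produce no dormant cells", {
  p <- sim_params("wildtype", beta1 = 0, sigma = 0)
  pop <- simulate_population(p, n_cells = 2000, t_end = 300, seed = 3)
  expect_equal(pop$dormant_fraction, 0)
})

test_that("dormancy is non-decreasing in synthesis-noise amplitude at fixed seed", {
  fr <- vapply(c(2e-4, 3.5e-4, 5e-4), function(sig) {
    p <- sim_params("wildtype", sigma = sig)
    simulate_population(p, n_cells = 8000, t_end = 300,
                        seed = 29)$dormant_fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_gt(fr[3], 0)
})

test_that("ppGpp0 cells keep exactly zero alarmone and no bright tail", {
  p0 <- genotype_preset("ppGpp0")
  pop0 <- simulate_population(p0, n_cells = 5000, t_end = 300, seed = 23)
  expect_true(all(pop0$states$P == 0))
  pw <- simulate_population(sim_params("wildtype"), n_cells = 5000,
                            t_end = 300, seed = 23)
  ctl <- event_table(pop0$control)
  th0 <- tail_heaviness(subtract_autofluorescence(event_table(pop0$events),
                                                  ctl))
  thw <- tail_heaviness(subtract_autofluorescence(event_table(pw$events),
                                                  event_table(pw$control)))
  expect_gt(thw$p999_over_median, th0$p999_over_median)
})

test_that("gmk-like preset keeps the wildtype mean GTP level", {
  gw <- mean(simulate_population(sim_params("wildtype"), 4000, 300,
                                 seed = 37)$states$G)
  gg <- mean(simulate_population(sim_params("ppGpp0_gmk"), 4000, 300,
                                 seed = 37)$states$G)
  expect_equal(gg / gw, 1, tolerance = 0.1)
})

test_that("frozen populations die by the closed-form exponential mixture", {
  p <- sim_params("wildtype", sigma = 0, sigma_alpha = 0)
  fp <- deterministic_fixed_points(p)
  stable <- fp[fp$stability == "stable", ]
  mu_g <- stable$mu_star[1]; mu_d <- stable$mu_star[2]
  k_of <- function(mu) p$k_min + (p$k_max - p$k_min) * mu / p$mu_max
  times <- c(1, 2, 3, 5)

  # all cells at the dormant state: single exponential at k(mu_dormant)
  kc_d <- simulate_killcurve(p, n_cells = 2000, sample_times = times,
                             t_grow = 1, seed = 5, init_dormant_frac = 1,
                             freeze_dynamics = TRUE)
  expect_equal(unname(kc_d$survival[-1]), exp(-k_of(mu_d) * times),
               tolerance = 1e-6)

  # frozen 0.1% dormant mixture: closed-form two-exponential
  kc_m <- simulate_killcurve(p, n_cells = 100000, sample_times = times,
                             t_grow = 1, seed = 6, init_dormant_frac = 1e-3,
                             freeze_dynamics = TRUE)
  expected <- 1e-3 * exp(-k_of(mu_d) * times) +
    (1 - 1e-3) * exp(-k_of(mu_g) * times)
  expect_equal(unname(kc_m$survival[-1]), expected, tolerance = 1e-3)

  # and the kill-kinetics module recovers the frozen dormant fraction
  fit <- fit_biphasic(kc_m$curve)
  expect_equal(fit$f, 1e-3, tolerance = 0.2)
})

test_that("serial passage washes out triggered dormancy; no-switch preset stays at zero", {
  sp0 <- simulate_serial_passage(sim_params("wildtype", beta1 = 0, sigma = 0),
                                 n_passages = 3, n_cells = 4000, seed = 62)
  expect_equal(sp0$dormant_fraction, rep(0, 3))

  sp <- simulate_serial_passage(sim_params("wildtype"), n_passages = 4,
                                n_cells = 8000, seed = 61)
  expect_true(all(diff(sp$dormant_fraction[1:3]) < 0))
  expect_gt(sp$dormant_fraction[4], 0)
  expect_error(simulate_serial_passage(sim_params("wildtype"),
                                       n_passages = 1), "n_passages")
})

test_that("null induction leaves pretreated and untreated arms equivalent", {
  p <- sim_params("sasA_induction", beta2 = 0)
  r <- simulate_antibiotic_induction(p, n_cells = 6000,
                                     lethal_times = c(2, 5), seed = 71)
  diff5 <- abs(r$survival_pretreated["5"] - r$survival_untreated["5"])
  se <- sqrt(r$surv_se_pretreated[2]^2 + r$surv_se_untreated[2]^2)
  expect_lt(diff5, 3 * se + 1e-12)
})

test_that("simulated kill tables are valid module-1 input", {
  p <- sim_params("wildtype")
  kc <- simulate_killcurve(p, n_cells = 3000, sample_times = c(1, 3, 5),
                           t_grow = 120, seed = 9)
  expect_s3_class(kc$curve, "kill_curve")
  expect_true(all(c("condition", "antibiotic", "replicate", "time_h",
                    "cfu_per_ml", "lod") %in% names(kc$table)))
  sf <- survival_fractions(kc$curve)
  expect_equal(sf$mean_survival[1], 1)
})
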