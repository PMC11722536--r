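# Independent oracles used across the suite. These deliberately avoid the
# package's fitting/search code paths: the biphasic oracle is a dense
# log-grid search with a local polish over the same least-squares objective,
# and the fixed-point oracle is a plain dense-grid sign-change scan over the
# quasi-steady-state alarmone flux balance.

two_exp <- function(t, f, kf, ks) (1 - f) * exp(-kf * t) + f * exp(-ks * t)

# sum of squared log10 residuals against observed mean-log10 survival
biphasic_sse <- function(f, kf, ks, t, y) {
  sum((log10(two_exp(t, f, kf, ks)) - y)^2)
}

# dense grid + optim polish oracle for the two-exponential decomposition
oracle_biphasic <- function(t, y, n_f = 50, n_kf = 40, n_ks = 20) {
  grid <- expand.grid(
    lf = seq(-7, -0.05, length.out = n_f),
    lkf = seq(log10(0.05), log10(40), length.out = n_kf),
    lks = c(-10, seq(-3, log10(2), length.out = n_ks - 1))
  )
  sse <- mapply(function(lf, lkf, lks) {
    kf <- 10^lkf; ks <- 10^lks
    if (ks >= kf) return(Inf)
    biphasic_sse(10^lf, kf, ks, t, y)
  }, grid$lf, grid$lkf, grid$lks)
  obj <- function(p) {
    kf <- 10^p[2]; ks <- 10^p[3]
    if (ks >= kf || p[1] > 0) return(1e10)
    biphasic_sse(10^p[1], kf, ks, t, y)
  }
  best <- NULL
  for (i in order(sse)[1:5]) {
    res <- optim(as.numeric(grid[i, ]), obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
    res <- optim(res$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(f = 10^best$par[1], k_fast = 10^best$par[2], k_slow = 10^best$par[3],
       sse = best$value)
}

# dense-grid sign-change count/location of dP/dt = 0 at GTP quasi-steady
# state; root-finds G for each P with its own bisection (not the package's)
oracle_fixed_points <- function(p, n_grid = 20001) {
  g_of_P <- function(P) {
    f <- function(G) {
      B <- p$beta0 + p$beta1 * P^p$h / (p$K_P^p$h + P^p$h)
      v <- B * G / (p$K_sub + G)
      mu <- p$mu_max * G^p$m / (p$G_th^p$m + G^p$m)
      p$alpha_G / (1 + P / p$K_i) - p$gamma * v - mu * G
    }
    lo <- 0; hi <- 10 * p$alpha_G / p$mu_max + 1
    if (f(hi) > 0) return(hi)
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  P_max <- 1.5 * (p$beta0 + p$beta1) / p$delta_P + 1e-6
  Pg <- seq(0, P_max, length.out = n_grid)
  r <- vapply(Pg, function(P) {
    G <- g_of_P(P)
    B <- p$beta0 + p$beta1 * P^p$h / (p$K_P^p$h + P^p$h)
    B * G / (p$K_sub + G) - p$delta_P * P
  }, numeric(1))
  roots <- numeric(0)
  if (abs(r[1]) < 1e-14) roots <- c(roots, Pg[1])
  for (i in seq_len(n_grid - 1)) {
    if (sign(r[i]) != 0 && sign(r[i + 1]) != 0 &&
        sign(r[i]) != sign(r[i + 1])) {
      w <- r[i] / (r[i] - r[i + 1])
      roots <- c(roots, Pg[i] + w * (Pg[i + 1] - Pg[i]))
    }
  }
  roots
}

# build a programmed step track: constant exponential growth, then arrest
programmed_track <- function(n_frames = 30, dt = 15, mu0 = 0.02,
                             arrest_frame = NA, fluor_fun = NULL,
                             id = "prog") {
  times <- (seq_len(n_frames) - 1) * dt
  mu <- rep(mu0, n_frames - 1)
  if (!is.na(arrest_frame)) mu[arrest_frame:(n_frames - 1)] <- mu0 / 100
  l <- 1.0 * cumprod(c(1, 1 + mu * dt))
  fl <- if (is.null(fluor_fun)) rep(1, n_frames) else fluor_fun(times)
  tibble::tibble(track_id = id, frame = seq_len(n_frames), time_min = times,
                 length_um = l, fluor_au = fl, division = 0L)
}

mean_log10_survival_of <- function(kc) persistkit:::mean_log10_survival(kc)

# track built directly from a specified per-interval growth-rate series
track_from_mu <- function(mu, dt = 15, fluor = NULL, id = "mu_track",
                          l0 = 1) {
  l <- l0 * cumprod(c(1, 1 + mu * dt))
  n <- length(l)
  tibble::tibble(track_id = id, frame = seq_len(n),
                 time_min = (seq_len(n) - 1) * dt, length_um = l,
                 fluor_au = if (is.null(fluor)) rep(1, n) else fluor,
                 division = 0L)
}
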