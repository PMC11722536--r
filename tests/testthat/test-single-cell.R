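test_that("specific growth rate: identity, forced arithmetic and closed form", {
  # constant length -> mu = 0
  tr <- cell_track(track_from_mu(rep(0, 10)))
  expect_equal(specific_growth_rate(tr)$mu, rep(0, 10))

  # 2.0 -> 2.2 um over 15 min
  d <- tibble::tibble(track_id = "x", frame = 1:2, time_min = c(0, 15),
                      length_um = c(2.0, 2.2), fluor_au = 0, division = 0L)
  expect_equal(specific_growth_rate(cell_track(d))$mu, 0.2 / (2.0 * 15))

  # exponential elongation l(t) = exp(0.02 t) sampled every 15 min
  t <- seq(0, 300, 15)
  d <- tibble::tibble(track_id = "x", frame = seq_along(t), time_min = t,
                      length_um = exp(0.02 * t), fluor_au = 0, division = 0L)
  mu <- specific_growth_rate(cell_track(d))$mu
  expect_equal(mu, rep((exp(0.3) - 1) / 15, length(t) - 1), tolerance = 1e-10)

  expect_error(specific_growth_rate(cell_track(d[1, ])), "at least 2")
})

test_that("growth rate is invariant to rescaling of length units", {
  t <- seq(0, 150, 15)
  mk <- function(scale) {
    d <- tibble::tibble(track_id = "x", frame = seq_along(t), time_min = t,
                        length_um = scale * exp(0.015 * t + 0.01 * sin(t)),
                        fluor_au = 0, division = 0L)
    specific_growth_rate(cell_track(d))$mu
  }
  expect_equal(mk(1), mk(1000), tolerance = 1e-12)
})

test_that("division intervals are excluded from the growth-rate series", {
  d <- tibble::tibble(track_id = "x", frame = 1:5, time_min = seq(0, 60, 15),
                      length_um = c(2, 3, 3.9, 2.05, 2.9),
                      fluor_au = 0, division = c(0L, 0L, 0L, 1L, 0L))
  mu <- specific_growth_rate(cell_track(d), smooth_window = 1)$mu
  expect_true(is.na(mu[3]))
  expect_false(anyNA(mu[-3]))
})

test_that("arrest detection: no-arrest, programmed drop, degenerate all-zero", {
  base <- 0.02
  s_flat <- specific_growth_rate(cell_track(track_from_mu(rep(base, 30))))
  expect_true(is.na(detect_growth_arrest(s_flat, base, 0.2, 3)))

  mu <- c(rep(0.02, 20), rep(0.001, 10))
  s <- specific_growth_rate(cell_track(track_from_mu(mu)))
  expect_equal(detect_growth_arrest(s, base, theta = 0.2, w = 3), 300)

  s0 <- specific_growth_rate(cell_track(track_from_mu(rep(0, 10))))
  expect_equal(detect_growth_arrest(s0, base, 0.2, 3), 0)

  expect_error(detect_growth_arrest(list(mu = numeric(0)), base), "empty")
})

test_that("threshold crossing requires a sustained run", {
  t <- seq(0, 435, 15)
  flat <- cell_track(tibble::tibble(track_id = "x", frame = seq_along(t),
                                    time_min = t, length_um = 1,
                                    fluor_au = 5, division = 0L))
  expect_true(is.na(detect_threshold_crossing(flat, 100, 2)))

  fl <- c(rep(5, 15), rep(150, 15))
  tr <- cell_track(tibble::tibble(track_id = "x", frame = seq_along(t),
                                  time_min = t, length_um = 1,
                                  fluor_au = fl, division = 0L))
  expect_equal(detect_threshold_crossing(tr, 100, 2), t[16])

  fl1 <- rep(5, 30); fl1[16] <- 150
  tr1 <- cell_track(tibble::tibble(track_id = "x", frame = seq_along(t),
                                   time_min = t, length_um = 1,
                                   fluor_au = fl1, division = 0L))
  expect_true(is.na(detect_threshold_crossing(tr1, 100, 2)))
})

test_that("switch events: programmed abrupt entry, quiescent track, graded mutant", {
  # reporter crosses at frame 16, abrupt arrest at frame 20 -> lag 60 min
  mu <- c(rep(0.02, 19), rep(2e-4, 10))
  fl <- c(rep(5, 15), rep(150, 15))
  ev <- extract_switch_event(cell_track(track_from_mu(mu, fluor = fl)),
                             baseline = 0.02, f_thr = 100)
  expect_equal(ev$t_arrest, 285)
  expect_equal(ev$t_threshold, 225)
  expect_equal(ev$lag, 60)
  expect_equal(ev$classification, "switch_like")

  # constant growth, flat reporter
  ev0 <- extract_switch_event(cell_track(track_from_mu(rep(0.02, 29))),
                              baseline = 0.02, f_thr = 100)
  expect_equal(ev0$classification, "none")
  expect_true(is.na(ev0$lag))

  # mutant-like: mu declining linearly to zero as the reporter rises
  mu_lin <- seq(0.02, 0, length.out = 25)
  fl_lin <- 10^seq(0.5, 2.8, length.out = 26)
  ev_g <- extract_switch_event(cell_track(track_from_mu(mu_lin, fluor = fl_lin)),
                               baseline = 0.02, f_thr = 100)
  expect_equal(ev_g$classification, "graded")
  expect_false(is.na(ev_g$t_arrest))
})

test_that("arrest-threshold consistency summary", {
  evs <- tibble::tibble(fluor_at_arrest = c(90, 100, 110))
  cs <- threshold_consistency(evs)
  expect_equal(cs$mean, 100)
  expect_equal(cs$sd, 10)
  expect_equal(cs$cv, 0.1)
  expect_equal(threshold_consistency(tibble::tibble(
    fluor_at_arrest = c(7, 7)))$cv, 0)
  expect_error(threshold_consistency(tibble::tibble(fluor_at_arrest = 5)),
               "at least 2")
})

test_that("precedence sign test matches the binomial tail", {
  expect_equal(precedence_test(tibble::tibble(lag = rep(10, 10)))$p_value,
               0.5^10)
  p55 <- precedence_test(tibble::tibble(lag = c(rep(1, 5), rep(-1, 5))))
  expect_equal(p55$fraction_positive, 0.5)
  expect_equal(p55$p_value, sum(dbinom(5:10, 10, 0.5)), tolerance = 1e-12)
  one <- precedence_test(tibble::tibble(lag = 3))
  expect_equal(one$p_value, 0.5)
  # ties dropped
  expect_equal(precedence_test(tibble::tibble(lag = c(0, 0, 4)))$n, 1)
  expect_error(precedence_test(tibble::tibble(lag = c(NA, 0))), "no events")
})

test_that("model selection: exact line chooses linear, steep logistic chooses logistic", {
  x <- seq(0, 2, length.out = 40)
  lin <- fit_growth_vs_reporter(x, 0.02 - 0.005 * x)
  expect_equal(lin$chosen_model, "linear")
  expect_equal(lin$linear$slope, -0.005, tolerance = 1e-8)

  set.seed(11)
  y <- 0.002 + 0.02 / (1 + 10^(4 * (x - 1))) + rnorm(40, 0, 4e-4)
  logi <- fit_growth_vs_reporter(x, y)
  expect_equal(logi$chosen_model, "variable_slope_logistic")
  expect_equal(logi$logistic$slope, 4, tolerance = 0.2)
  expect_equal(logi$logistic$logF50, 1, tolerance = 0.1)

  expect_error(fit_growth_vs_reporter(x[1:4], y[1:4]), "at least 6")
  expect_error(fit_growth_vs_reporter(rep(c(0.1, 0.4), 10), rnorm(20)),
               "decade")
})

test_that("model selection is reliable across seeded replicates", {
  picks <- vapply(1:40, function(s) {
    set.seed(s)
    x <- runif(60, 0, 2)
    y_lin <- 0.022 - 0.008 * x + rnorm(60, 0, 1e-3)
    y_log <- 0.002 + 0.02 / (1 + 10^(3.5 * (x - 1))) + rnorm(60, 0, 1e-3)
    c(fit_growth_vs_reporter(x, y_lin)$chosen_model == "linear",
      fit_growth_vs_reporter(x, y_log)$chosen_model ==
        "variable_slope_logistic")
  }, logical(2))
  expect_gte(mean(picks[1, ]), 0.95)
  expect_gte(mean(picks[2, ]), 0.95)
})
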