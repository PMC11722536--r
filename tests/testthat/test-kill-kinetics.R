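make_tab <- function(times, counts_by_rep, lod = 100,
                     condition = "c", antibiotic = "a") {
  do.call(rbind, lapply(seq_along(counts_by_rep), function(r) {
    tibble::tibble(condition = condition, antibiotic = antibiotic,
                   replicate = r, time_h = times,
                   cfu_per_ml = counts_by_rep[[r]], lod = lod)
  }))
}

test_that("survival fractions: identity, forced arithmetic and replicate summary", {
  # constant counts -> survival 1 everywhere
  kc <- kill_curve(make_tab(c(0, 1, 2, 3), list(rep(2e7, 4))))
  expect_equal(survival_fractions(kc)$mean_survival, rep(1, 4))

  # single replicate 1e8 -> 1e5 at 5 h
  kc <- kill_curve(make_tab(c(0, 1, 3, 5), list(c(1e8, 1e7, 1e6, 1e5))))
  expect_equal(survival_fractions(kc)$mean_survival[4], 1e-3)

  # three replicates {1e5, 2e5, 4e5} at 5 h over 1e8: hand-computed summary
  kc <- kill_curve(make_tab(c(0, 1, 3, 5), list(
    c(1e8, 1e7, 1e6, 1e5), c(1e8, 1e7, 1e6, 2e5), c(1e8, 1e7, 1e6, 4e5))))
  sf <- survival_fractions(kc)
  s <- c(1e-3, 2e-3, 4e-3)
  expect_equal(sf$mean_survival[4], mean(s))
  expect_equal(sf$sd_survival[4], sd(s))
})

test_that("zero or censored t=0 counts are rejected with the replicate named", {
  tab <- make_tab(c(0, 1, 2, 3), list(c(1e8, 1e7, 1e6, 1e5),
                                      c(0, 1e7, 1e6, 1e5)))
  kc <- kill_curve(tab)
  expect_error(survival_fractions(kc), "rep2")
})

test_that("curve container validates schema, monotonicity and non-negative counts", {
  tab <- make_tab(c(0, 1, 2, 3), list(rep(1e7, 4)))
  expect_error(kill_curve(tab[, -4]), "missing column")
  bad <- tab; bad$cfu_per_ml[2] <- -5
  expect_error(kill_curve(bad), ">= 0")
  bad <- tab; bad$time_h <- c(0, 1, 1, 3)
  expect_error(kill_curve(bad), "strictly increasing")
  bad <- tab; bad$time_h <- bad$time_h + 1
  expect_error(kill_curve(bad), "include 0")
})

test_that("single-exponential limit: persister fraction collapses to the boundary", {
  kc <- make_biphasic_curve(0, 2, 0, times = seq(0, 5, 0.5))
  fit <- fit_biphasic(kc)
  expect_true(fit$converged)
  expect_lte(fit$f, 1e-6)
  expect_equal(fit$k_fast, 2, tolerance = 1e-3)
})

test_that("noiseless two-exponential parameters are recovered within 1%", {
  kc <- make_biphasic_curve(1e-3, 6, 0.05, times = c(0, 0.5, 1, 2, 3, 4, 5))
  fit <- fit_biphasic(kc)
  expect_true(fit$converged)
  expect_equal(fit$f, 1e-3, tolerance = 0.01)
  expect_equal(fit$k_fast, 6, tolerance = 0.01)
  expect_equal(fit$k_slow, 0.05, tolerance = 0.01)
})

test_that("fit preconditions: too few points and fully censored curves error", {
  kc <- kill_curve(make_tab(c(0, 1, 2), list(c(1e8, 1e6, 1e4))))
  expect_error(fit_biphasic(kc), "at least 4")
  tab <- make_tab(c(0, 1, 2, 3, 4), list(c(1e8, 0, 0, 0, 0)))
  expect_error(fit_biphasic(kill_curve(tab)), "censored")
})

test_that("oracle equivalence on noiseless two-exponential curves", {
  # both parameters identifiable everywhere: the plateau dominates the last
  # sampled time (constrains f) and the fast phase dominates the second
  # (constrains k_fast)
  cases <- expand.grid(f = c(1e-3, 1e-2, 0.05),
                       kf = c(2, 4, 6), ks = c(0, 0.05))
  times <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8)
  for (i in seq_len(nrow(cases))) {
    f <- cases$f[i]; kf <- cases$kf[i]; ks <- cases$ks[i]
    if (kf / max(ks, 1e-9) < 10) next
    kc <- make_biphasic_curve(f, kf, ks, times = times)
    fit <- fit_biphasic(kc)
    d <- mean_log10_survival_of(kc)
    orc <- oracle_biphasic(d$t, d$y)
    expect_equal(fit$f, orc$f, tolerance = 0.01)
    expect_equal(fit$k_fast, orc$k_fast, tolerance = 0.01)
    expect_lte(abs(fit$k_slow - orc$k_slow), 0.01 * orc$k_fast)
  }
})

test_that("tolerance metrics: closed forms, interpolation and plateau handling", {
  kc <- make_biphasic_curve(1e-3, log(100), 0.01, times = seq(0, 5, 0.5))
  fit <- fit_biphasic(kc)
  tm <- tolerance_metrics(fit, kc, t_ref = 5)
  expect_equal(tm$mdk99_sensitive, log(100) / fit$k_fast)

  # pure exponential at rate ln(100)/h: bulk MDK99 is exactly 1 h
  kc1 <- make_biphasic_curve(0, log(100), 0, times = seq(0, 3, 0.25), lod = 1)
  fit1 <- fit_biphasic(kc1)
  tm1 <- tolerance_metrics(fit1, kc1, t_ref = 3)
  expect_equal(tm1$mdk99_bulk, 1, tolerance = 1e-3)
  expect_equal(tm1$mdk99_sensitive, 1, tolerance = 1e-3)

  # empirical persister fraction at t_ref = 5 h
  kc2 <- make_biphasic_curve(1e-3, 6, 0.05, times = c(0, 1, 2, 3, 4, 5))
  fit2 <- fit_biphasic(kc2)
  tm2 <- tolerance_metrics(fit2, kc2, t_ref = 5)
  expect_equal(tm2$persister_fraction_empirical,
               1e-3 * exp(-0.25) + (1 - 1e-3) * exp(-30), tolerance = 1e-6)

  # a plateau above 1%: bulk MDK99 not reached
  kc3 <- make_biphasic_curve(0.05, 6, 0, times = c(0, 1, 2, 3, 4, 5))
  fit3 <- fit_biphasic(kc3)
  tm3 <- tolerance_metrics(fit3, kc3)
  expect_false(tm3$bulk_reached)
  expect_true(is.na(tm3$mdk99_bulk))

  fit_bad <- fit3; fit_bad$converged <- FALSE
  expect_error(tolerance_metrics(fit_bad, kc3), "converge")
})

test_that("condition comparison: folds, symmetry and the Welch t oracle", {
  kc <- make_biphasic_curve(1e-3, 6, 0.05, times = c(0, 1, 3, 5))
  fit <- fit_biphasic(kc)
  same <- compare_conditions(list(curve = kc, fit = fit),
                             list(curve = kc, fit = fit), t_ref = 5)
  expect_equal(same$fold_survival, 1)
  expect_equal(same$fold_f, 1)
  expect_equal(same$ratio_mdk99, 1)
  expect_equal(same$p_value, 1)

  # forced 10-fold survival difference
  mk <- function(s5) {
    kill_curve(make_tab(c(0, 1, 3, 5), list(
      c(1e8, 1e7, 5e7 * s5 * 2, 1e8 * s5))))
  }
  a <- mk(5e-1); b <- mk(5e-2)
  fa <- list(curve = a, fit = fit); fb <- list(curve = b, fit = fit)
  expect_equal(compare_conditions(fa, fb, t_ref = 5)$fold_survival, 10)

  # Welch t against the textbook formula
  la <- c(-1.0, -1.1, -0.9); lb <- c(-3.0, -3.1, -2.9)
  mk_rep <- function(lvals) {
    kill_curve(make_tab(c(0, 1, 3, 5), lapply(lvals, function(l) {
      c(1e8, 1e7, 1e6, 1e8 * 10^l)
    })))
  }
  ca <- mk_rep(la); cb <- mk_rep(lb)
  cmp <- compare_conditions(list(curve = ca, fit = fit),
                            list(curve = cb, fit = fit), t_ref = 5)
  se <- sqrt(var(la) / 3 + var(lb) / 3)
  t_hand <- (mean(la) - mean(lb)) / se
  df_hand <- se^4 / ((var(la) / 3)^2 / 2 + (var(lb) / 3)^2 / 2)
  expect_equal(cmp$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(cmp$df, df_hand, tolerance = 1e-10)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  expect_error(compare_conditions(fa, fb, t_ref = 2.5), "not sampled")
})

test_that("empirical persister fraction is monotone in the true plateau", {
  fracs <- vapply(c(1e-4, 3e-4, 1e-3, 3e-3, 1e-2), function(f) {
    kc <- make_biphasic_curve(f, 6, 0.05, times = c(0, 1, 2, 3, 4, 5))
    sf <- survival_fractions(kc)
    sf$mean_survival[sf$time_h == 5]
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("as the plateau vanishes the sensitive MDK99 matches the bulk MDK99", {
  # sampled within the uncensored range (counts above the detection limit)
  kc <- make_biphasic_curve(1e-8, 4, 0.05, times = seq(0, 2.5, 0.2))
  fit <- fit_biphasic(kc)
  tm <- tolerance_metrics(fit, kc, t_ref = 2)
  expect_equal(tm$mdk99_sensitive, tm$mdk99_bulk, tolerance = 1e-3)
})

test_that("plateau recovery under lognormal noise (seeded)", {
  errs <- vapply(1:30, function(s) {
    kc <- make_biphasic_curve(1e-3, 6, 0.05, times = c(0, 0.5, 1, 1.5, 2, 3, 4, 5),
                              cv = 0.2, n_replicates = 3, seed = s)
    abs(fit_biphasic(kc)$f - 1e-3) / 1e-3
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})
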