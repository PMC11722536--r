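# Population-level simulation protocols. All randomness is driven by a single
# `seed` argument per protocol; times are minutes inside the model and hours
# in kill-curve outputs, matching the analysis-module schemas.

measured_fluor <- function(F, p, n = length(F)) {
  F * exp(rnorm(n, 0, p$meas_sd_fluor)) +
    clip0(rnorm(n, p$af_mean, p$af_sd))
}

#' Simulate an unstressed cell population
#'
#' Runs `n_cells` independent cells of the stochastic alarmone-GTP switch
#' from the growing steady state for `t_end` minutes and returns (i) a
#' cytometry-style snapshot of measured reporter fluorescence with matched
#' reporterless-control events, (ii) time-lapse tracks in the single-cell
#' module's schema for a recorded subset of cells, and (iii) per-cell final
#' states with dormancy flags.
#'
#' @param params a [sim_params()] object.
#' @param n_cells number of cells.
#' @param t_end simulated time, minutes.
#' @param seed integer seed.
#' @param n_tracks number of cells returned as time-lapse tracks. The track
#'   set is rare-event enriched, as in time-lapse screens that
#'   retrospectively analyze detected entrance events: cells dormant at
#'   `t_end` are kept first, up to `track_dormant_cap` of the set, the rest
#'   are growing cells.
#' @param track_dormant_cap maximum fraction of tracks taken from dormant
#'   cells.
#' @param frame_every track sampling interval, minutes.
#' @param sample_label label used in the event-table output.
#' @return A list with elements `events`, `control` (event tibbles with
#'   columns `sample`, `value`), `tracks` (tibble with columns `track_id`,
#'   `frame`, `time_min`, `length_um`, `fluor_au`, `division`), `states`
#'   (final state vectors incl. `mu`), `dormant` (logical), and
#'   `dormant_fraction`.
#' @export
simulate_population <- function(params, n_cells, t_end = 300, seed = 1,
                                n_tracks = 0, frame_every = 15,
                                sample_label = attr(params, "preset") %||% "sim",
                                track_dormant_cap = 0.2) {
  p <- params
  set.seed(seed)
  n_steps <- round(t_end / p$dt)
  record_every <- max(1L, round(frame_every / p$dt))
  state <- init_cells(p, n_cells)
  # dormancy is not known a priori, so all cells are recorded and dormant
  # tracks are kept preferentially afterwards (rare-event enrichment, as in
  # time-lapse screens that retrospectively analyze detected entrance events)
  n_rec <- if (n_tracks > 0) n_cells else 0L
  record_ids <- if (n_rec > 0) seq_len(n_cells) else integer(0)
  out <- run_kernel(p, state, n_steps,
                    record_ids = record_ids, record_every = record_every,
                    snapshot_steps = n_steps)
  mu_final <- out$snap_mu[, 1]
  dormant <- mu_final < p$dormant_mu_frac * p$mu_max
  events <- tibble::tibble(
    sample = sample_label,
    value = measured_fluor(out$snap_F[, 1], p)
  )
  control <- tibble::tibble(
    sample = paste0(sample_label, "_control"),
    value = clip0(rnorm(n_cells, p$af_mean, p$af_sd))
  )
  tracks <- NULL
  if (n_rec > 0) {
    rec_dorm <- dormant[record_ids]
    n_dorm <- min(sum(rec_dorm), max(1L, round(track_dormant_cap * n_tracks)))
    keep <- c(head(which(rec_dorm), n_dorm),
              head(which(!rec_dorm), n_tracks - n_dorm))
    keep <- sort(keep)
    times <- seq(0, n_steps * p$dt, by = record_every * p$dt)
    nfr <- length(times)
    tracks <- do.call(rbind, lapply(keep, function(j) {
      tibble::tibble(
        track_id = sprintf("%s_c%05d", sample_label, record_ids[j]),
        frame = seq_len(nfr),
        time_min = times,
        length_um = out$rec_l[, j] * exp(rnorm(nfr, 0, p$meas_sd_length)),
        fluor_au = clip0(out$rec_F[, j] * exp(rnorm(nfr, 0, p$meas_sd_fluor))),
        division = as.integer(out$rec_div[, j]),
        mu_true = out$rec_mu[, j],
        gtp_mM = out$rec_G[, j]
      )
    }))
  }
  list(
    events = events, control = control, tracks = tracks,
    states = out, dormant = dormant,
    dormant_fraction = mean(dormant)
  )
}

#' Simulate an antibiotic kill curve
#'
#' Grows a population for `t_grow` minutes, then applies antibiotic and
#' accumulates each cell's growth-dependent death hazard
#' `k(mu) = k_min + (k_max - k_min) mu/mu_max`. CFU counts at the sampling
#' times are Poisson draws around the population mean survival scaled to
#' `N0` CFU/mL, with a small lognormal replicate effect.
#'
#' @param params a [sim_params()] object.
#' @param n_cells number of simulated cells.
#' @param sample_times sampling times under antibiotic, hours (0 included
#'   automatically).
#' @param t_grow unstressed growth (burn-in) before treatment, minutes.
#' @param seed integer seed.
#' @param n_replicates plating replicates.
#' @param N0 CFU/mL at treatment start.
#' @param lod detection limit, CFU/mL.
#' @param condition,antibiotic labels for the output table.
#' @param rep_cv lognormal coefficient of variation of the replicate effect.
#' @param init_dormant_frac start with this fraction of cells at the dormant
#'   fixed point (frozen-mixture experiments).
#' @param freeze_dynamics if `TRUE`, cell states are frozen during treatment
#'   (the hazard integrates the state at treatment start); used to compare
#'   against the closed-form two-exponential mixture.
#' @return A list: `table` (tibble in the kill-curve CSV schema), `curve`
#'   (a [kill_curve()] object), `survival` (true mean survival per sampling
#'   time), `dormant_fraction_t0` (dormant fraction at treatment start).
#' @export
simulate_killcurve <- function(params, n_cells,
                               sample_times = c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 8),
                               t_grow = 300, seed = 1, n_replicates = 3,
                               N0 = 1e8, lod = 100,
                               condition = attr(params, "preset") %||% "sim",
                               antibiotic = "vancomycin", rep_cv = 0.1,
                               init_dormant_frac = 0, freeze_dynamics = FALSE) {
  p <- params
  set.seed(seed)
  sample_times <- sort(unique(c(0, sample_times)))
  grow_steps <- round(t_grow / p$dt)
  kill_steps <- round(max(sample_times) * 60 / p$dt)
  state <- init_cells(p, n_cells, dormant_fraction = init_dormant_frac)
  snap_steps <- grow_steps + round(sample_times * 60 / p$dt)
  if (freeze_dynamics) {
    # run burn-in only, then integrate the hazard analytically at frozen mu
    out <- run_kernel(p, state, max(grow_steps, 1L),
                      snapshot_steps = max(grow_steps, 1L))
    mu0 <- out$snap_mu[, 1]
    k <- p$k_min + (p$k_max - p$k_min) * mu0 / p$mu_max
    surv_cell <- outer(k, sample_times, function(k, t) exp(-k * t))
    mu_t0 <- mu0
  } else {
    n_steps <- grow_steps + kill_steps
    abx <- c(rep(FALSE, grow_steps), rep(TRUE, kill_steps))
    out <- run_kernel(p, state, n_steps, antibiotic_on = abx,
                      snapshot_steps = snap_steps)
    surv_cell <- exp(-out$snap_Lambda)
    mu_t0 <- out$snap_mu[, 1]
  }
  surv <- colMeans(surv_cell)
  dormant_t0 <- mean(mu_t0 < p$dormant_mu_frac * p$mu_max)
  tab <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    eff <- exp(rnorm(1, 0, rep_cv))
    tibble::tibble(
      condition = condition, antibiotic = antibiotic, replicate = r,
      time_h = sample_times,
      cfu_per_ml = rpois(length(sample_times), N0 * eff * surv),
      lod = lod
    )
  }))
  curve <- kill_curve(tab)
  list(table = tab, curve = curve,
       survival = stats::setNames(surv, sample_times),
       dormant_fraction_t0 = dormant_t0,
       surv_se = apply(surv_cell, 2, sd) / sqrt(n_cells))
}

#' Simulate a serial-passage (spontaneous persistence) experiment
#'
#' Starts from a stationary-like population (alarmone spread around the
#' unstable threshold), then repeatedly regrows for `growth_window` minutes
#' and dilutes back. Dilution is implemented as weighted resampling of cells
#' with probability proportional to each cell's expected offspring number,
#' which keeps per-cell resolution while reproducing the frequency dynamics
#' of bulk dilution. Starvation-triggered dormant cells are overgrown and
#' washed out passage by passage, leaving the spontaneous plateau.
#'
#' @param params a [sim_params()] object.
#' @param n_passages number of passages (>= 2).
#' @param growth_window regrowth time per passage, minutes.
#' @param n_cells cells tracked per passage.
#' @param seed integer seed.
#' @return A tibble with columns `passage`, `dormant_fraction` (offspring-
#'   weighted dormant frequency at the passage end), `mean_growth_factor`.
#' @export
simulate_serial_passage <- function(params, n_passages = 5,
                                    growth_window = 150, n_cells = 20000,
                                    seed = 1) {
  p <- params
  if (n_passages < 2) stop("n_passages must be >= 2")
  set.seed(seed)
  n_steps <- round(growth_window / p$dt)
  state <- init_cells(p, n_cells, mode = "stationary")
  res <- vector("list", n_passages)
  for (pass in seq_len(n_passages)) {
    out <- run_kernel(p, state, n_steps, snapshot_steps = n_steps)
    w <- exp(out$logW)
    dorm <- out$snap_mu[, 1] < p$dormant_mu_frac * p$mu_max
    gf <- mean(w)
    if (gf < 1.05) {
      stop("simulated population went extinct (no net growth in passage ",
           pass, ")")
    }
    res[[pass]] <- tibble::tibble(
      passage = pass,
      dormant_fraction = sum(w * dorm) / sum(w),
      mean_growth_factor = gf
    )
    idx <- sample.int(n_cells, n_cells, replace = TRUE, prob = w)
    state <- list(G = out$G[idx], P = out$P[idx], F = out$F[idx],
                  l = out$l[idx], b = out$b[idx], a = out$a[idx])
  }
  do.call(rbind, res)
}

#' Simulate sublethal pretreatment followed by lethal challenge
#'
#' Runs two time-matched arms from the same seed: a pretreated arm with a
#' sublethal antibiotic window (the SasA-like induced synthesis rate `beta2`
#' active, no killing) preceding the lethal challenge, and an untreated
#' control arm on the identical schedule without the sublethal induction.
#' Induction stays active during the lethal phase in both arms (the lethal
#' drug also induces the synthetase). Emits
#' cytometry snapshots before and after the sublethal window plus both kill
#' curves, so the induced low-GTP fraction and the protection ratio can be
#' computed by the analysis modules.
#'
#' @param params a [sim_params()] object with `beta2` configured (e.g. the
#'   `sasA_induction` preset; `beta2 = 0` models a synthetase deletion).
#' @param sublethal_window duration of the sublethal pretreatment, minutes.
#' @param lethal_times kill-curve sampling times, hours.
#' @param n_cells number of cells per arm.
#' @param t_grow unstressed burn-in, minutes.
#' @param flow_delay time between end of the sublethal window and the flow
#'   measurement, minutes (the reporter integrates GTP depletion with a lag).
#' @param seed integer seed.
#' @param ... passed to [simulate_killcurve()] (replicates, `N0`, `lod`).
#' @return A list: `events_before`, `events_after`, `control` (event
#'   tibbles), `kill_pretreated`, `kill_untreated` (kill-curve tables),
#'   `survival_pretreated`, `survival_untreated` (named mean-survival
#'   vectors), `surv_se_*` (Monte-Carlo standard errors), and
#'   `dormant_fraction_before/after` the sublethal window.
#' @export
simulate_antibiotic_induction <- function(params, sublethal_window = 60,
                                          lethal_times = c(1, 2, 3, 4, 5),
                                          n_cells = 30000, t_grow = 300,
                                          flow_delay = 30, seed = 1, ...) {
  p <- params
  run_arm <- function(pretreat, arm_seed) {
    set.seed(arm_seed)
    grow_steps <- round(t_grow / p$dt)
    # both arms run the identical time-matched schedule; only the sublethal
    # induction window differs (the lethal drug induces in both arms)
    pre_steps <- round((sublethal_window + flow_delay) / p$dt)
    kill_steps <- round(max(lethal_times) * 60 / p$dt)
    n_steps <- grow_steps + pre_steps + kill_steps
    ind <- c(rep(FALSE, grow_steps),
             rep(pretreat, pre_steps),
             rep(TRUE, kill_steps))
    abx <- c(rep(FALSE, grow_steps + pre_steps), rep(TRUE, kill_steps))
    state <- init_cells(p, n_cells)
    snaps <- c(grow_steps, grow_steps + pre_steps,
               grow_steps + pre_steps + round(lethal_times * 60 / p$dt))
    out <- run_kernel(p, state, n_steps, induction_on = ind,
                      antibiotic_on = abx, snapshot_steps = snaps)
    out
  }
  arm_seed <- derive_seed(seed, "induction_arm")
  pre <- run_arm(TRUE, arm_seed)
  unt <- run_arm(FALSE, arm_seed)
  set.seed(derive_seed(seed, "induction_measure"))
  n_snap <- ncol(pre$snap_F)
  surv_pre <- colMeans(exp(-pre$snap_Lambda[, 3:n_snap, drop = FALSE]))
  surv_unt <- colMeans(exp(-unt$snap_Lambda[, 3:n_snap, drop = FALSE]))
  se <- function(o) apply(exp(-o$snap_Lambda[, 3:n_snap, drop = FALSE]), 2, sd) /
    sqrt(n_cells)
  dorm <- function(mu) mean(mu < p$dormant_mu_frac * p$mu_max)
  mk_events <- function(F, label) {
    tibble::tibble(sample = label, value = measured_fluor(F, p))
  }
  kc <- function(surv, label) {
    do.call(rbind, lapply(1:3, function(r) {
      eff <- exp(rnorm(1, 0, 0.1))
      tibble::tibble(condition = label, antibiotic = "bacitracin",
                     replicate = r, time_h = c(0, lethal_times),
                     cfu_per_ml = rpois(length(lethal_times) + 1,
                                        1e8 * eff * c(1, surv)),
                     lod = 100)
    }))
  }
  list(
    events_before = mk_events(pre$snap_F[, 1], "before_induction"),
    events_after = mk_events(pre$snap_F[, 2], "after_induction"),
    control = tibble::tibble(sample = "control",
                             value = clip0(rnorm(n_cells, p$af_mean, p$af_sd))),
    kill_pretreated = kc(surv_pre, "pretreated"),
    kill_untreated = kc(surv_unt, "untreated"),
    survival_pretreated = stats::setNames(surv_pre, lethal_times),
    survival_untreated = stats::setNames(surv_unt, lethal_times),
    surv_se_pretreated = se(pre), surv_se_untreated = se(unt),
    dormant_fraction_before = dorm(pre$snap_mu[, 1]),
    dormant_fraction_after = dorm(pre$snap_mu[, 2])
  )
}
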