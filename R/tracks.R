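# Single-cell dormancy-entry analysis: per-interval specific growth rates
# from length tracks, growth-arrest and reporter-threshold detection, the
# rise-precedes-arrest test, and switch-like vs graded classification of the
# growth-reporter relationship.

#' Single-cell track container
#'
#' @param data data frame with columns `track_id`, `frame`, `time_min`,
#'   `length_um`, `fluor_au`, `division` (0/1 flags at frames where the
#'   length resets). One track only.
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(data) {
  req <- c("track_id", "frame", "time_min", "length_um", "fluor_au", "division")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(data$track_id)) != 1L) stop("cell_track holds one track")
  d <- data[order(data$time_min), ]
  if (any(diff(d$time_min) <= 0)) stop("times must be strictly increasing")
  if (any(d$length_um <= 0)) stop("lengths must be > 0")
  if (any(d$fluor_au < 0)) stop("fluorescence must be >= 0")
  div <- as.logical(d$division)
  bad <- which(div[-1] & diff(d$length_um) >= 0) + 1L
  if (length(bad)) {
    stop("division flag at frame(s) ", paste(d$frame[bad], collapse = ", "),
         " without a length decrease")
  }
  structure(list(
    track_id = as.character(d$track_id[1]), times = d$time_min,
    lengths = d$length_um, fluor = d$fluor_au, division_flags = div
  ), class = "cell_track")
}

#' Per-interval specific growth rate
#'
#' For each frame interval not crossing a division,
#' `mu_i = (l_{i+1} - l_i) / (l_i * dt_i)` using the interval-start length
#' (the discrete form of `mu = (1/l) dl/dt`). Intervals ending at a division
#' flag are omitted (`NA`): size resets are not growth. A rolling-median
#' smoothed series is included for arrest detection.
#'
#' @param track a [cell_track()] with at least 2 frames.
#' @param smooth_window rolling-median window, frames (odd; 1 = none).
#' @return An object of class `growth_rate_series`: interval start `times`
#'   (min), `mu` and `smoothed_mu` (/min; `NA` across divisions).
#' @export
specific_growth_rate <- function(track, smooth_window = 3) {
  n <- length(track$times)
  if (n < 2) stop("track must have at least 2 frames")
  dt <- diff(track$times)
  mu <- diff(track$lengths) / (head(track$lengths, -1) * dt)
  mu[track$division_flags[-1]] <- NA_real_
  smoothed <- rolling_median(mu, smooth_window)
  structure(list(times = head(track$times, -1), mu = mu,
                 smoothed_mu = smoothed, track_id = track$track_id),
            class = "growth_rate_series")
}

# centered rolling median ignoring NAs; window shrinks at the edges
rolling_median <- function(x, w) {
  if (w <= 1) return(x)
  half <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else median(win, na.rm = TRUE)
  }, numeric(1))
}

#' Detect growth arrest (entry into dormancy)
#'
#' The arrest time is the start of the first run of at least `w` consecutive
#' intervals whose smoothed growth rate falls below `theta * baseline`.
#' Intervals without a defined rate (division crossings) break a run.
#'
#' @param series a [specific_growth_rate()] result.
#' @param baseline reference growth rate, per minute (> 0); typically the
#'   population median.
#' @param theta arrest fraction of baseline, in (0, 1).
#' @param w minimum run length, intervals.
#' @return Arrest time in minutes, or `NA_real_` when no arrest.
#' @export
detect_growth_arrest <- function(series, baseline, theta = 0.2, w = 3) {
  if (!length(series$mu)) stop("empty growth-rate series")
  stopifnot(baseline > 0, theta > 0, theta < 1, w >= 1)
  below <- !is.na(series$smoothed_mu) & series$smoothed_mu < theta * baseline
  run_start <- first_run(below, w)
  if (is.na(run_start)) NA_real_ else series$times[run_start]
}

# index of the first element of the first run of >= w consecutive TRUEs
first_run <- function(flag, w) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= w)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Detect sustained reporter-threshold crossing
#'
#' First time the reporter fluorescence is at or above `f_thr` for at least
#' `w` consecutive frames.
#'
#' @param track a [cell_track()].
#' @param f_thr fluorescence threshold, a.u. (> 0).
#' @param w minimum run length, frames.
#' @return Crossing time in minutes, or `NA_real_`.
#' @export
detect_threshold_crossing <- function(track, f_thr, w = 2) {
  stopifnot(f_thr > 0, w >= 1)
  run_start <- first_run(track$fluor >= f_thr, w)
  if (is.na(run_start)) NA_real_ else track$times[run_start]
}

#' Extract the dormancy-entry (switch) event of a track
#'
#' Combines arrest and threshold detection and classifies the entry:
#' `"switch_like"` when the smoothed growth rate drops by at least
#' `r_abrupt`-fold within `n_abrupt` intervals of the arrest (the sudden
#' stop in elongation), `"graded"` when arrest is reached by a slower
#' monotone decline, `"none"` without arrest.
#'
#' @param track a [cell_track()].
#' @param baseline reference growth rate, /min.
#' @param f_thr reporter threshold, a.u. (defaults to the cytometry-style
#'   gate value when analyzing a dataset; here an explicit number).
#' @param theta,w_arrest arrest criterion (see [detect_growth_arrest()]).
#' @param w_thr sustained-crossing frames (see [detect_threshold_crossing()]).
#' @param r_abrupt,n_abrupt abruptness rule: fold drop and interval span.
#' @param smooth_window rolling-median window for the growth-rate series.
#' @return An object of class `switch_event`: `track_id`, `t_arrest`,
#'   `t_threshold`, `lag` (`t_arrest - t_threshold`, min), `fluor_at_arrest`,
#'   `classification`.
#' @export
extract_switch_event <- function(track, baseline, f_thr,
                                 theta = 0.2, w_arrest = 3, w_thr = 2,
                                 r_abrupt = 5, n_abrupt = 2,
                                 smooth_window = 3) {
  series <- specific_growth_rate(track, smooth_window)
  t_arrest <- detect_growth_arrest(series, baseline, theta, w_arrest)
  t_thr <- detect_threshold_crossing(track, f_thr, w_thr)
  cls <- "none"
  fluor_at <- NA_real_
  if (!is.na(t_arrest)) {
    i0 <- which(series$times == t_arrest)
    if (i0 == 1) {
      cls <- "switch_like"  # arrested from the first interval
    } else {
      # abrupt if the smoothed rate falls r_abrupt-fold across <= n_abrupt
      # intervals anywhere in a window around the arrest
      s <- series$smoothed_mu
      win <- max(1, i0 - n_abrupt - 1):min(length(s), i0 + n_abrupt)
      cls <- "graded"
      for (i in win) {
        for (d in seq_len(n_abrupt)) {
          j <- i + d
          if (j > max(win)) next
          if (!is.na(s[i]) && !is.na(s[j]) &&
              s[i] >= r_abrupt * max(s[j], 1e-12)) {
            cls <- "switch_like"
          }
        }
      }
    }
    fluor_at <- track$fluor[which.min(abs(track$times - t_arrest))]
  }
  structure(list(
    track_id = track$track_id, t_arrest = t_arrest, t_threshold = t_thr,
    lag = if (!is.na(t_arrest) && !is.na(t_thr)) t_arrest - t_thr else NA_real_,
    fluor_at_arrest = fluor_at, classification = cls
  ), class = "switch_event")
}

switch_events_table <- function(events) {
  do.call(rbind, lapply(events, function(e) {
    tibble::tibble(track_id = e$track_id, t_arrest = e$t_arrest,
                   t_threshold = e$t_threshold, lag = e$lag,
                   fluor_at_arrest = e$fluor_at_arrest,
                   classification = e$classification)
  }))
}

#' Consistency of the arrest-time reporter level
#'
#' Sample mean, standard deviation and coefficient of variation of the
#' reporter fluorescence at arrest across detected events.
#'
#' @param events list of [extract_switch_event()] results (or a table with a
#'   `fluor_at_arrest` column); at least 2 defined values required.
#' @return A tibble with `n`, `mean`, `sd`, `cv`.
#' @export
threshold_consistency <- function(events) {
  v <- if (is.data.frame(events)) events$fluor_at_arrest else {
    vapply(events, function(e) e$fluor_at_arrest, numeric(1))
  }
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 events with a defined arrest-time fluorescence")
  tibble::tibble(n = length(v), mean = mean(v), sd = sd(v),
                 cv = sd(v) / mean(v))
}

#' Does the reporter rise precede growth arrest?
#'
#' Fraction of events with positive lag (`t_arrest > t_threshold`) and a
#' one-sided sign test `P(X >= k | n, 1/2)`; zero lags (ties) are dropped.
#'
#' @param events list of switch events or a table with a `lag` column.
#' @return A tibble with `n`, `n_positive`, `fraction_positive`, `p_value`.
#' @export
precedence_test <- function(events) {
  lag <- if (is.data.frame(events)) events$lag else {
    vapply(events, function(e) e$lag, numeric(1))
  }
  lag <- lag[!is.na(lag) & lag != 0]
  if (!length(lag)) stop("no events with a defined non-zero lag")
  k <- sum(lag > 0); n <- length(lag)
  tibble::tibble(n = n, n_positive = k, fraction_positive = k / n,
                 p_value = pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

logistic4 <- function(logF, bottom, span, logF50, slope) {
  bottom + span / (1 + 10^(slope * (logF - logF50)))
}

#' Variable-slope logistic vs linear growth-reporter relationship
#'
#' Fits pooled `(log10 fluorescence, mu)` points with (i) a four-parameter
#' variable-slope logistic `mu = bottom + (top-bottom)/(1 + 10^{slope (logF -
#' logF50)})` and (ii) a straight line, and selects the model with the lower
#' small-sample-corrected AIC. Wildtype-like data with a sharp transition
#' near the arrest threshold select the logistic; a linear GTP-growth
#' relationship (feedback-less mutants) selects the line.
#'
#' @param log_fluor,mu paired vectors: log10 reporter fluorescence (a.u.)
#'   and specific growth rate (/min); at least 6 points spanning at least
#'   one decade of fluorescence.
#' @return An object of class `growth_reporter_fit`: `chosen_model`
#'   (`"variable_slope_logistic"` or `"linear"`), `logistic` (top, bottom,
#'   logF50, slope, rss, aicc), `linear` (intercept, slope, rss, aicc).
#' @export
fit_growth_vs_reporter <- function(log_fluor, mu) {
  keep <- is.finite(log_fluor) & is.finite(mu)
  log_fluor <- log_fluor[keep]; mu <- mu[keep]
  n <- length(mu)
  if (n < 6) stop("need at least 6 points")
  if (diff(range(log_fluor)) < 1) {
    stop("fluorescence must span at least one decade (got ",
         signif(diff(range(log_fluor)), 3), ")")
  }
  lin <- lm(mu ~ log_fluor)
  rss_lin <- sum(lin$residuals^2)
  obj <- function(par) {
    pred <- logistic4(log_fluor, par[1], par[2], par[3], par[4])
    sum((mu - pred)^2)
  }
  span_mu <- diff(range(mu))
  lower <- c(min(mu) - span_mu, 0, min(log_fluor) - 1, 0.1)
  upper <- c(max(mu), 2.5 * max(span_mu, 1e-12), max(log_fluor) + 1, 50)
  starts <- expand.grid(
    logF50 = quantile(log_fluor, c(0.25, 0.5, 0.75)),
    slope = c(1, 2, 4, 8)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(min(mu), span_mu, starts$logF50[i], starts$slope[i])
    par0 <- pmin(pmax(par0, lower), upper)
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  rss_log <- if (is.null(best)) Inf else best$value
  aicc_lin <- aicc_ls(rss_lin, n, 3)   # intercept, slope, sigma
  aicc_log <- aicc_ls(rss_log, n, 5)   # 4 curve params + sigma
  chosen <- if (aicc_log < aicc_lin) "variable_slope_logistic" else "linear"
  logi <- if (is.null(best)) NULL else list(
    top = best$par[1] + best$par[2], bottom = best$par[1],
    logF50 = unname(best$par[3]), slope = unname(best$par[4]),
    rss = rss_log, aicc = aicc_log)
  structure(list(
    chosen_model = chosen,
    logistic = logi,
    linear = list(intercept = unname(coef(lin)[1]),
                  slope = unname(coef(lin)[2]),
                  rss = rss_lin, aicc = aicc_lin),
    n = n
  ), class = "growth_reporter_fit")
}

#' @export
print.growth_reporter_fit <- function(x, ...) {
  cat("<growth_reporter_fit> chosen:", x$chosen_model,
      sprintf("(AICc logistic %.1f vs linear %.1f, n = %d)\n",
              x$logistic$aicc %||% NA, x$linear$aicc, x$n))
  invisible(x)
}

#' Pooled growth-reporter summary points
#'
#' One `(log10 fluorescence, mu)` summary point per track: the medians of
#' the last `nlast` frames' fluorescence and smoothed growth rate. This is
#' the pooled per-trace summary fed to [fit_growth_vs_reporter()] (pooled
#' across traces, not fitted per trace).
#'
#' @param tracks tibble in the track CSV schema.
#' @param nlast number of trailing frames summarized per track.
#' @param smooth_window rolling-median window for the growth-rate series.
#' @return A tibble with `track_id`, `log_fluor`, `mu`.
#' @export
growth_reporter_points <- function(tracks, nlast = 7, smooth_window = 3) {
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- cell_track(tracks[tracks$track_id == id, ])
    s <- specific_growth_rate(tr, smooth_window)
    n <- length(s$mu)
    idx <- max(1, n - nlast + 1):n
    tibble::tibble(
      track_id = id,
      log_fluor = log10(max(median(tail(tr$fluor, nlast)), 1e-6)),
      mu = median(s$smoothed_mu[idx], na.rm = TRUE)
    )
  }))
}

#' Analyze a set of tracks for dormancy-entry events
#'
#' Convenience driver: computes the population-median growth rate as the
#' arrest baseline, extracts a switch event per track, and summarizes
#' threshold consistency, precedence and the pooled growth-reporter model
#' selection.
#'
#' @param tracks tibble in the track CSV schema (multiple `track_id`s).
#' @param f_thr reporter threshold, a.u. Defaults to the cytometry-module
#'   gate value (5x mean) computed on the matching population snapshot when
#'   available; when `NULL`, set to 5x the mean fluorescence over all frames
#'   of the track set (note track sets enriched for entrance events bias
#'   this fallback upward).
#' @param nlast trailing frames per track pooled into the growth-reporter
#'   fit (see [growth_reporter_points()]).
#' @param ... detector settings passed to [extract_switch_event()].
#' @return A list: `events` (per-track tibble), `baseline`, `f_thr`,
#'   `consistency`, `precedence`, `growth_reporter`
#'   (a [fit_growth_vs_reporter()] result or `NULL` if not fittable).
#' @export
analyze_tracks <- function(tracks, f_thr = NULL, nlast = 7, ...) {
  ids <- unique(tracks$track_id)
  tr_list <- lapply(ids, function(id) cell_track(tracks[tracks$track_id == id, ]))
  all_mu <- unlist(lapply(tr_list, function(tr) {
    specific_growth_rate(tr)$mu
  }))
  baseline <- median(all_mu, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("population-median growth rate is not positive; cannot set baseline")
  }
  if (is.null(f_thr)) f_thr <- 5 * mean(tracks$fluor_au)
  events <- lapply(tr_list, extract_switch_event, baseline = baseline,
                   f_thr = f_thr, ...)
  pts <- growth_reporter_points(tracks, nlast = nlast)
  gr <- tryCatch(fit_growth_vs_reporter(pts$log_fluor, pts$mu),
                 error = function(e) NULL)
  ev_tab <- switch_events_table(events)
  list(
    events = ev_tab, baseline = baseline, f_thr = f_thr,
    consistency = tryCatch(threshold_consistency(ev_tab),
                           error = function(e) NULL),
    precedence = tryCatch(precedence_test(ev_tab), error = function(e) NULL),
    growth_reporter = gr
  )
}

#' Benchmark track set with programmed switch events
#'
#' Generates `n_null` tracks of growing cells (supply noise and measurement
#' noise, no synthesis noise so no spontaneous arrests) and `n_switch`
#' tracks in which a strong basal-synthesis pulse at a random time forces
#' entry into dormancy, using the full stochastic cell model. Ground-truth
#' pulse times are attached.
#'
#' @param params a [sim_params()] object (wildtype-like).
#' @param n_switch,n_null track counts.
#' @param t_end track duration, minutes.
#' @param frame_every frame spacing, minutes.
#' @param pulse_window time window for the programmed pulse start, minutes.
#' @param pulse_beta strength of the programmed synthesis pulse, mM/min.
#' @param pulse_len pulse duration, minutes.
#' @param seed integer seed.
#' @return A list: `tracks` (tibble, all tracks), `truth` (tibble with
#'   `track_id`, `is_switch`, `t_pulse`).
#' @export
make_benchmark_tracks <- function(params, n_switch = 10, n_null = 190,
                                  t_end = 600, frame_every = 15,
                                  pulse_window = c(150, 350),
                                  pulse_beta = 1.6e-3, pulse_len = 60,
                                  seed = 1) {
  p0 <- sim_params(attr(params, "preset") %||% "wildtype", sigma = 0)
  set.seed(seed)
  record_every <- max(1L, round(frame_every / p0$dt))
  n_steps <- round(t_end / p0$dt)
  times <- seq(0, t_end, by = frame_every)
  nfr <- length(times)
  pulse_starts <- runif(n_switch, pulse_window[1], pulse_window[2])
  # the programmed switch is a supercritical synthesis pulse delivered
  # through the induced-synthesis channel
  p_pulse <- sim_params(attr(params, "preset") %||% "wildtype",
                        sigma = 0, beta2 = pulse_beta)
  state0 <- init_cells(p0, n_switch + n_null)
  take <- function(state, i) lapply(state, `[`, i)
  measure <- function(out, j, id) {
    nk <- min(nfr, nrow(out$rec_l))
    tibble::tibble(
      track_id = id, frame = seq_len(nk), time_min = times[seq_len(nk)],
      length_um = out$rec_l[seq_len(nk), j] * exp(rnorm(nk, 0, p0$meas_sd_length)),
      fluor_au = clip0(out$rec_F[seq_len(nk), j] *
                         exp(rnorm(nk, 0, p0$meas_sd_fluor))),
      division = as.integer(out$rec_div[seq_len(nk), j])
    )
  }
  ids_sw <- sprintf("switch_%02d", seq_len(n_switch))
  ids_nu <- sprintf("null_%03d", seq_len(n_null))
  sw <- Map(function(i, pulse_at) {
    s1 <- round(pulse_at / p0$dt)
    s2 <- min(n_steps, s1 + round(pulse_len / p0$dt))
    ind <- seq_len(n_steps) > s1 & seq_len(n_steps) <= s2
    out <- run_kernel(p_pulse, take(state0, i), n_steps, induction_on = ind,
                      record_ids = 1L, record_every = record_every)
    measure(out, 1L, ids_sw[i])
  }, seq_len(n_switch), pulse_starts)
  null_idx <- n_switch + seq_len(n_null)
  out_null <- run_kernel(p0, take(state0, null_idx), n_steps,
                         record_ids = seq_len(n_null),
                         record_every = record_every)
  nu <- lapply(seq_len(n_null), function(j) measure(out_null, j, ids_nu[j]))
  tracks <- rbind(do.call(rbind, sw), do.call(rbind, nu))
  truth <- tibble::tibble(
    track_id = c(ids_sw, ids_nu),
    is_switch = rep(c(TRUE, FALSE), c(n_switch, n_null)),
    t_pulse = c(pulse_starts, rep(NA_real_, n_null))
  )
  list(tracks = tracks, truth = truth)
}
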