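#!/usr/bin/env Rscript

# Stage 1: generate the study datasets from the stochastic alarmone-GTP
# switch simulator. One master seed drives every stage; all downstream
# stages consume only the CSVs written here.

library(persistkit)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Kill curves: wildtype, alarmone-null, no-self-amplification (1e5 cells each)")
kill_tabs <- lapply(c("wildtype", "ppGpp0", "sasB_null_or_F42A"), function(g) {
  simulate_killcurve(sim_params(g), n_cells = 1e5,
                     sample_times = c(0.5, 1, 1.5, 2, 3, 4, 5),
                     seed = derive_seed(seed, paste0("kill/", g)),
                     condition = g)$table
})
readr::write_csv(do.call(rbind, kill_tabs), file.path(out, "kill_curves.csv"))

message("Time-lapse tracks + cytometry snapshot: wildtype and gmk-like mutant")
pop_wt <- simulate_population(sim_params("wildtype"), n_cells = 8000,
                              t_end = 450, n_tracks = 120,
                              seed = derive_seed(seed, "pop/wildtype"))
pop_g <- simulate_population(sim_params("ppGpp0_gmk"), n_cells = 1500,
                             t_end = 450, n_tracks = 100,
                             seed = derive_seed(seed, "pop/gmk"))
cols <- c("track_id", "frame", "time_min", "length_um", "fluor_au", "division")
readr::write_csv(rbind(pop_wt$tracks[cols], pop_g$tracks[cols]),
                 file.path(out, "tracks.csv"))
readr::write_csv(rbind(pop_wt$events, pop_g$events),
                 file.path(out, "events.csv"))
readr::write_csv(rbind(pop_wt$control, pop_g$control),
                 file.path(out, "controls.csv"))

message("Carbon-source panel: snapshots + kill curves for 5 growth conditions")
panel <- carbon_panel()
panel_rows <- lapply(names(panel), function(cn) {
  p <- panel[[cn]]
  pp <- simulate_population(p, n_cells = 20000, t_end = 300,
                            seed = derive_seed(seed, paste0("panel_pop/", cn)),
                            sample_label = cn)
  kk <- simulate_killcurve(p, n_cells = 20000,
                           sample_times = c(1, 2, 3, 4, 5),
                           seed = derive_seed(seed, paste0("panel_kill/", cn)),
                           condition = cn)
  list(events = pp$events, control = pp$control, kill = kk$table,
       growth = tibble::tibble(condition = cn,
                               median_growth_rate = median(pp$states$mu)))
})
readr::write_csv(do.call(rbind, lapply(panel_rows, `[[`, "events")),
                 file.path(out, "panel_events.csv"))
readr::write_csv(do.call(rbind, lapply(panel_rows, `[[`, "control")),
                 file.path(out, "panel_controls.csv"))
readr::write_csv(do.call(rbind, lapply(panel_rows, `[[`, "kill")),
                 file.path(out, "panel_kill_curves.csv"))
readr::write_csv(do.call(rbind, lapply(panel_rows, `[[`, "growth")),
                 file.path(out, "panel_growth.csv"))

message("Sublethal pretreatment experiment (SasA-like induction)")
ind <- simulate_antibiotic_induction(sim_params("sasA_induction"),
                                     n_cells = 20000,
                                     seed = derive_seed(seed, "induction"))
readr::write_csv(rbind(ind$events_before, ind$events_after),
                 file.path(out, "induction_events.csv"))
readr::write_csv(ind$control, file.path(out, "induction_controls.csv"))
readr::write_csv(rbind(ind$kill_pretreated, ind$kill_untreated),
                 file.path(out, "induction_kill_curves.csv"))

message("Serial passage (spontaneous persistence)")
sp <- simulate_serial_passage(sim_params("wildtype"), n_passages = 6,
                              n_cells = 20000,
                              seed = derive_seed(seed, "passage"))
readr::write_csv(sp, file.path(out, "serial_passage.csv"))

message("Done: study datasets under ", out)
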