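#!/usr/bin/env Rscript
# Generates the synthetic study datasets used by the downstream analysis
# scripts: monopolar-spindle images for the polar-ejection-force assay,
# anaphase time-lapses for both segregation regimes, FRAP traces, and
# proliferation well curves. Everything is seeded and written with sidecar
# calibration plus a run manifest, so each dataset is regenerable.

suppressMessages(library(mitoquant))
seed <- 20231L
fix_dir <- "results/fixtures"
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

## Polar ejection force: 10 control-regime cells (3.7 um) and 10 cells with
## collapsed forces (1.6 um), 10% peak noise
pef_truth <- do.call(rbind, lapply(seq_len(20), function(i) {
  r <- if (i <= 10) 3.7 else 1.6
  g <- generate_monopolar(monopolar_spec(ring_radius = r, noise_sd = 100,
                                         seed = seed + i))
  path <- file.path(fix_dir, sprintf("monopolar_%02d.tif", i))
  write_image_stack(g$image, path)
  data.frame(cell_id = sprintf("cell_%02d", i),
             condition = if (i <= 10) "control" else "knockdown",
             file = basename(path), pole_x = 127.5, pole_y = 127.5,
             true_radius_um = r)
}))
write_measurements_csv(pef_truth, file.path(fix_dir, "pef_truth.csv"))

## Anaphase: monotone wild-type-like segregation and a recongression mutant
recongress <- function(t) {
  if (t <= 3) 2 * t else if (t <= 7) 6 - (t - 3) else 2 + (t - 7)
}
trajs <- list(wildtype = function(t) pmin(2.2 * t, 12.9), mutant = recongress)
for (cond in names(trajs)) {
  a <- generate_anaphase(anaphase_spec(trajs[[cond]], mass_sigma = 0.5,
                                       n_frames = 11, noise_sd = 50,
                                       seed = seed + match(cond, names(trajs))))
  write_image_stack(a$chromosomes,
                    file.path(fix_dir, paste0("anaphase_", cond, ".tif")))
  rois <- rbind(
    data.frame(frame = a$poles$frame, role = "pole1",
               x = a$poles$pole1_x, y = a$poles$pole1_y),
    data.frame(frame = a$poles$frame, role = "pole2",
               x = a$poles$pole2_x, y = a$poles$pole2_y))
  write_measurements_csv(rois,
                         file.path(fix_dir, paste0("anaphase_", cond, "_rois.csv")))
  write_measurements_csv(a$truth,
                         file.path(fix_dir, paste0("anaphase_", cond, "_truth.csv")))
}

## FRAP: interphase, metaphase, and anaphase bleaching regimes
frap_specs <- list(
  interphase = frap_spec(bleach_depth = 0.45, mobile_fraction = 1,
                         recovery_tau = 40, noise_sd = 1, seed = seed + 31L),
  metaphase = frap_spec(bleach_depth = 0.18, mobile_fraction = 0.09,
                        recovery_tau = 60, noise_sd = 1, seed = seed + 32L),
  anaphase = frap_spec(bleach_depth = 0.17, mobile_fraction = 0.22,
                       recovery_tau = 60, noise_sd = 1, seed = seed + 33L))
frap_rows <- do.call(rbind, lapply(names(frap_specs), function(ph) {
  g <- generate_frap_trace(frap_specs[[ph]])
  tr <- g$trace
  data.frame(phase = ph, time_s = tr$times, bleached = tr$bleached,
             unbleached = tr$unbleached, background = tr$background,
             postbleach = seq_along(tr$times) >= tr$bleach_index)
}))
write_measurements_csv(frap_rows, file.path(fix_dir, "frap_traces.csv"))

## Proliferation: 12 wells spanning the first-frame density filter window
wells <- do.call(rbind, lapply(seq_len(12), function(i) {
  generate_growth_curve(growth_spec(
    b = 2, tau = 20.72, count_noise_cv = 0.05,
    initial_count = 8000 + 1200 * (i - 1),
    well_id = sprintf("w%02d", i), seed = seed + 40L + i))$curve
}))
write_measurements_csv(wells, file.path(fix_dir, "growth_counts.csv"))

run_manifest(fix_dir, "simulate", config = list(seed = seed), seed = seed)
cat("fixtures written to", fix_dir, "\n")
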