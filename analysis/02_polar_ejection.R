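#!/usr/bin/env Rscript
# Polar-ejection-force assay over the simulated monopolar cells: radial DNA
# profile inside a 12.5 um circle around the pole, distance to the profile
# maximum per cell, and per-condition summaries.

suppressMessages(library(mitoquant))
fix_dir <- "results/fixtures"
truth <- utils::read.csv(file.path(fix_dir, "pef_truth.csv"))

images <- lapply(truth$file, function(f)
  read_image_stack(file.path(fix_dir, f))$frames[[1]])
poles <- Map(point_roi, truth$pole_x, truth$pole_y)
res <- pef_batch(images, poles, cell_ids = truth$cell_id)
res$condition <- truth$condition
res$true_radius_um <- truth$true_radius_um
write_measurements_csv(res, "results/pef_per_cell.csv")

summ <- do.call(rbind, lapply(split(res, res$condition), function(d) {
  ok <- d[d$status == "ok", ]
  data.frame(condition = d$condition[1], n = nrow(ok),
             mean_distance_um = mean(ok$distance_to_max_um),
             sem_um = stats::sd(ok$distance_to_max_um) / sqrt(nrow(ok)),
             mean_abs_error_um = mean(abs(ok$distance_to_max_um -
                                            ok$true_radius_um)))
}))
write_measurements_csv(summ, "results/pef_summary.csv")
run_manifest("results", "pef",
             config = list(max_radius_um = 12.5, bin_width_px = 1),
             inputs = file.path(fix_dir, "pef_truth.csv"))
cat("Polar ejection force, distance to max DAPI signal:\n")
print(summ, row.names = FALSE, digits = 3)
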