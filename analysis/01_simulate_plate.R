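#!/usr/bin/env Rscript
# Simulates the screening plate used throughout the analysis: two compounds
# with equal maximal effect but 10-fold different potency (EC50 50 vs
# 500 nM), dosed over the assay's 9-point 3x dilution series from 10 uM,
# in 3 replicate wells of 3 fields of view each, plus a vehicle condition.
# Stacks are kept as TIFFs + sidecars under scratch/stacks/; the plate
# layout and ground truth go to results/, so later stages can run from disk.

library(axonwrap)

out_dir <- "results"
stack_dir <- file.path("scratch", "stacks")
dir.create(stack_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(fov_shape = c(256L, 256L), noise_sd = 0.02, seed = 1L)
truths <- list(
  T3   = dose_response_truth(bottom = 0.02, top = 0.12, ec50 = 50,  hill = 1),
  cmpB = dose_response_truth(bottom = 0.02, top = 0.12, ec50 = 500, hill = 1))

message("simulating plate (", n_pillars(cfg), " pillars per field) ...")
plate <- generate_plate(truths, cfg, reference = "T3",
                        n_wells = 3L, n_fov = 3L)

for (st in plate$stacks)
  write_stack(st, file.path(stack_dir,
                            sprintf("%s_%s.tif", st$well_id, st$fov_id)))
write_layout(plate$layout, file.path(out_dir, "plate_layout.csv"))
write.csv(plate$truth$conditions, file.path(out_dir, "truth_conditions.csv"),
          row.names = FALSE)
write.csv(plate$truth$axons, file.path(out_dir, "truth_axons.csv"),
          row.names = FALSE)
write.csv(plate$truth$fourpl, file.path(out_dir, "truth_4pl.csv"),
          row.names = FALSE)

message(sprintf("wrote %d stacks; %d wells; true EC50s: %s",
                length(plate$stacks), nrow(plate$layout),
                paste(sprintf("%s = %g nM", plate$truth$fourpl$compound,
                              plate$truth$fourpl$ec50), collapse = ", ")))
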