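#!/usr/bin/env Rscript
# Sheath-length analysis at each compound's peak dose: boxplot statistics
# and normalized histograms of the >80%-wrapped segment lengths, and the
# wrapping index recomputed under stricter length thresholds (> 6 um vs
# > 10 um), which separates "many short sheaths" from "few long sheaths".

library(axonwrap)

out_dir <- "results"
per_axon <- read.csv(file.path(out_dir, "per_axon.csv"))
fov_metrics <- read.csv(file.path(out_dir, "fov_metrics.csv"))
layout <- read_layout(file.path(out_dir, "plate_layout.csv"))
results <- read.csv(file.path(out_dir, "dose_response_results.csv"))

# Re-derive profiles at the peak dose of each compound from the stacks
stack_dir <- file.path("scratch", "stacks")
rows <- list()
for (cp in results$compound) {
  pk <- results$peak_concentration_nM[results$compound == cp]
  wells <- layout$well_id[layout$compound == cp &
                            abs(layout$concentration_nM - pk) < 1e-9]
  profs <- list(); nuclei <- 0
  for (w in wells) {
    for (p in list.files(stack_dir, pattern = paste0("^", w, "_.*\\.tif$"),
                         full.names = TRUE)) {
      q <- quantify_stack(read_stack(p))
      profs <- c(profs, q$profiles)
      nuclei <- nuclei + q$n_nuclei
    }
  }
  lens <- sheath_lengths(profs)
  if (!length(lens)) next
  s <- length_stats(lens)
  rows[[cp]] <- data.frame(
    compound = cp, peak_nM = pk, n_segments = s$n,
    median_um = s$median, q1_um = s$q1, q3_um = s$q3, iqr_um = s$iqr,
    whisker_low_um = s$whisker_low, whisker_high_um = s$whisker_high,
    index_gt6um = index_at_length_threshold(profs, nuclei, 6),
    index_gt10um = index_at_length_threshold(profs, nuclei, 10))
  hist_tab <- length_histogram(lens, min_length = 6, bin_width = 2)
  write.csv(hist_tab,
            file.path(out_dir, sprintf("sheath_histogram_%s.csv", cp)),
            row.names = FALSE)
}
sheath <- do.call(rbind, rows)
write.csv(sheath, file.path(out_dir, "sheath_stats.csv"), row.names = FALSE)
message("sheath-length summary at peak dose:")
for (i in seq_len(nrow(sheath)))
  message(sprintf(
    "  %s: %d segments, median %.1f um (IQR %.1f-%.1f); index >6um %.3f, >10um %.3f",
    sheath$compound[i], sheath$n_segments[i], sheath$median_um[i],
    sheath$q1_um[i], sheath$q3_um[i],
    sheath$index_gt6um[i], sheath$index_gt10um[i]))
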