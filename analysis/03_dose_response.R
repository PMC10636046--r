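#!/usr/bin/env Rscript
# Fits the dose-response structure: aggregates the per-field wrapping index
# per condition (mean +/- SEM over all fields), excludes cytotoxic doses,
# fits 4-parameter logistics with plateau-checked EC50s, and reports
# efficacy, relative efficacy (vs T3) and statistical ranks.

library(axonwrap)

out_dir <- "results"
fov_metrics <- read.csv(file.path(out_dir, "fov_metrics.csv"))
layout <- read_layout(file.path(out_dir, "plate_layout.csv"))

series <- aggregate_conditions(fov_metrics, layout,
                               response = "wrapping_index")
series <- exclude_cytotoxic(series)
results <- efficacy_and_relative(series, reference = "T3")

fovl <- merge(fov_metrics, layout, by = "well_id")
results <- rank_compounds(
  results,
  data.frame(compound = fovl$compound,
             concentration_nM = fovl$concentration_nM,
             response = fovl$wrapping_index))

write.csv(series, file.path(out_dir, "condition_series.csv"),
          row.names = FALSE)
write.csv(results, file.path(out_dir, "dose_response_results.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(out_dir, "truth_4pl.csv"))
for (cp in results$compound) {
  tr <- truth[truth$compound == cp, ]
  message(sprintf(
    "%s: efficacy %.3f (SEM %.3f), relative %.2f, EC50 %.1f nM (truth %.0f), rank %d",
    cp, results$efficacy[results$compound == cp],
    results$efficacy_sem[results$compound == cp],
    results$relative_efficacy[results$compound == cp],
    results$ec50_nM[results$compound == cp], tr$ec50,
    results$rank[results$compound == cp]))
}
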