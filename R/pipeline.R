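#' Quantification configuration
#'
#' All tunables of the segmentation and wrapping stages in one validated
#' list. `axon_link_tolerance_px = NULL` derives the tolerance from the
#' stack (half the expected pillar diameter in px).
#'
#' @param threshold_method,threshold_value,threshold_min_contrast
#'   Thresholding engine settings (see [threshold_channel()]); the contrast
#'   guard keeps structure-free slices from being split on noise.
#' @param cleanup_min_area_px Small-object removal during thresholding.
#' @param axon_link_tolerance_px Max XY centroid drift when linking axon
#'   components across z.
#' @param axon_min_area_px,axon_max_area_px In-plane axon component area
#'   bounds.
#' @param nuclei_min_area_px,nuclei_watershed Nuclei counting settings.
#' @param wrap_threshold Strict per-slice coverage threshold for segments.
#' @param min_segment_length_um Full-wrap minimum contiguous length, um.
#' @param pillar_diameter_um Expected pillar diameter (for the derived link
#'   tolerance).
#' @param sheath_min_length_um,sheath_bin_width_um,sheath_alt_thresholds_um
#'   Sheath-length analysis settings.
#' @param viability_fraction Cytotoxicity exclusion cutoff (fraction of
#'   vehicle nuclei).
#' @param alpha Significance level for rank ties.
#' @return A `quant_config` list.
#' @export
quant_config <- function(threshold_method = "otsu_slice",
                         threshold_value = NULL,
                         threshold_min_contrast = 0.1,
                         cleanup_min_area_px = 5,
                         axon_link_tolerance_px = NULL,
                         axon_min_area_px = 20,
                         axon_max_area_px = Inf,
                         nuclei_min_area_px = 5,
                         nuclei_watershed = FALSE,
                         wrap_threshold = 0.8,
                         min_segment_length_um = 6,
                         pillar_diameter_um = 8,
                         sheath_min_length_um = 6,
                         sheath_bin_width_um = 2,
                         sheath_alt_thresholds_um = c(6, 10),
                         viability_fraction = 0.5,
                         alpha = 0.05) {
  structure(as.list(environment()), class = "quant_config")
}

#' Quantify 3D myelin wrapping in one stack
#'
#' Runs the full per-field pipeline: threshold the three channels, detect
#' and z-link axon pillars, trace outlines and compute per-slice wrap
#' fractions, aggregate into segments and categories, count nuclei on the
#' projection, and compute the field's wrapping index.
#'
#' @param stack An [image_stack()] with axon, myelin and nuclei channels.
#' @param qc A [quant_config()].
#' @return List: `field` (one-row metrics data frame), `profiles` (per-axon
#'   wrap profiles), `n_nuclei`.
#' @export
quantify_stack <- function(stack, qc = quant_config()) {
  link_tol <- qc$axon_link_tolerance_px %||%
    ((qc$pillar_diameter_um / 2) / stack$pixel_size)
  thr <- function(ch) threshold_channel(
    stack, ch, method = qc$threshold_method, value = qc$threshold_value,
    min_area = qc$cleanup_min_area_px,
    min_contrast = qc$threshold_min_contrast)
  axon_masks <- suppressWarnings(thr("axon"))
  myelin_masks <- suppressWarnings(thr("myelin"))
  nuclei_masks <- suppressWarnings(thr("nuclei"))
  regions <- detect_axons(axon_masks, link_tolerance = link_tol,
                          min_area = qc$axon_min_area_px,
                          max_area = qc$axon_max_area_px)
  profiles <- lapply(regions, build_profile, myelin_masks = myelin_masks,
                     z_step = stack$z_step,
                     wrap_threshold = qc$wrap_threshold,
                     min_segment_length = qc$min_segment_length_um)
  n_nuc <- count_nuclei(nuclei_masks, min_area = qc$nuclei_min_area_px,
                        watershed = qc$nuclei_watershed)
  field <- suppressWarnings(
    field_metrics(profiles, n_nuc, stack$well_id, stack$fov_id))
  list(field = field, profiles = profiles, n_nuclei = n_nuc)
}

#' Wrapping-extent category progression per condition
#'
#' For each condition, the percentage of myelin-engaged axons (maximum wrap
#' fraction > 0) in each wrapping category, plus the mean wrapping index —
#' the per-concentration progression of wrapping extent. Conditions with no
#' engaged axons are flagged by `n_engaged = 0` and carry NA percentages.
#'
#' @param profiles_by_condition Named list (condition label ->
#'   list of profiles pooled over that condition's fields).
#' @param index_by_condition Optional named numeric vector of mean wrapping
#'   indices per condition.
#' @return Data frame: `condition`, `n_engaged`, `pct_0_20` ...
#'   `pct_80_100`, `wrapping_index`.
#' @export
summarize_categories <- function(profiles_by_condition,
                                 index_by_condition = NULL) {
  rows <- lapply(names(profiles_by_condition), function(cond) {
    ps <- Filter(function(p) !isTRUE(p$border_touching),
                 profiles_by_condition[[cond]])
    maxf <- vapply(ps, `[[`, numeric(1), "max_fraction")
    engaged <- ps[maxf > 0]
    n <- length(engaged)
    cats <- table(factor(vapply(engaged, function(p)
      as.character(p$category), character(1)),
      levels = c("0-20%", "20-50%", "50-80%", "80-100%")))
    pct <- if (n > 0) 100 * as.numeric(cats) / n else rep(NA_real_, 4)
    data.frame(condition = cond, n_engaged = n,
               pct_0_20 = pct[1], pct_20_50 = pct[2],
               pct_50_80 = pct[3], pct_80_100 = pct[4],
               wrapping_index = if (!is.null(index_by_condition))
                 unname(index_by_condition[cond]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Run the full screen on a set of stacks
#'
#' simulate/load -> quantify every field -> aggregate per condition ->
#' cytotoxicity exclusion -> 4PL fits with plateau-checked EC50 ->
#' efficacy, relative efficacy and ranks -> sheath-length statistics at the
#' peak dose of each compound.
#'
#' @param stacks List of [image_stack()]s.
#' @param layout Plate layout data frame.
#' @param qc A [quant_config()].
#' @param reference Reference compound for relative efficacy.
#' @return List: `fov_metrics`, `series`, `results` (ranked), `fits`,
#'   `sheath` (per-compound stats at peak dose), `categories`
#'   (per-condition category progression), `profiles` (per condition).
#' @export
run_screen <- function(stacks, layout, qc = quant_config(),
                       reference = "T3") {
  layout <- validate_layout(layout)
  wells <- vapply(stacks, `[[`, character(1), "well_id")
  orphan <- setdiff(unique(wells), layout$well_id)
  if (length(orphan))
    abort_validation(paste("stacks with no layout row for well(s):",
                           paste(orphan, collapse = ", ")))
  quant <- lapply(stacks, quantify_stack, qc = qc)
  fov_metrics <- do.call(rbind, lapply(quant, `[[`, "field"))

  layout$cond_label <- sprintf("%s@%g", layout$compound,
                               layout$concentration_nM)
  label_of <- stats::setNames(layout$cond_label, layout$well_id)
  profiles_by_cond <- list()
  for (q in quant) {
    lbl <- label_of[[q$field$well_id]]
    profiles_by_cond[[lbl]] <- c(profiles_by_cond[[lbl]], q$profiles)
  }

  series <- aggregate_conditions(fov_metrics, layout,
                                 response = "wrapping_index")
  series <- exclude_cytotoxic(series, viability_fraction = qc$viability_fraction)
  fits <- lapply(split(series, series$compound), function(s)
    tryCatch(fit_4pl(s), error = function(e)
      list(converged = FALSE, ec50 = NA_real_, hill = NA_real_)))
  results <- efficacy_and_relative(series, reference = reference, fits = fits)

  fovl <- merge(fov_metrics, layout, by = "well_id")
  fov_responses <- data.frame(compound = fovl$compound,
                              concentration_nM = fovl$concentration_nM,
                              response = fovl$wrapping_index)
  if (nrow(results) >= 2)
    results <- rank_compounds(results, fov_responses, alpha = qc$alpha)

  sheath <- lapply(stats::setNames(results$compound, results$compound),
    function(cp) {
      pk <- results$peak_concentration_nM[results$compound == cp]
      ps <- profiles_by_cond[[sprintf("%s@%g", cp, pk)]]
      lens <- sheath_lengths(ps)
      if (!length(lens)) return(NULL)
      c(length_stats(lens),
        list(histogram = length_histogram(lens, qc$sheath_min_length_um,
                                          qc$sheath_bin_width_um)))
    })

  idx <- vapply(names(profiles_by_cond), function(lbl) {
    w <- layout$well_id[layout$cond_label == lbl]
    mean(fov_metrics$wrapping_index[fov_metrics$well_id %in% w], na.rm = TRUE)
  }, numeric(1))
  categories <- summarize_categories(profiles_by_cond, idx)

  list(fov_metrics = fov_metrics, series = series, results = results,
       fits = fits, sheath = sheath, categories = categories,
       profiles = profiles_by_cond)
}

#' Run the pipeline end to end and write result tables
#'
#' Either simulates a plate (when `plate` is given) or reads stacks + layout
#' from disk, runs [run_screen()], and writes per-FOV, per-condition,
#' dose-response and category tables plus a JSON run manifest to `out_dir`.
#' Reruns with the same configuration and seed are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param plate Output of [generate_plate()] (simulated input).
#' @param stack_paths,layout_path Paths to TIFF stacks and the layout CSV
#'   (disk input, used when `plate` is `NULL`).
#' @param qc A [quant_config()].
#' @param reference Reference compound.
#' @param seed Seed recorded in the manifest.
#' @return The [run_screen()] bundle, invisibly.
#' @export
run_pipeline <- function(out_dir, plate = NULL, stack_paths = NULL,
                         layout_path = NULL, qc = quant_config(),
                         reference = "T3", seed = NA_integer_) {
  if (is.null(plate) && (is.null(stack_paths) || is.null(layout_path)))
    abort_validation("provide either a simulated `plate` or stack_paths + layout_path")
  if (!is.null(plate)) {
    stacks <- plate$stacks
    layout <- plate$layout
  } else {
    stacks <- lapply(stack_paths, read_stack)
    layout <- read_layout(layout_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- run_screen(stacks, layout, qc = qc, reference = reference)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$fov_metrics, "fov_metrics.csv")
  wr(bundle$series, "condition_series.csv")
  wr(bundle$results, "dose_response_results.csv")
  wr(bundle$categories, "category_progression.csv")
  manifest <- list(
    seed = seed,
    n_stacks = length(stacks),
    reference = reference,
    quant_config = qc[setdiff(names(qc), character(0))],
    package_version = as.character(utils::packageVersion("axonwrap")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
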