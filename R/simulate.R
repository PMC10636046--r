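#' Four-parameter logistic dose-response curve
#'
#' `R(c) = bottom + (top - bottom) / (1 + (ec50/c)^hill)`. At `c = 0` the
#' curve evaluates to `bottom` (the limit for positive hill slopes).
#'
#' @param conc Concentration(s), nM.
#' @param bottom,top Lower and upper response asymptotes.
#' @param ec50 Concentration of half-maximal response, nM.
#' @param hill Hill slope (dimensionless).
#' @return Response value(s).
#' @export
fourpl <- function(conc, bottom, top, ec50, hill = 1) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Ground-truth parameters for a simulated dose-response series
#'
#' Defaults follow the assay's dosing design: 9 concentrations by 3-fold
#' serial dilution from 10 uM, in triplicate.
#'
#' @param bottom,top Response asymptotes (`top >= bottom`).
#' @param ec50 True EC50, nM (> 0).
#' @param hill Hill slope.
#' @param concentrations Tested concentrations in nM, strictly decreasing by
#'   a constant fold.
#' @param replicate_sd SD of additive replicate noise (response units).
#' @param n_replicates Replicates per concentration.
#' @param seed RNG seed for the replicate noise.
#' @return A `dose_response_truth` object.
#' @export
dose_response_truth <- function(bottom = 0.02, top = 0.12, ec50 = 100,
                                hill = 1,
                                concentrations = 10000 / 3^(0:8),
                                replicate_sd = 0, n_replicates = 3L,
                                seed = 1L) {
  assert_scalar_num(bottom, "bottom"); assert_scalar_num(top, "top")
  if (top < bottom) abort_validation("top must be >= bottom")
  assert_scalar_num(ec50, "ec50", positive = TRUE)
  assert_scalar_num(hill, "hill", positive = TRUE)
  if (length(concentrations) < 2L || any(diff(concentrations) >= 0))
    abort_validation("concentrations must be strictly decreasing")
  folds <- concentrations[-length(concentrations)] / concentrations[-1]
  if (max(folds) / min(folds) - 1 > 1e-6)
    abort_validation("concentrations must decrease by a constant fold")
  if (replicate_sd < 0) abort_validation("replicate_sd must be >= 0")
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill,
                 concentrations = concentrations,
                 replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_response_truth")
}

#' Simulate a tabular dose-response series
#'
#' Evaluates the 4PL at each tested concentration and adds independent
#' Gaussian replicate noise. Deterministic under the truth's seed.
#'
#' @param truth A [dose_response_truth()].
#' @return `data.frame(concentration_nM, replicate, response)`.
#' @export
generate_dose_series <- function(truth) {
  stopifnot(inherits(truth, "dose_response_truth"))
  mu <- fourpl(truth$concentrations, truth$bottom, truth$top,
               truth$ec50, truth$hill)
  n <- length(mu) * truth$n_replicates
  noise <- if (truth$replicate_sd > 0)
    with_seed(truth$seed, rnorm(n, 0, truth$replicate_sd)) else numeric(n)
  data.frame(
    concentration_nM = rep(truth$concentrations, each = truth$n_replicates),
    replicate = rep(seq_len(truth$n_replicates), length(mu)),
    response = rep(mu, each = truth$n_replicates) + noise
  )
}

# Maximal runs of consecutive present slices whose coverage exceeds the wrap
# threshold. `present` marks slices where the pillar exists; absent slices
# break contiguity.
coverage_segments <- function(coverage, present, z_step,
                              wrap_threshold = 0.8) {
  hit <- present & !is.na(coverage) & coverage > wrap_threshold
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_slice = starts[keep],
             n_slices = r$lengths[keep],
             length_um = r$lengths[keep] * z_step)
}

is_fully_wrapped <- function(segments, min_segment_length = 6) {
  nrow(segments) > 0 && any(segments$length_um >= min_segment_length)
}

#' Render one synthetic artificial-axon field of view
#'
#' Renders (i) an axon channel of filled pillar discs on a square grid, in
#' every slice a pillar spans; (ii) a myelin channel of annular arcs
#' concentric with each pillar, whose angular extent equals the requested
#' per-slice coverage (arc start angle drawn from the seeded generator);
#' (iii) a nuclei channel of non-overlapping blobs in the middle slice.
#' Constant background and additive Gaussian noise are applied and
#' intensities clipped to [0, 1]. The returned ground truth describes the
#' rendered geometry exactly.
#'
#' @param config A [sim_config()].
#' @param coverage_spec Angular coverage fractions in [0, 1]: a matrix with
#'   one row per pillar and one column per z-slice (a single number or
#'   per-slice vector is recycled across pillars).
#' @param well_id,fov_id Identifiers stamped on the stack.
#' @param wrap_threshold,min_segment_length Thresholds used to derive the
#'   ground-truth full-wrap flag (defaults: coverage > 0.8 over a contiguous
#'   span of >= 6 um).
#'
#' @return List with `stack` (an [image_stack()]), `axons` (data frame of
#'   per-axon ground truth), `coverage` (the requested coverage matrix,
#'   zeroed beyond the pillar height), `segments` (list of per-axon true
#'   segment tables) and `nuclei_truth` (rendered nuclei count).
#' @export
generate_field <- function(config, coverage_spec,
                           well_id = "W01", fov_id = "F01",
                           wrap_threshold = 0.8, min_segment_length = 6) {
  stopifnot(inherits(config, "sim_config"))
  grid <- pillar_grid(config)
  np <- nrow(grid$centers)
  nz <- config$n_slices
  cov <- coverage_spec
  if (is.list(cov)) cov <- do.call(rbind, cov)
  if (!is.matrix(cov)) cov <- matrix(cov, nrow = np, ncol = nz, byrow = TRUE)
  if (nrow(cov) != np || ncol(cov) != nz)
    abort_validation(sprintf(
      "coverage_spec must be %d pillars x %d slices (got %d x %d)",
      np, nz, nrow(cov), ncol(cov)))
  if (any(is.na(cov)) || any(cov < 0) || any(cov > 1))
    abort_validation("coverage fractions must lie in [0, 1]")

  H <- config$fov_shape[1]; W <- config$fov_shape[2]
  hgt <- config$pillar_height_slices
  r <- grid$radius_px
  t <- config$myelin_ring_thickness
  r_in2 <- max(r - t, 0)^2
  axon <- array(0, c(nz, H, W))
  myelin <- array(0, c(nz, H, W))
  nuclei <- array(0, c(nz, H, W))
  fg <- config$foreground_level

  with_seed(config$seed, {
    theta0 <- matrix(runif(np * nz, 0, 2 * pi), np, nz)

    for (p in seq_len(np)) {
      cy <- grid$centers[p, "row"]; cx <- grid$centers[p, "col"]
      y0 <- max(1L, floor(cy - r - 1)); y1 <- min(H, ceiling(cy + r + 1))
      x0 <- max(1L, floor(cx - r - 1)); x1 <- min(W, ceiling(cx + r + 1))
      dy <- (y0:y1) - cy; dx <- (x0:x1) - cx
      d2 <- outer(dy^2, dx^2, `+`)
      disc <- d2 <= r^2
      ann <- d2 <= r^2 & d2 > r_in2
      phi <- (atan2(outer(dy, rep(1, length(dx))),
                    outer(rep(1, length(dy)), dx))) %% (2 * pi)
      for (z in seq_len(hgt)) {
        win <- axon[z, y0:y1, x0:x1]
        win[disc] <- fg
        axon[z, y0:y1, x0:x1] <- win
        cz <- cov[p, z]
        if (cz > 0) {
          rel <- (phi - theta0[p, z]) %% (2 * pi)
          arc <- if (cz >= 1) ann else ann & rel <= cz * 2 * pi
          win <- myelin[z, y0:y1, x0:x1]
          win[arc] <- fg
          myelin[z, y0:y1, x0:x1] <- win
        }
      }
    }

    # nuclei: rejection-sampled non-overlapping blobs in the middle slice
    nr <- config$nucleus_radius_px
    zmid <- as.integer(ceiling(nz / 2))
    placed <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(placed) < config$n_nuclei) {
      tries <- tries + 1L
      if (tries > 1000L * max(config$n_nuclei, 1L))
        abort_validation("could not place non-overlapping nuclei; field too crowded")
      cand <- c(runif(1, nr + 2, H - nr - 1), runif(1, nr + 2, W - nr - 1))
      if (nrow(placed) == 0 ||
          min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) >
            (2 * nr + 3)^2) {
        placed <- rbind(placed, cand)
        y0 <- floor(cand[1] - nr); y1 <- ceiling(cand[1] + nr)
        x0 <- floor(cand[2] - nr); x1 <- ceiling(cand[2] + nr)
        d2 <- outer(((y0:y1) - cand[1])^2, ((x0:x1) - cand[2])^2, `+`)
        win <- nuclei[zmid, y0:y1, x0:x1]
        win[d2 <= nr^2] <- fg
        nuclei[zmid, y0:y1, x0:x1] <- win
      }
    }

    axon <- axon + config$background_level
    myelin <- myelin + config$background_level
    nuclei <- nuclei + config$background_level
    if (config$noise_sd > 0) {
      nv <- nz * H * W
      axon <- axon + array(rnorm(nv, 0, config$noise_sd), c(nz, H, W))
      myelin <- myelin + array(rnorm(nv, 0, config$noise_sd), c(nz, H, W))
      nuclei <- nuclei + array(rnorm(nv, 0, config$noise_sd), c(nz, H, W))
    }
  })

  clip01 <- function(a) { a[a < 0] <- 0; a[a > 1] <- 1; a }
  data <- array(0, c(3, nz, H, W),
                dimnames = list(c("axon", "myelin", "nuclei"), NULL, NULL, NULL))
  data["axon", , , ] <- clip01(axon)
  data["myelin", , , ] <- clip01(myelin)
  data["nuclei", , , ] <- clip01(nuclei)
  stack <- image_stack(data, config$pixel_size, config$z_step,
                       well_id = well_id, fov_id = fov_id)

  present <- seq_len(nz) <= hgt
  cov[, !present] <- 0
  segs <- lapply(seq_len(np), function(p)
    coverage_segments(cov[p, ], present, config$z_step, wrap_threshold))
  axons <- data.frame(
    axon_id = seq_len(np),
    centroid_row = grid$centers[, "row"],
    centroid_col = grid$centers[, "col"],
    max_coverage = apply(cov, 1, max),
    true_fully_wrapped = vapply(segs, is_fully_wrapped, logical(1),
                                min_segment_length = min_segment_length)
  )
  list(stack = stack, axons = axons, coverage = cov, segments = segs,
       nuclei_truth = config$n_nuclei)
}

# Draw one axon's per-slice coverage profile. Values keep a margin around
# the 0.8 wrap threshold (<= 0.72 or >= 0.87) so that rasterized wrap
# fractions (accurate to ~1-2 outline pixels) classify identically to the
# requested ground truth.
sample_axon_coverage <- function(n_slices, full) {
  cov <- runif(n_slices, 0, 0.45)
  if (full) {
    k <- if (n_slices >= 4) sample(3:min(5, n_slices), 1) else 3L
    k <- min(k, n_slices)
    start <- if (n_slices - k >= 1) sample(seq_len(n_slices - k + 1), 1) else 1L
    cov[start:(start + k - 1)] <- runif(k, 0.88, 0.98)
    return(cov)
  }
  type <- sample(c("none", "low", "mid", "high_short"), 1,
                 prob = c(0.35, 0.30, 0.20, 0.15))
  switch(type,
    none = rep(0, n_slices),
    low = cov,
    mid = {
      j <- sample(seq_len(n_slices), 1)
      cov[j] <- runif(1, 0.55, 0.70)
      cov
    },
    high_short = {
      k <- sample(1:min(2, max(n_slices - 1, 1)), 1)
      start <- sample(seq_len(max(n_slices - k + 1, 1)), 1)
      cov[start:(start + k - 1)] <- runif(k, 0.88, 0.98)
      # guard: never extend the >0.8 run to 3 slices
      if (start > 1) cov[start - 1] <- min(cov[start - 1], 0.45)
      if (start + k <= n_slices) cov[start + k] <- min(cov[start + k], 0.45)
      cov
    })
}

#' Simulate a full screening plate with known ground truth
#'
#' For every compound in `compound_truths` and every concentration of its
#' series, generates `n_wells` replicate wells of `n_fov` fields each. The
#' fraction of fully wrapped pillars per field is set so that the expected
#' wrapping index (fully wrapped axons / nuclei) equals the condition's true
#' 4PL mean response. A vehicle condition (concentration 0, response at the
#' minimum bottom asymptote) is always generated.
#'
#' @param compound_truths Named list of [dose_response_truth()] objects,
#'   one per compound.
#' @param config A [sim_config()]; its seed drives all plate randomness.
#' @param reference Name of the reference compound (must be present).
#' @param n_wells Replicate wells per condition.
#' @param n_fov Fields of view per well.
#' @param nuclei_loss Optional cytotoxicity emulation:
#'   `data.frame(compound, concentration_nM, multiplier)` scaling the nuclei
#'   count of matching conditions.
#'
#' @return List with `stacks` (list of [image_stack()]), `layout`
#'   (plate-layout data frame), and `truth` (`conditions` per-condition truth
#'   table, `axons` per-axon truth rows, `fourpl` true parameters).
#' @export
generate_plate <- function(compound_truths, config, reference = "T3",
                           n_wells = 3L, n_fov = 9L, nuclei_loss = NULL) {
  if (is.null(names(compound_truths)) || any(names(compound_truths) == ""))
    abort_validation("compound_truths must be a named list")
  if (!reference %in% names(compound_truths))
    abort_validation(sprintf("reference compound '%s' missing from compound_truths",
                             reference))
  stopifnot(inherits(config, "sim_config"))
  np <- n_pillars(config)
  nz <- config$n_slices

  conds <- do.call(rbind, lapply(names(compound_truths), function(cp) {
    tr <- compound_truths[[cp]]
    data.frame(compound = cp, concentration_nM = tr$concentrations,
               role = if (cp == reference) "reference" else "test",
               true_mean = fourpl(tr$concentrations, tr$bottom, tr$top,
                                  tr$ec50, tr$hill))
  }))
  vehicle_mean <- min(vapply(compound_truths, `[[`, numeric(1), "bottom"))
  conds <- rbind(conds,
                 data.frame(compound = "vehicle", concentration_nM = 0,
                            role = "vehicle", true_mean = vehicle_mean))

  conds$nuclei_multiplier <- 1
  if (!is.null(nuclei_loss)) {
    for (i in seq_len(nrow(nuclei_loss))) {
      hit <- conds$compound == nuclei_loss$compound[i] &
        abs(conds$concentration_nM - nuclei_loss$concentration_nM[i]) < 1e-9
      conds$nuclei_multiplier[hit] <- nuclei_loss$multiplier[i]
    }
  }
  conds$n_nuclei <- pmax(1L, as.integer(round(config$n_nuclei * conds$nuclei_multiplier)))
  conds$p_full <- conds$true_mean * conds$n_nuclei / np
  if (any(conds$p_full > 1)) {
    warning("true mean response implies >100% fully wrapped pillars; clipping")
    conds$p_full <- pmin(conds$p_full, 1)
  }

  stacks <- list()
  layout <- list()
  axon_truth <- list()
  well_no <- 0L
  fov_counter <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (w in seq_len(n_wells)) {
      well_no <- well_no + 1L
      wid <- sprintf("W%03d", well_no)
      layout[[well_no]] <- data.frame(
        well_id = wid, compound = conds$compound[ci],
        concentration_nM = conds$concentration_nM[ci],
        role = conds$role[ci], replicate = w)
      for (f in seq_len(n_fov)) {
        fov_counter <- fov_counter + 1L
        fid <- sprintf("F%02d", f)
        draw_seed <- (config$seed + 7919L * fov_counter) %% 2147483647L
        cov <- with_seed(draw_seed, {
          full <- runif(np) < conds$p_full[ci]
          list(full = full,
               mat = do.call(rbind, lapply(full, function(fl)
                 sample_axon_coverage(nz, fl))))
        })
        cfg_f <- config
        cfg_f$seed <- (draw_seed + 104729L) %% 2147483647L
        cfg_f$n_nuclei <- conds$n_nuclei[ci]
        fld <- generate_field(cfg_f, cov$mat, well_id = wid, fov_id = fid)
        stacks[[fov_counter]] <- fld$stack
        ax <- fld$axons
        ax$well_id <- wid; ax$fov_id <- fid
        ax$compound <- conds$compound[ci]
        ax$concentration_nM <- conds$concentration_nM[ci]
        axon_truth[[fov_counter]] <- ax
      }
    }
  }

  fourpl_truth <- do.call(rbind, lapply(names(compound_truths), function(cp) {
    tr <- compound_truths[[cp]]
    data.frame(compound = cp, bottom = tr$bottom, top = tr$top,
               ec50 = tr$ec50, hill = tr$hill)
  }))

  list(stacks = stacks,
       layout = do.call(rbind, layout),
       truth = list(conditions = conds,
                    axons = do.call(rbind, axon_truth),
                    fourpl = fourpl_truth))
}
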