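# Brute-force, per-pixel oracles kept independent of the implementation.

# Outline by definition: a region pixel with at least one of its 8
# neighbours outside the region (or outside the image).
brute_outline <- function(mask) {
  mask <- mask != 0
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    boundary <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) ||
          !mask[ii, jj]) boundary <- TRUE
    }
    out[i, j] <- boundary
  }
  out
}

# Wrap fraction by explicit per-pixel counting.
brute_wrap_fraction <- function(outline, myelin) {
  hits <- 0L; tot <- 0L
  for (i in seq_len(nrow(outline))) for (j in seq_len(ncol(outline))) {
    if (outline[i, j]) {
      tot <- tot + 1L
      if (myelin[i, j]) hits <- hits + 1L
    }
  }
  hits / tot
}

# Quantiles by explicit linear interpolation between order statistics
# (h = (n - 1) p + 1), independent of stats::quantile.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

rasterize_disc <- function(dims, center, radius) {
  d2 <- outer((seq_len(dims[1]) - center[1])^2,
              (seq_len(dims[2]) - center[2])^2, `+`)
  d2 <= radius^2
}

# A mask_stack built directly from logical matrices (fixed thresholds).
make_mask_stack <- function(masks, channel = "myelin") {
  structure(list(masks = masks, channel = channel,
                 threshold_record = list(method = "fixed",
                                         value = rep(0.5, length(masks)))),
            class = "mask_stack")
}

# An axon_region for a centred disc present in the slices where
# `present` is TRUE.
make_disc_region <- function(present, dims = c(21L, 21L), radius = 5,
                             axon_id = 1L, border_touching = FALSE) {
  disc <- rasterize_disc(dims, (dims + 1) / 2, radius)
  pix <- which(disc)
  structure(list(
    axon_id = axon_id,
    pixels = lapply(present, function(p) if (p) pix else NULL),
    centroid = (dims + 1) / 2,
    border_touching = border_touching,
    dims = dims), class = "axon_region")
}

# Build an axon_wrap_profile whose per-slice wrap fractions are close to
# `fractions` (NA = axon absent in that slice), by painting the requested
# share of outline pixels myelin-positive and running the real pipeline.
make_profile <- function(fractions, z_step = 2, wrap_threshold = 0.8,
                         min_segment_length = 6, dims = c(21L, 21L),
                         radius = 5, border_touching = FALSE) {
  present <- !is.na(fractions)
  region <- make_disc_region(present, dims, radius,
                             border_touching = border_touching)
  disc <- rasterize_disc(dims, (dims + 1) / 2, radius)
  ol <- which(region_outline(disc))
  masks <- lapply(fractions, function(f) {
    m <- matrix(FALSE, dims[1], dims[2])
    if (!is.na(f) && f > 0) m[ol[seq_len(round(f * length(ol)))]] <- TRUE
    m
  })
  build_profile(region, make_mask_stack(masks), z_step,
                wrap_threshold, min_segment_length)
}

withr_local_tempfile <- function(ext) tempfile(fileext = ext)

# Small noiseless simulation configs used across tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(fov_shape = c(128L, 128L), n_nuclei = 8L,
                   noise_sd = 0, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
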