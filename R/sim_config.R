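#' Simulation configuration for synthetic artificial-axon fields
#'
#' Bundles the geometry and imaging parameters of a simulated field of view:
#' vertical cylindrical pillars (the artificial axons) on a square grid,
#' nuclei blobs, and myelin arcs rendered concentric with each pillar.
#' Defaults reproduce the assay geometry: ~8 um pillar diameter at 20 um
#' centre-to-centre spacing, imaged as 10 z-slices at 2 um step with a 20x
#' air objective (0.65 um/px).
#'
#' @param pixel_size Pixel size in um/px.
#' @param fov_shape Field-of-view shape in pixels, `c(height, width)`.
#' @param n_slices Number of z-slices.
#' @param z_step Axial step between slices, um.
#' @param pillar_diameter Pillar diameter, um.
#' @param pillar_spacing Centre-to-centre pillar spacing, um
#'   (must exceed `pillar_diameter`).
#' @param pillar_height_slices Number of slices each pillar spans, counted
#'   from the first slice; `NULL` means all slices.
#' @param n_nuclei Nuclei blobs rendered per field.
#' @param myelin_ring_thickness Radial thickness of the rendered myelin
#'   annulus, px.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units on the [0, 1] scale).
#' @param background_level Constant background intensity.
#' @param foreground_level Intensity of rendered structures.
#' @param nucleus_radius_px Radius of rendered nuclei blobs, px.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(pixel_size = 0.65,
                       fov_shape = c(512L, 512L),
                       n_slices = 10L,
                       z_step = 2,
                       pillar_diameter = 8,
                       pillar_spacing = 20,
                       pillar_height_slices = NULL,
                       n_nuclei = 40L,
                       myelin_ring_thickness = 2,
                       noise_sd = 0.02,
                       background_level = 0.05,
                       foreground_level = 0.8,
                       nucleus_radius_px = 3,
                       seed = 1L) {
  assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar_num(z_step, "z_step", positive = TRUE)
  assert_scalar_num(pillar_diameter, "pillar_diameter", positive = TRUE)
  assert_scalar_num(pillar_spacing, "pillar_spacing", positive = TRUE)
  if (pillar_diameter >= pillar_spacing)
    abort_validation("pillar_diameter must be smaller than pillar_spacing")
  if (length(fov_shape) != 2L || any(fov_shape < 16))
    abort_validation("fov_shape must be c(height, width) with both >= 16 px")
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L)
    abort_validation("n_slices must be >= 1")
  if (is.null(pillar_height_slices)) pillar_height_slices <- n_slices
  pillar_height_slices <- as.integer(pillar_height_slices)
  if (pillar_height_slices < 1L || pillar_height_slices > n_slices)
    abort_validation("pillar_height_slices must be in [1, n_slices]")
  assert_scalar_num(myelin_ring_thickness, "myelin_ring_thickness", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) abort_validation("noise_sd must be >= 0")
  assert_scalar_num(background_level, "background_level")
  assert_scalar_num(foreground_level, "foreground_level", positive = TRUE)
  assert_scalar_num(nucleus_radius_px, "nucleus_radius_px", positive = TRUE)
  n_nuclei <- as.integer(n_nuclei)
  if (n_nuclei < 0L) abort_validation("n_nuclei must be >= 0")
  structure(list(
    pixel_size = pixel_size,
    fov_shape = as.integer(fov_shape),
    n_slices = n_slices,
    z_step = z_step,
    pillar_diameter = pillar_diameter,
    pillar_spacing = pillar_spacing,
    pillar_height_slices = pillar_height_slices,
    n_nuclei = n_nuclei,
    myelin_ring_thickness = myelin_ring_thickness,
    noise_sd = noise_sd,
    background_level = background_level,
    foreground_level = foreground_level,
    nucleus_radius_px = nucleus_radius_px,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Square-lattice pillar centres, centred in the field with a margin so every
# rendered disc lies strictly inside the image.
pillar_grid <- function(config) {
  r_px <- (config$pillar_diameter / 2) / config$pixel_size
  sp_px <- config$pillar_spacing / config$pixel_size
  margin <- r_px + 2
  centers_axis <- function(len) {
    n <- floor((len - 2 * margin) / sp_px) + 1
    if (n < 1) abort_validation("pillar grid does not fit the field of view")
    start <- (len + 1 - (n - 1) * sp_px) / 2
    start + sp_px * (seq_len(n) - 1)
  }
  ys <- centers_axis(config$fov_shape[1])
  xs <- centers_axis(config$fov_shape[2])
  g <- expand.grid(row = ys, col = xs)
  list(centers = as.matrix(g), radius_px = r_px, spacing_px = sp_px)
}

#' Number of pillars that fit a simulated field
#'
#' @param config A [sim_config()].
#' @return Integer pillar count.
#' @export
n_pillars <- function(config) nrow(pillar_grid(config)$centers)
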