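#' Trace the 1-px inner outline of a region
#'
#' The outline is the region minus its erosion by a 3x3 box structuring
#' element: the set of region pixels with at least one background
#' 8-neighbour. A single-pixel region is its own outline.
#'
#' @param mask Logical matrix with the region foreground.
#' @return Logical matrix marking outline pixels.
#' @export
region_outline <- function(mask) {
  mask <- mask != 0
  if (!any(mask))
    abort_validation("cannot outline an empty region")
  # pad with a background ring: outside the image counts as background
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  er <- EBImage::erode(EBImage::Image(padded * 1), makeBrush(3, "box"))
  er <- matrix(as.numeric(er), nrow(padded))[2:(nrow(mask) + 1L),
                                             2:(ncol(mask) + 1L)]
  mask & !(er > 0.5)
}

#' Build the outline/myelin overlap mask
#'
#' Encodes, for one z-slice, which outline pixels of an axon are
#' myelin-positive: those pixels are assigned 255 and outline pixels with no
#' myelin are assigned 0. Pixels off the outline are `NA` (background).
#'
#' @param outline Logical matrix from [region_outline()].
#' @param myelin Logical myelin mask for the same slice.
#' @return Integer matrix: 255 / 0 on the outline, `NA` elsewhere.
#' @export
overlap_mask <- function(outline, myelin) {
  stopifnot(all(dim(outline) == dim(myelin)))
  out <- matrix(NA_integer_, nrow(outline), ncol(outline))
  out[outline & (myelin != 0)] <- 255L
  out[outline & !(myelin != 0)] <- 0L
  out
}

#' Circumferential wrap fraction of one axon in one slice
#'
#' Fraction of outline pixels that are myelin-positive: the pixel-level
#' estimate of the fraction of the axon's circumference covered by myelin.
#'
#' @inheritParams overlap_mask
#' @return Fraction in [0, 1].
#' @export
wrap_fraction <- function(outline, myelin) {
  n <- sum(outline)
  if (n == 0) abort_validation("wrap_fraction needs a non-empty outline")
  sum(outline & (myelin != 0)) / n
}

# Build a logical slice mask from an axon_region's pixel indices.
region_slice_mask <- function(region, z) {
  m <- matrix(FALSE, region$dims[1], region$dims[2])
  m[region$pixels[[z]]] <- TRUE
  m
}

#' Per-axon wrapping profile across z
#'
#' Computes the wrap fraction in every slice where the axon region is
#' present, then aggregates along z: maximal runs of consecutive slices
#' with fraction strictly above `wrap_threshold` become myelin segments of
#' length `n_slices x z_step` um (slices where the region is undetected
#' break contiguity). The axon is fully wrapped when some segment reaches
#' `min_segment_length` um — at the default 6 um and 2 um z-step, three
#' consecutive >80% slices. The wrapping-extent category bins the maximum
#' per-slice fraction into 0-20 / 20-50 / 50-80 / 80-100%.
#'
#' @param region An `axon_region` from [detect_axons()].
#' @param myelin_masks A `mask_stack` for the myelin channel.
#' @param z_step Axial slice spacing, um.
#' @param wrap_threshold Per-slice coverage a segment slice must exceed
#'   (strict), default 0.8.
#' @param min_segment_length Minimum contiguous segment length for full
#'   wrapping, um (default 6).
#' @return An `axon_wrap_profile`: `axon_id`, `wrap_fraction` (per-slice,
#'   `NA` where absent), `segments` data frame, `max_fraction`, `category`,
#'   `fully_wrapped`, `border_touching`.
#' @export
build_profile <- function(region, myelin_masks, z_step,
                          wrap_threshold = 0.8, min_segment_length = 6) {
  stopifnot(inherits(region, "axon_region"),
            inherits(myelin_masks, "mask_stack"))
  nz <- length(region$pixels)
  present <- !vapply(region$pixels, is.null, logical(1))
  if (!any(present))
    abort_validation("region must be present in at least one slice")
  frac <- rep(NA_real_, nz)
  for (z in which(present)) {
    m <- region_slice_mask(region, z)
    frac[z] <- wrap_fraction(region_outline(m), myelin_masks$masks[[z]])
  }
  segs <- coverage_segments(frac, present, z_step, wrap_threshold)
  max_fraction <- max(frac, na.rm = TRUE)
  structure(list(
    axon_id = region$axon_id,
    wrap_fraction = frac,
    segments = segs,
    max_fraction = max_fraction,
    category = wrap_category(max_fraction),
    fully_wrapped = is_fully_wrapped(segs, min_segment_length),
    border_touching = isTRUE(region$border_touching)
  ), class = "axon_wrap_profile")
}

#' Wrapping-extent category of a maximum wrap fraction
#'
#' Bin edges `[0, 0.2], (0.2, 0.5], (0.5, 0.8], (0.8, 1]`, labelled
#' `0-20%`, `20-50%`, `50-80%`, `80-100%`.
#'
#' @param max_fraction Maximum per-slice wrap fraction in [0, 1].
#' @return Factor with the four category levels.
#' @export
wrap_category <- function(max_fraction) {
  cut(max_fraction, breaks = c(0, 0.2, 0.5, 0.8, 1),
      labels = c("0-20%", "20-50%", "50-80%", "80-100%"),
      include.lowest = TRUE)
}

#' Per-field wrapping metrics and the wrapping index
#'
#' Tallies wrapping categories over myelin-engaged axons (maximum fraction
#' > 0), counts fully wrapped axons, and computes the wrapping index: fully
#' wrapped axons divided by the nuclei count. Border-touching axons are
#' never included. A field with zero nuclei has an undefined index and is
#' flagged invalid with a warning.
#'
#' @param profiles List of `axon_wrap_profile`s for one field.
#' @param n_nuclei Nuclei count of the field.
#' @param well_id,fov_id Identifiers.
#' @return One-row data frame: `well_id`, `fov_id`, `n_axons`, the four
#'   category counts (`cat_0_20` ... `cat_80_100`), `n_fully_wrapped`,
#'   `n_nuclei`, `wrapping_index`, `valid`.
#' @export
field_metrics <- function(profiles, n_nuclei, well_id = "W01", fov_id = "F01") {
  if (n_nuclei < 0) abort_validation("n_nuclei must be >= 0")
  profiles <- Filter(function(p) !isTRUE(p$border_touching), profiles)
  maxf <- vapply(profiles, `[[`, numeric(1), "max_fraction")
  engaged <- maxf > 0
  cats <- table(factor(vapply(profiles[engaged], function(p)
    as.character(p$category), character(1)),
    levels = c("0-20%", "20-50%", "50-80%", "80-100%")))
  nfw <- sum(vapply(profiles, `[[`, logical(1), "fully_wrapped"))
  valid <- n_nuclei > 0
  if (!valid)
    warning(sprintf("field %s/%s has zero nuclei; wrapping index undefined",
                    well_id, fov_id))
  data.frame(
    well_id = well_id, fov_id = fov_id,
    n_axons = length(profiles),
    cat_0_20 = as.integer(cats[["0-20%"]]),
    cat_20_50 = as.integer(cats[["20-50%"]]),
    cat_50_80 = as.integer(cats[["50-80%"]]),
    cat_80_100 = as.integer(cats[["80-100%"]]),
    n_fully_wrapped = as.integer(nfw),
    n_nuclei = as.integer(n_nuclei),
    wrapping_index = if (valid) nfw / n_nuclei else NA_real_,
    valid = valid
  )
}
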