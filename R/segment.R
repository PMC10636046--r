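#' Threshold one channel of a stack into binary masks
#'
#' Produces per-slice boolean masks with a recorded threshold per slice.
#' Methods: `otsu_slice` (Otsu recomputed per slice, the default),
#' `otsu_global` (one Otsu threshold from the pooled stack histogram) and
#' `fixed` (user-supplied value). A slice of constant intensity cannot be
#' bisected and falls back to all-background with a warning. Optional
#' cleanup removes objects below `min_area` px and fills holes.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param method `"otsu_slice"`, `"otsu_global"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"` (intensities > value are
#'   foreground).
#' @param min_area Remove connected foreground objects smaller than this
#'   many pixels (0 disables).
#' @param fill_holes Fill enclosed background holes in foreground objects.
#' @param min_contrast Minimum separation between foreground and background
#'   mean intensities for an automatic threshold to be trusted; a slice
#'   whose Otsu split separates the classes by less than this (e.g. pure
#'   noise, no structures present) is declared all-background with a
#'   warning. 0 disables the guard; ignored for `fixed`.
#' @return A `mask_stack`: list with `masks` (list of logical matrices per
#'   slice) and `threshold_record` (method + per-slice threshold).
#' @export
threshold_channel <- function(stack, channel,
                              method = c("otsu_slice", "otsu_global", "fixed"),
                              value = NULL, min_area = 0, fill_holes = FALSE,
                              min_contrast = 0) {
  method <- match.arg(method)
  slices <- stack_channel(stack, channel)
  if (method == "fixed" && is.null(value))
    abort_validation("fixed thresholding requires `value`")
  thr <- numeric(length(slices))
  if (method == "otsu_global") {
    pooled <- unlist(slices, use.names = FALSE)
    if (diff(range(pooled)) < 1e-12) {
      warning(sprintf("channel '%s' has constant intensity; empty masks", channel))
      gthr <- Inf
    } else gthr <- otsu_threshold(pooled)
  }
  masks <- vector("list", length(slices))
  for (z in seq_along(slices)) {
    s <- slices[[z]]
    th <- switch(method,
      fixed = value,
      otsu_global = gthr,
      otsu_slice = {
        if (diff(range(s)) < 1e-12) {
          warning(sprintf("slice %d of channel '%s' has constant intensity; empty mask",
                          z, channel))
          Inf
        } else otsu_threshold(s)
      })
    thr[z] <- th
    m <- s > th
    if (method != "fixed" && min_contrast > 0 && any(m)) {
      contrast <- if (all(m)) 0 else mean(s[m]) - mean(s[!m])
      if (contrast < min_contrast) {
        warning(sprintf(
          "slice %d of channel '%s': foreground/background contrast %.3g below %.3g; empty mask",
          z, channel, contrast, min_contrast))
        m[] <- FALSE
        thr[z] <- Inf
      }
    }
    if (min_area > 0 && any(m)) {
      lab <- label8(m)
      keep <- which(tabulate(lab[lab > 0L]) >= min_area)
      m <- matrix(lab %in% keep, nrow(m), ncol(m))
    }
    if (fill_holes && any(m))
      m <- EBImage::fillHull(m) > 0
    masks[[z]] <- m
  }
  structure(list(masks = masks, channel = channel,
                 threshold_record = list(method = method, value = thr)),
            class = "mask_stack")
}

# Otsu threshold on raw intensities (256-bin histogram over the observed
# range), returned on the intensity scale.
otsu_threshold <- function(x) {
  rng <- range(x)
  EBImage::otsu(EBImage::Image(matrix(x, ncol = 1)), range = rng, levels = 256)
}

#' Detect pillar axons and link them across z
#'
#' In-plane connected components (8-connectivity) per slice, filtered by
#' area, are linked across z by XY centroid proximity — the pillars are
#' vertical, so no general 3D tracking is needed. Components touching the
#' field border are flagged `border_touching` (their circumference is not
#' fully observable) and are excluded from downstream counts.
#'
#' @param axon_masks A `mask_stack` for the axon channel.
#' @param link_tolerance Maximum XY centroid distance (px) to link a
#'   component to an existing axon.
#' @param min_area,max_area In-plane component area bounds (px).
#' @return List of `axon_region` objects: `axon_id`, `pixels` (per-slice
#'   linear pixel indices, `NULL` where absent), `centroid` (reference
#'   row/col), `border_touching`.
#' @export
detect_axons <- function(axon_masks, link_tolerance = 6,
                         min_area = 10, max_area = Inf) {
  stopifnot(inherits(axon_masks, "mask_stack"))
  nz <- length(axon_masks$masks)
  dims <- dim(axon_masks$masks[[1]])
  regions <- list()
  for (z in seq_len(nz)) {
    m <- axon_masks$masks[[z]]
    if (!any(m)) next
    st <- component_stats(label8(m))
    for (k in seq_along(st$pixels)) {
      if (st$area[k] < min_area || st$area[k] > max_area) next
      cen <- st$centroid[k, ]
      pix <- st$pixels[[k]]
      rows <- (pix - 1L) %% dims[1] + 1L
      cols <- (pix - 1L) %/% dims[1] + 1L
      on_border <- any(rows == 1L | rows == dims[1] |
                       cols == 1L | cols == dims[2])
      hit <- 0L
      if (length(regions)) {
        dists <- vapply(regions, function(r)
          sqrt(sum((r$centroid - cen)^2)), numeric(1))
        if (min(dists) <= link_tolerance) hit <- which.min(dists)
      }
      if (hit == 0L) {
        regions[[length(regions) + 1L]] <- list(
          axon_id = length(regions) + 1L,
          pixels = vector("list", nz),
          centroid = cen, border_touching = FALSE, dims = dims)
        hit <- length(regions)
      }
      regions[[hit]]$pixels[[z]] <- pix
      regions[[hit]]$border_touching <-
        regions[[hit]]$border_touching || on_border
    }
  }
  lapply(regions, function(r) structure(r, class = "axon_region"))
}

#' Count nuclei on the maximum-intensity projection
#'
#' The per-slice nuclei masks are collapsed by logical OR (the mask-level
#' equivalent of a max projection), components below `min_area` px are
#' discarded, and the remaining 8-connected components are counted.
#' Optionally, merged blobs are split by a distance-transform watershed
#' before counting.
#'
#' @param nuclei_masks A `mask_stack` for the nuclei channel.
#' @param min_area Minimum component area in px.
#' @param watershed Split touching blobs via distance-transform watershed.
#' @return Integer nuclei count.
#' @export
count_nuclei <- function(nuclei_masks, min_area = 5, watershed = FALSE) {
  stopifnot(inherits(nuclei_masks, "mask_stack"))
  proj <- Reduce(`|`, nuclei_masks$masks)
  if (!any(proj)) return(0L)
  if (watershed) {
    dm <- EBImage::distmap(EBImage::Image(proj * 1))
    lab <- EBImage::watershed(dm)
    lab <- matrix(as.integer(round(lab)), nrow(proj))
  } else {
    lab <- label8(proj)
  }
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= min_area)
}
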