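#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are written channel-major: all z-slices of the first channel, then
#' the next channel. Acquisition metadata (pixel size, z-step, channel order,
#' well/fov ids) goes to `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- list()
  k <- 0L
  for (ch in stack$channels) for (z in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$data[ch, z, , ], d[3], d[4])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size, z_step_um = stack$z_step,
               channel_order = stack$channels, n_slices = d[2],
               well_id = stack$well_id, fov_id = stack$fov_id)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Metadata comes from the JSON sidecar unless overridden. The declared
#' channel order and slice count must be consistent with the page count;
#' z order is taken as acquisition order and never reordered.
#'
#' @param path TIFF path (sidecar at `<path>.json`).
#' @param channel_map Optional character vector renaming stored channels to
#'   the canonical `axon`/`myelin`/`nuclei` names, e.g.
#'   `c(rhodamine = "axon")`.
#' @param pixel_size,z_step Optional metadata overrides (um).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL,
                       pixel_size = NULL, z_step = NULL) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    abort_validation(sprintf("metadata sidecar not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  channels <- meta$channel_order
  nz <- as.integer(meta$n_slices)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels) * nz)
    abort_validation(sprintf(
      "page count %d inconsistent with %d channels x %d slices",
      length(pages), length(channels), nz))
  if (!is.null(channel_map)) {
    hit <- match(channels, names(channel_map))
    channels[!is.na(hit)] <- unname(channel_map[hit[!is.na(hit)]])
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, c(length(channels), nz, H, W),
                dimnames = list(channels, NULL, NULL, NULL))
  k <- 0L
  for (ci in seq_along(channels)) for (z in seq_len(nz)) {
    k <- k + 1L
    data[ci, z, , ] <- pages[[k]]
  }
  image_stack(data,
              pixel_size = as.numeric(pixel_size %||% meta$pixel_size_um),
              z_step = as.numeric(z_step %||% meta$z_step_um),
              well_id = meta$well_id %||% "W01",
              fov_id = meta$fov_id %||% "F01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a plate layout CSV
#'
#' Required columns: `well_id`, `compound`, `concentration_nM`, `role`
#' (vehicle | reference | test), `replicate`. Well ids must be unique;
#' exactly one compound may carry the reference role; at least one vehicle
#' row is required unless `require_reference = FALSE` workflows drop it.
#'
#' @param path CSV path.
#' @param require_reference Demand a reference row (needed for relative
#'   efficacy); default `TRUE`.
#' @return Validated layout data frame.
#' @export
read_layout <- function(path, require_reference = TRUE) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_layout(layout, require_reference = require_reference)
}

#' @rdname read_layout
#' @param layout A layout data frame to validate in-memory.
#' @export
validate_layout <- function(layout, require_reference = TRUE) {
  need <- c("well_id", "compound", "concentration_nM", "role", "replicate")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    abort_validation(paste("layout missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(layout$well_id))
    abort_validation("duplicate well_id in layout")
  layout$concentration_nM <- as.numeric(layout$concentration_nM)
  if (any(is.na(layout$concentration_nM)))
    abort_validation("concentration_nM must be numeric (nM)")
  bad <- setdiff(unique(layout$role), c("vehicle", "reference", "test"))
  if (length(bad))
    abort_validation(paste("unknown role(s):", paste(bad, collapse = ", ")))
  if (!any(layout$role == "vehicle"))
    abort_validation("layout must contain at least one vehicle well")
  ref <- unique(layout$compound[layout$role == "reference"])
  if (require_reference && length(ref) != 1L)
    abort_validation("layout must flag exactly one compound as reference")
  layout
}

#' Write a plate layout CSV
#'
#' @param layout Layout data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE)
  invisible(path)
}
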