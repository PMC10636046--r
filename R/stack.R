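#' Multi-channel image z-stack
#'
#' Container for one field of view: intensity data indexed
#' `[channel, z, y, x]` plus the acquisition metadata needed to convert
#' pixels and slices into physical lengths. Channel identity is by name
#' (`axon`, `myelin`, `nuclei`), never by page order.
#'
#' @param data Numeric 4-d array `[channel, z, y, x]` with channel dimnames.
#' @param pixel_size Pixel size, um/px.
#' @param z_step Axial slice spacing, um.
#' @param well_id,fov_id Identifiers carried into all result tables.
#'
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size, z_step,
                        well_id = "W01", fov_id = "F01") {
  if (!is.array(data) || length(dim(data)) != 4L)
    abort_validation("data must be a 4-d array [channel, z, y, x]")
  ch <- dimnames(data)[[1]]
  if (is.null(ch) || anyDuplicated(ch))
    abort_validation("channel dimension must carry unique names")
  assert_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar_num(z_step, "z_step", positive = TRUE)
  structure(list(
    data = data,
    channels = ch,
    pixel_size = pixel_size,
    z_step = z_step,
    well_id = as.character(well_id),
    fov_id = as.character(fov_id)
  ), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %s/%s: %d channel(s) [%s], %d slice(s), %d x %d px, %.3g um/px, z-step %.3g um\n",
    x$well_id, x$fov_id, d[1], paste(x$channels, collapse = ", "),
    d[2], d[3], d[4], x$pixel_size, x$z_step))
  invisible(x)
}

#' Extract one channel of a stack as a z-slice list
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return List of `y x x` intensity matrices, one per z-slice in
#'   acquisition order.
#' @export
stack_channel <- function(stack, channel) {
  if (!channel %in% stack$channels)
    abort_validation(sprintf("channel '%s' not present (have: %s)",
                             channel, paste(stack$channels, collapse = ", ")))
  d <- dim(stack$data)
  lapply(seq_len(d[2]), function(z)
    matrix(stack$data[channel, z, , ], nrow = d[3], ncol = d[4]))
}

n_slices_of <- function(stack) dim(stack$data)[2]
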