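#' MBP-positive membrane area of a single-plane field
#'
#' The 2D differentiation readout: threshold the myelin (MBP) channel of a
#' single-plane image with the same engine as the 3D pipeline, optionally
#' drop small objects, and report the foreground area in um^2
#' (pixel count x pixel_size^2). Total area per field of view, not
#' per cell.
#'
#' @param image Either an [image_stack()] with one z-slice or a plain
#'   intensity matrix of the myelin channel.
#' @param pixel_size Pixel size in um/px (taken from the stack when given
#'   one; required for a plain matrix).
#' @param method,value Thresholding method and fixed value
#'   (see [threshold_channel()]).
#' @param min_area Remove foreground objects smaller than this many px.
#' @param well_id,fov_id Identifiers (overridden by the stack's own).
#' @return One-row data frame: `well_id`, `fov_id`, `mbp_area_um2`,
#'   `n_foreground_px`, `threshold`.
#' @export
mbp_area <- function(image, pixel_size = NULL,
                     method = c("otsu_slice", "otsu_global", "fixed"),
                     value = NULL, min_area = 0,
                     well_id = "W01", fov_id = "F01") {
  method <- match.arg(method)
  if (inherits(image, "image_stack")) {
    if (n_slices_of(image) != 1L)
      abort_validation("mbp_area expects a single-plane image")
    pixel_size <- image$pixel_size
    well_id <- image$well_id; fov_id <- image$fov_id
    stack <- image
  } else {
    if (is.null(pixel_size))
      abort_validation("pixel_size is required to convert area to um^2")
    data <- array(image, c(1, 1, nrow(image), ncol(image)),
                  dimnames = list("myelin", NULL, NULL, NULL))
    stack <- image_stack(data, pixel_size, z_step = 1,
                         well_id = well_id, fov_id = fov_id)
  }
  ms <- threshold_channel(stack, "myelin", method = method, value = value,
                          min_area = min_area)
  npx <- sum(ms$masks[[1]])
  data.frame(well_id = well_id, fov_id = fov_id,
             mbp_area_um2 = npx * pixel_size^2,
             n_foreground_px = npx,
             threshold = ms$threshold_record$value[1])
}
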