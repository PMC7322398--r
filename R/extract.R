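#' Extract the bleach-spot ROI trace from an image stack
#'
#' Computes the per-frame mean intensity of pixels whose centers lie
#' within distance `w` of the ROI center, following the package's
#' coordinate convention (top-left origin, (row, col) order, physical
#' position = pixel index times `pixel_size`).
#'
#' The observed membrane disc area `A` used by the geometry QC check is
#' taken from the stack metadata when present
#' (`membrane_radius_um`); otherwise it is measured from the mean
#' pre-bleach frame as the area of pixels above half of the maximum
#' intensity.
#'
#' @param stack an [image_stack()] with a frame schedule.
#' @param center ROI center `c(row_um, col_um)` in physical units;
#'   `NULL` uses the spot center recorded in the stack metadata.
#' @param w ROI radius (um); `NULL` uses the metadata spot radius.
#' @return A [frap_trace()].
#' @export
extract_trace <- function(stack, center = NULL, w = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(stack$schedule))
    stopf("stack has no frame schedule; supply one via image_stack()")
  if (is.null(center)) center <- stack$metadata$center_um
  if (is.null(w)) w <- stack$metadata$spot_radius_um
  if (is.null(center) || is.null(w))
    stopf("ROI center and radius must be given or present in metadata")
  if (!is_num1(w) || w <= 0) stopf("w must be > 0 (um)")

  ps <- stack$pixel_size
  d <- dim(stack$frames)
  cr <- center[1] / ps
  cc <- center[2] / ps
  w_px <- w / ps
  if (cr - w_px < 0.5 || cc - w_px < 0.5 ||
      cr + w_px > d[2] + 0.5 || cc + w_px > d[3] + 0.5)
    stopf("ROI (center %.1f, %.1f um, radius %g um) extends outside the %d x %d image",
          center[1], center[2], w, d[2], d[3])

  rows <- matrix(seq_len(d[2]), d[2], d[3])
  cols <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  roi <- (rows - cr)^2 + (cols - cc)^2 <= w_px^2
  if (!any(roi)) stopf("ROI contains no pixel centers; radius too small")

  vals <- apply(stack$frames, 1, function(fr) mean(fr[roi]))

  area <- if (!is.null(stack$metadata$membrane_radius_um)) {
    pi * stack$metadata$membrane_radius_um^2
  } else {
    pre_idx <- seq_len(stack$schedule$n_pre)
    pre_mean <- apply(stack$frames[pre_idx, , , drop = FALSE], c(2, 3), mean)
    sum(pre_mean > max(pre_mean) / 2) * ps^2
  }

  ft <- frame_times(stack$schedule)
  frap_trace(ft$time_s, vals, stack$schedule,
             spot_geometry(w, area, stack$schedule$t_bleach))
}
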