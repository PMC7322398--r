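#' Image stack container
#'
#' A single-channel time-lapse image stack: a 3-D array indexed
#' `(time, y, x)` with physical pixel size, frame schedule and free-form
#' metadata.  Image coordinates follow the top-left origin, (row, col)
#' convention with pixel centers at integer pixel coordinates; physical
#' positions are pixel coordinates times `pixel_size`.
#'
#' @param frames numeric 3-D array `(time, y, x)`, all values `>= 0`.
#' @param pixel_size physical pixel size (um/px), `> 0`.
#' @param schedule a [frame_schedule()] or `NULL`.
#' @param metadata named list of free-form key/value metadata.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, schedule = NULL, metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stopf("frames must be a 3-D array (time, y, x)")
  if (any(frames < 0)) stopf("intensities must be >= 0")
  if (!is_num1(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0 (um/px)")
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "frame_schedule"))
    if (dim(frames)[1] != schedule$n_pre + schedule$n_post)
      stopf("frame count %d does not match schedule", dim(frames)[1])
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 schedule = schedule, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%g um/px)\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Render a FRAP measurement as a confocal-like image stack
#'
#' Draws the bottom of a GUV as a bright fluorescent disc of radius
#' `reservoir_radius` with an evolving dark bleach spot at its center.
#' Spot pixels carry the current noise-free ROI mean of
#' [generate_trace()] for the same configuration, so extracting the
#' spot ROI from the rendered stack reproduces the trace.  An optional
#' Gaussian blur emulates the point-spread function, and per-pixel
#' Gaussian or Poisson noise emulates the detector.
#'
#' @param config a [sim_config()] with finite `reservoir_radius`.
#' @param pixel_size um per pixel (default 0.2).
#' @param blur_sd PSF Gaussian sd in um (0 disables blurring).
#' @param noise `"none"`, `"gaussian"` (per-pixel sd `sigma_noise`) or
#'   `"poisson"` (per-pixel counts with the noise-free mean).
#' @param margin_px empty border around the membrane disc, in pixels.
#' @return An [image_stack()]; metadata records the spot center (um),
#'   spot radius and membrane radius.
#' @export
render_frap_stack <- function(config, pixel_size = 0.2, blur_sd = 0,
                              noise = c("none", "gaussian", "poisson"),
                              margin_px = 4) {
  stopifnot(inherits(config, "sim_config"))
  noise <- match.arg(noise)
  if (!is_num1(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0 (um/px)")
  if (!is.finite(config$reservoir_radius))
    stopf("rendering requires a finite reservoir_radius")
  if (!is.null(config$seed)) set.seed(config$seed)

  # noise-free ROI trace drives the spot intensity; noise is added per pixel
  cfg0 <- config
  cfg0$sigma_noise <- 0
  cfg0$seed <- NULL
  trace <- if (config$curve_model == "lattice")
    simulate_lattice_frap(cfg0) else generate_trace(cfg0)

  R_px <- config$reservoir_radius / pixel_size
  w_px <- config$w / pixel_size
  side <- ceiling(2 * R_px) + 2 * margin_px
  c_px <- (side + 1) / 2
  rows <- matrix(seq_len(side), side, side)
  cols <- t(rows)
  d2 <- (rows - c_px)^2 + (cols - c_px)^2
  in_disc <- d2 <= R_px^2
  in_spot <- d2 <= w_px^2

  n_frames <- length(trace$times)
  frames <- array(0, dim = c(n_frames, side, side))
  for (k in seq_len(n_frames)) {
    img <- matrix(0, side, side)
    img[in_disc] <- config$F_pre
    if (trace$phase[k] == "post") img[in_spot] <- trace$intensities[k]
    if (blur_sd > 0)
      img <- EBImage::gblur(img, sigma = blur_sd / pixel_size)
    if (noise == "gaussian" && config$sigma_noise > 0)
      img <- img + matrix(rnorm(side^2, sd = config$sigma_noise), side, side)
    if (noise == "poisson")
      img <- matrix(rpois(side^2, lambda = pmax(img, 0)), side, side)
    frames[k, , ] <- pmax(img, 0)
  }

  image_stack(frames, pixel_size, trace$schedule,
              metadata = list(center_um = c(c_px, c_px) * pixel_size,
                              spot_radius_um = config$w,
                              membrane_radius_um = config$reservoir_radius))
}
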