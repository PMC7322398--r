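#' Configuration for a simulated composition dataset
#'
#' Describes a binary lipid system imaged at several mixing ratios.
#' Each group carries the relative concentration `x_rel` of the
#' fluorescently labelled lipid (1, 2 and 3 for the 3:1, 2:2 and 1:3
#' non-fluorescent:fluorescent mixtures); per-vesicle ring intensity is
#' `brightness_per_unit * x_rel` plus Gaussian noise, truncated at 0.
#'
#' @param groups named numeric vector mapping group labels to `x_rel`
#'   (default `c("3:1" = 1, "2:2" = 2, "1:3" = 3)`).
#' @param n_per_group vesicles per group (default 50).
#' @param brightness_per_unit intensity per unit `x_rel` (a.u.), `> 0`.
#' @param sigma_noise per-vesicle intensity sd (a.u.), `>= 0`.
#' @param render_images also render equatorial-ring images per vesicle.
#' @param seed integer seed or `NULL`.
#' @return An object of class `composition_sim_config`.
#' @export
composition_sim_config <- function(groups = c("3:1" = 1, "2:2" = 2, "1:3" = 3),
                                   n_per_group = 50,
                                   brightness_per_unit = 10,
                                   sigma_noise = 1,
                                   render_images = FALSE,
                                   seed = NULL) {
  if (!length(groups)) stopf("groups must be non-empty")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be a named vector (label -> x_rel)")
  if (any(!is.finite(groups)) || any(groups <= 0)) stopf("x_rel must be > 0")
  if (!is_count(n_per_group) || n_per_group < 1)
    stopf("n_per_group must be an integer >= 1")
  if (!is_num1(brightness_per_unit) || brightness_per_unit <= 0)
    stopf("brightness_per_unit must be > 0")
  if (!is_num1(sigma_noise) || sigma_noise < 0) stopf("sigma_noise must be >= 0")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 brightness_per_unit = brightness_per_unit,
                 sigma_noise = sigma_noise,
                 render_images = isTRUE(render_images),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "composition_sim_config")
}

#' Simulate a composition dataset
#'
#' @param config a [composition_sim_config()].
#' @param system label for the lipid system (e.g. `"PCPE"`).
#' @return A data frame (class `composition_dataset`) with columns
#'   `vesicle_id`, `system`, `group`, `x_rel`, `intensity`.  When
#'   `render_images` is set, a list of equatorial-ring images (one per
#'   vesicle) is attached as attribute `"images"`.
#' @export
generate_composition_dataset <- function(config, system = "synthetic") {
  stopifnot(inherits(config, "composition_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_per_group
  records <- do.call(rbind, lapply(seq_along(config$groups), function(i) {
    x <- config$groups[[i]]
    mu <- config$brightness_per_unit * x
    data.frame(
      vesicle_id = sprintf("%s_%s_%03d", system, names(config$groups)[i],
                           seq_len(n)),
      system = system,
      group = names(config$groups)[i],
      x_rel = x,
      intensity = pmax(mu + rnorm(n, sd = config$sigma_noise), 0),
      stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL

  if (config$render_images) {
    attr(records, "images") <- lapply(records$intensity, function(I)
      render_ring_image(ring_intensity = I))
  }
  class(records) <- c("composition_dataset", "data.frame")
  records
}

#' Render a synthetic equatorial-ring image
#'
#' Draws the bright circle seen when the confocal plane cuts a vesicle
#' at its equator: an annulus of the given intensity over a uniform
#' background.  Used for end-to-end tests of the ring measurement.
#'
#' @param ring_intensity intensity of the ring above background (a.u.).
#' @param radius_px ring radius in pixels.
#' @param band_px ring thickness in pixels.
#' @param size image side length in pixels.
#' @param background background level (a.u.).
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param center ring center `c(row, col)` in pixels; `NULL` centers it.
#' @return A `size x size` matrix.
#' @export
render_ring_image <- function(ring_intensity, radius_px = 20, band_px = 3,
                              size = 64, background = 0, noise_sd = 0,
                              center = NULL) {
  if (!is_num1(ring_intensity) || ring_intensity < 0)
    stopf("ring_intensity must be >= 0")
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dist <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  img <- matrix(background, size, size)
  img[abs(dist - radius_px) <= band_px / 2] <- background + ring_intensity
  if (noise_sd > 0) img <- img + matrix(rnorm(size^2, sd = noise_sd), size, size)
  pmax(img, 0)
}
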