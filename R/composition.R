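#' Measure the mean intensity of a vesicle's equatorial ring
#'
#' Locates the bright ring in a single confocal frame and returns its
#' background-subtracted mean intensity.  The center is refined by
#' intensity centroid, the ring radius is the argmax of the radial
#' mean-intensity profile, the ring mean is taken over an annulus of
#' `band_width` pixels centered on that radius, and the background is
#' the median intensity beyond 1.5 times the ring radius.
#'
#' When the radial profile has more than one local peak of comparable
#' height (nested rings), the brighter one is returned with a warning.
#'
#' @param image 2-D numeric matrix.
#' @param pixel_size um per pixel (default 1; geometry fields are then
#'   in pixels).
#' @param seed_center initial center `c(row, col)` in pixels, or `NULL`
#'   to start from the image intensity centroid.
#' @param band_width annulus thickness in pixels (default 3).
#' @param vesicle_id optional identifier carried into the result.
#' @return An object of class `ring_measurement`: `vesicle_id`,
#'   `center` (um), `radius` (um), `band_width` (um), `mean_intensity`
#'   (background-subtracted, a.u.), `background` (a.u.).
#' @export
measure_ring_intensity <- function(image, pixel_size = 1, seed_center = NULL,
                                   band_width = 3, vesicle_id = NA_character_) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("image must be a numeric matrix")
  if (!is_num1(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")

  rows <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)

  # intensity-weighted centroid, computed above the median to ignore background
  refine_center <- function(start) {
    fg <- image - median(image)
    fg[fg < 0] <- 0
    if (sum(fg) == 0) return(start)
    c(sum(rows * fg) / sum(fg), sum(cols * fg) / sum(fg))
  }
  center <- refine_center(if (is.null(seed_center))
    c((nrow(image) + 1) / 2, (ncol(image) + 1) / 2) else seed_center)

  dist <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  bin <- round(dist)
  prof <- tapply(as.vector(image), as.vector(bin), mean)
  radii <- as.numeric(names(prof))
  usable <- radii <= min(nrow(image), ncol(image)) / 2
  prof <- prof[usable]
  radii <- radii[usable]

  bg_floor <- median(image)
  peak_idx <- which.max(prof)
  if (prof[peak_idx] <= bg_floor + 1e-12)
    stopf("no radial intensity peak above background: no ring detected")

  # local maxima above a fraction of the global peak flag nested rings
  is_peak <- vapply(seq_along(prof), function(i) {
    lo <- max(1, i - 1); hi <- min(length(prof), i + 1)
    prof[i] == max(prof[lo:hi]) &&
      prof[i] > bg_floor + 0.25 * (prof[peak_idx] - bg_floor)
  }, logical(1))
  runs <- rle(is_peak)
  n_peaks <- sum(runs$values)
  if (n_peaks > 1)
    warnf("%d candidate rings detected; returning the brightest", n_peaks)

  # a thick ring produces a flat-topped radial peak; take the centroid of
  # the near-maximal plateau rather than the first maximal bin
  plateau <- prof >= bg_floor + 0.95 * (prof[peak_idx] - bg_floor)
  plateau_run <- cumsum(!plateau)[plateau] == cumsum(!plateau)[peak_idx]
  radius <- mean(radii[plateau][plateau_run])
  annulus <- abs(dist - radius) <= band_width / 2
  outside <- dist > 1.5 * radius
  background <- if (any(outside)) median(image[outside]) else 0
  structure(list(vesicle_id = vesicle_id,
                 center = center * pixel_size,
                 radius = radius * pixel_size,
                 band_width = band_width * pixel_size,
                 mean_intensity = mean(image[annulus]) - background,
                 background = background),
            class = "ring_measurement")
}

#' Zero-intercept regression slope of intensity on labelled-lipid content
#'
#' Least-squares line through the origin, pooled over all vesicles of
#' one lipid system:
#' \deqn{s = \frac{\sum_i x_i I_i}{\sum_i x_i^2}.}
#'
#' @param records data frame with columns `x_rel` and `intensity`, or a
#'   [generate_composition_dataset()] result.
#' @return The fitted slope `s` (a.u. per unit `x_rel`).
#' @export
fit_zero_intercept <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("x_rel", "intensity") %in% names(records)))
    stopf("records must have columns x_rel and intensity")
  x <- records$x_rel
  I <- records$intensity
  if (length(x) < 2) stopf("need at least 2 records to fit a slope")
  if (sum(x^2) == 0) stopf("all x_rel are zero; slope undefined")
  sum(x * I) / sum(x^2)
}

#' Normalize intensities by the fitted slope
#'
#' Divides each vesicle intensity by the slope of the zero-intercept
#' regression for its lipid system, so the normalized values scale
#' directly with the relative labelled-lipid concentration: expected
#' values 1, 2 and 3 for the 3:1, 2:2 and 1:3 mixtures.
#'
#' @param records data frame with columns `x_rel` and `intensity`.
#' @param slope slope `s > 0`; `NULL` fits it via
#'   [fit_zero_intercept()].
#' @return `records` with an added `normalized` column and the slope in
#'   attribute `"slope"`.
#' @export
normalize_intensities <- function(records, slope = NULL) {
  records <- as.data.frame(records)
  if (is.null(slope)) slope <- fit_zero_intercept(records)
  if (!is_num1(slope) || slope <= 0) stopf("slope must be > 0")
  records$normalized <- records$intensity / slope
  attr(records, "slope") <- slope
  records
}

#' Per-group summary of normalized composition values
#'
#' Reports, per mixing-ratio group: mean, sample standard deviation, N,
#' and the boxplot statistics used for display — median, quartiles,
#' whiskers at the smallest and largest value of the set, and the count
#' of values beyond 1.5 IQR from the quartiles.  Outliers are flagged
#' for display purposes only; they stay in every statistic.
#'
#' @param records data frame with columns `group`, `x_rel` and
#'   `normalized` (see [normalize_intensities()]).
#' @return A data frame with one row per group, ordered by `x_rel`.
#' @export
summarize_composition <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("group", "normalized") %in% names(records)))
    stopf("records must have columns group and normalized")
  groups <- unique(records[, intersect(c("group", "x_rel"), names(records)),
                           drop = FALSE])
  if ("x_rel" %in% names(groups)) groups <- groups[order(groups$x_rel), , drop = FALSE]
  out <- do.call(rbind, lapply(groups$group, function(g) {
    v <- records$normalized[records$group == g]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)  # linear interpolation
    iqr <- q[3] - q[1]
    data.frame(group = g, n = length(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
               median = q[2], q1 = q[1], q3 = q[3],
               whisker_low = min(v), whisker_high = max(v),
               n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
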