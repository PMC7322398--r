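#' Raw bleach-spot intensity trace
#'
#' Per-frame mean intensity of the bleach-spot ROI, together with the
#' frame schedule, spot geometry and optional movement information.
#' Times use the convention of [frame_times()]: origin at the first
#' recovery frame, negative times for pre-bleach frames.
#'
#' @param times per-frame acquisition times (s), strictly increasing.
#' @param intensities per-frame ROI mean intensities (a.u.), finite.
#' @param schedule a [frame_schedule()].
#' @param geometry a [spot_geometry()].
#' @param phase character vector of `"pre"`/`"post"` per frame, or
#'   `NULL` to derive it from the schedule.
#' @param movement optional observed vesicle displacement (um) during
#'   the measurement, or a logical exclusion flag.
#' @param condition optional condition label.
#' @param vesicle_id optional identifier.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, intensities, schedule, geometry,
                       phase = NULL, movement = NULL,
                       condition = NA_character_, vesicle_id = NA_character_) {
  if (length(times) != length(intensities))
    stopf("times and intensities must have equal length")
  if (any(!is.finite(intensities))) stopf("intensities must be finite")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  stopifnot(inherits(schedule, "frame_schedule"),
            inherits(geometry, "spot_geometry"))
  if (length(times) != schedule$n_pre + schedule$n_post)
    stopf("trace length %d does not match schedule (%d frames)",
          length(times), schedule$n_pre + schedule$n_post)
  if (is.null(phase))
    phase <- rep(c("pre", "post"), c(schedule$n_pre, schedule$n_post))
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 phase = phase, schedule = schedule, geometry = geometry,
                 movement = movement, condition = condition,
                 vesicle_id = vesicle_id),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %s: %d frames (%d pre, %d post), w = %g um\n",
              ifelse(is.na(x$vesicle_id), "unnamed", x$vesicle_id),
              length(x$times), x$schedule$n_pre, x$schedule$n_post,
              x$geometry$w))
  invisible(x)
}

trace_recovery <- function(trace) {
  keep <- trace$phase == "post"
  list(times = trace$times[keep], intensities = trace$intensities[keep])
}

trace_prebleach <- function(trace) {
  trace$intensities[trace$phase == "pre"]
}
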