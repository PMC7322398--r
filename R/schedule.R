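#' Acquisition frame schedule for a FRAP measurement
#'
#' Describes the timing of a bleach-spot acquisition: a block of
#' pre-bleach frames, a bleach pulse, and a block of recovery frames.
#' The time origin `t = 0` is the first recovery frame; pre-bleach
#' frames carry negative times.
#'
#' @param n_pre number of pre-bleach frames (default 8).
#' @param t_bleach bleach pulse duration in seconds (default 0.1 s).
#' @param n_post number of recovery frames (default 100).
#' @param dt frame interval in seconds (default 0.2 s).
#'
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(n_pre = 8, t_bleach = 0.1, n_post = 100, dt = 0.2) {
  if (!is_count(n_pre) || n_pre < 1) stopf("n_pre must be an integer >= 1")
  if (!is_count(n_post) || n_post < 2) stopf("n_post must be an integer >= 2")
  if (!is_num1(dt) || dt <= 0) stopf("dt must be a positive number (s)")
  if (!is_num1(t_bleach) || t_bleach < 0) stopf("t_bleach must be >= 0 (s)")
  structure(list(n_pre = as.integer(n_pre), t_bleach = t_bleach,
                 n_post = as.integer(n_post), dt = dt),
            class = "frame_schedule")
}

#' Frame times and phases for a schedule
#'
#' Pre-bleach frames end one pulse length before `t = 0`; recovery
#' frames start at `t = 0` and are spaced by `dt`.
#'
#' @param schedule a [frame_schedule()].
#' @return A data frame with columns `frame`, `time_s`, `phase`
#'   (`"pre"` or `"post"`).
#' @export
frame_times <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  pre <- -schedule$t_bleach - (schedule$n_pre:1 - 1) * schedule$dt
  post <- (seq_len(schedule$n_post) - 1) * schedule$dt
  data.frame(
    frame = seq_len(schedule$n_pre + schedule$n_post),
    time_s = c(pre, post),
    phase = rep(c("pre", "post"), c(schedule$n_pre, schedule$n_post)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d pre-bleach + %d recovery frames, dt = %g s, bleach pulse %g s\n",
    x$n_pre, x$n_post, x$dt, x$t_bleach))
  invisible(x)
}
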