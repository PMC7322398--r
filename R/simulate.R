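#' Simulate a bleach-spot recovery trace
#'
#' Generates the ROI-mean intensity time series of one simulated FRAP
#' measurement.  Pre-bleach frames sit at the pre-bleach intensity
#' `F_pre`; the bleach pulse is treated as instantaneous, so the first
#' recovery frame has noise-free mean `F(0) = F_pre (1 - beta)`.
#' Recovery frames follow
#' \deqn{F(t) = F(0) + (F_\infty - F(0))\, g(t),}
#' with plateau `F_inf = F(0) + M_true (F_pre - F(0))` and `g` the
#' configured curve model (closed-form disk recovery, or the matched
#' exponential whose half-crossing coincides with the closed form's).
#' Zero-mean Gaussian noise of sd `sigma_noise` is added to every frame.
#'
#' @param config a [sim_config()]; `curve_model` must not be
#'   `"lattice"` (use [simulate_lattice_frap()] for that).
#' @return A [frap_trace()].
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$curve_model == "lattice")
    return(simulate_lattice_frap(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  sched <- config$schedule
  ft <- frame_times(sched)
  t_post <- ft$time_s[ft$phase == "post"]

  F0 <- config$F_pre * (1 - config$beta)
  Finf <- F0 + config$M_true * (config$F_pre - F0)
  g <- switch(config$curve_model,
    closed_form = soumpasis_fractional(t_post, config$w, config$D_true),
    exponential_model = {
      a <- log(2) / (solve_half_time_constant() * config$w^2 / config$D_true)
      1 - exp(-a * t_post)
    })
  means <- c(rep(config$F_pre, sched$n_pre), F0 + (Finf - F0) * g)
  noisy <- means + rnorm(length(means), sd = config$sigma_noise)

  area <- if (is.finite(config$reservoir_radius))
    pi * config$reservoir_radius^2 else Inf
  frap_trace(ft$time_s, noisy, sched,
             spot_geometry(config$w, area, sched$t_bleach))
}

#' Simulate a labelled cohort of FRAP traces across conditions
#'
#' Draws `n_per_condition` traces for each requested condition, using
#' the preset condition mean as the generator ground truth `D_true`.
#'
#' @param conditions character vector of condition names from
#'   [frap_presets()], or a data frame with at least columns
#'   `condition` and `D` (optionally `N`).
#' @param n_per_condition traces per condition, `>= 1`; `NULL` uses the
#'   preset per-condition `N`.
#' @param seed integer seed for the whole cohort.
#' @param ... further arguments passed to [sim_config()] (e.g.
#'   `sigma_noise`, `curve_model`, `schedule`).
#' @return A list of [frap_trace()] objects with `condition` and
#'   `vesicle_id` filled in.
#' @export
generate_cohort <- function(conditions, n_per_condition = NULL, seed = NULL, ...) {
  presets <- if (is.data.frame(conditions)) conditions else {
    all <- frap_presets()
    missing <- setdiff(conditions, all$condition)
    if (length(missing))
      stopf("unknown condition preset(s): %s", paste(missing, collapse = ", "))
    all[match(conditions, all$condition), , drop = FALSE]
  }
  if (nrow(presets) == 0) stopf("no conditions supplied")
  if (!is.null(n_per_condition) && (!is_count(n_per_condition) || n_per_condition < 1))
    stopf("n_per_condition must be an integer >= 1")
  if ("seed" %in% names(list(...)))
    stopf("per-trace seeds are not allowed in a cohort; use the seed argument")
  if (!is.null(seed)) set.seed(seed)

  traces <- list()
  for (i in seq_len(nrow(presets))) {
    n <- if (!is.null(n_per_condition)) n_per_condition else presets$N[i]
    if (is.null(n) || is.na(n) || n < 1)
      stopf("no trace count for condition %s", presets$condition[i])
    cfg <- sim_config(D_true = presets$D[i], ...)
    for (k in seq_len(n)) {
      tr <- generate_trace(cfg)
      tr$condition <- presets$condition[i]
      tr$vesicle_id <- sprintf("%s_%03d", presets$condition[i], k)
      traces[[length(traces) + 1L]] <- tr
    }
  }
  traces
}
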