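#' Fractional fluorescence recovery of a trace
#'
#' Rescales the recovery portion of a raw trace so the first post-bleach
#' frame is 0 and the recovered plateau is 1:
#' \deqn{f_K(t) = \frac{F_K(t) - F_K(0)}{F_K(\infty) - F_K(0)},}
#' with `F_K(0)` the intensity of the first recovery frame ("just after
#' bleaching"), `F_K(Inf)` the mean of the last 8 recovery frames, and
#' `F_K(t<0)` the mean of the 8 pre-bleach frames.  The mobile fraction
#' is
#' \deqn{M = \frac{F_K(\infty) - F_K(0)}{F_K(t<0) - F_K(0)}.}
#'
#' @param trace a [frap_trace()] with at least 8 pre-bleach and 8
#'   recovery frames.
#' @return An object of class `fractional_trace` with fields `times`,
#'   `f_values`, `F0`, `Finf`, `Fpre`, `M`.
#' @export
fractional_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- trace_prebleach(trace)
  rec <- trace_recovery(trace)
  if (length(pre) < 8) stopf("need >= 8 pre-bleach frames, got %d", length(pre))
  if (length(rec$times) < 8) stopf("need >= 8 recovery frames, got %d",
                                   length(rec$times))
  F0 <- rec$intensities[1]
  Finf <- mean(tail(rec$intensities, 8))
  Fpre <- mean(tail(pre, 8))
  if (Finf == F0)
    stop(structure(class = c("guvfrap_degenerate", "error", "condition"),
                   list(message = "flat trace: no recovery (Finf = F0)",
                        call = NULL)))
  if (Fpre == F0)
    stop(structure(class = c("guvfrap_degenerate", "error", "condition"),
                   list(message = "no bleach detected (Fpre = F0)",
                        call = NULL)))
  structure(list(times = rec$times,
                 f_values = (rec$intensities - F0) / (Finf - F0),
                 F0 = F0, Finf = Finf, Fpre = Fpre,
                 M = (Finf - F0) / (Fpre - F0)),
            class = "fractional_trace")
}

#' Fit an exponential recovery curve and extract the half-life
#'
#' Unweighted least-squares fit of
#' \deqn{y = y_0\,(1 - e^{-a t})}
#' to the fractional recovery curve (recovery frames only, time origin
#' at the first post-bleach frame).  The half-life recovery time is
#' `t_half = ln(2) / a`, the time at which the fitted curve reaches half
#' of its own asymptote `y0`.
#'
#' Initialisation is deterministic: `y0` starts at the mean of the last
#' 8 fractional values and `a` at `ln(2)` over the first time the curve
#' exceeds `y0 / 2`.  Parameters are bounded (`a > 0`,
#' `0 < y0 <= 1.5`); on non-convergence up to three deterministic
#' restarts with rescaled `a` are tried, and persistent failure is
#' reported via `converged = FALSE` rather than an error.
#'
#' @param frac a [fractional_recovery()] result with `>= 5` recovery
#'   points.
#' @return An object of class `recovery_fit` with fields `y0`, `a`
#'   (1/s), `t_half` (s), `rss`, `converged`.
#' @export
fit_recovery <- function(frac) {
  stopifnot(inherits(frac, "fractional_trace"))
  t <- frac$times
  y <- frac$f_values
  if (length(t) < 5) stopf("need >= 5 recovery points, got %d", length(t))
  if (any(t < 0)) stopf("recovery times must be >= 0")

  y0_init <- min(max(mean(tail(y, 8)), 0.05), 1.5)
  cross <- which(y >= y0_init / 2 & t > 0)
  a_init <- if (length(cross)) log(2) / t[cross[1]] else log(2) / (max(t) / 2)

  resid_fn <- function(p) p[2] * (1 - exp(-p[1] * t)) - y
  best <- NULL
  for (mult in c(1, 0.5, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a = a_init * mult, y0 = y0_init),
                         lower = c(1e-8, 1e-8), upper = c(Inf, 1.5),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4
    if (ok) { best <- fit; break }
    if (is.null(best) && !is.null(fit)) best <- fit
  }

  if (is.null(best)) {
    return(structure(list(y0 = NA_real_, a = NA_real_, t_half = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "recovery_fit"))
  }
  p <- best$par
  structure(list(y0 = unname(p["y0"]), a = unname(p["a"]),
                 t_half = log(2) / unname(p["a"]),
                 rss = sum(best$fvec^2),
                 converged = best$info %in% 1:4),
            class = "recovery_fit")
}

#' Analyze one FRAP trace end to end
#'
#' Runs the full per-vesicle pipeline: fractional recovery, exponential
#' fit, conversion of the half-life to a diffusion coefficient, and the
#' quality-control checks.  Degenerate traces and failed fits are
#' reported in the result (with `qc$pass = FALSE` and an explanatory
#' reason) instead of raising, so batch runs never crash on one bad
#' vesicle.
#'
#' @param trace a [frap_trace()].
#' @param rules a [qc_rules()] object.
#' @return An object of class `frap_result` with fields `D` (um^2/s,
#'   `NA` on failure), `fit`, `M`, `qc`, `condition`, `vesicle_id`,
#'   `error` (message or `NULL`).
#' @export
analyze_trace <- function(trace, rules = qc_rules()) {
  stopifnot(inherits(trace, "frap_trace"))
  frac <- tryCatch(fractional_recovery(trace), error = function(e) e)
  if (inherits(frac, "error")) {
    qc <- qc_report_failure(if (inherits(frac, "guvfrap_degenerate"))
      "degenerate_trace" else "invalid_trace")
    return(frap_result(NA_real_, NULL, NA_real_, qc, trace,
                       error = conditionMessage(frac)))
  }
  fit <- fit_recovery(frac)
  if (!fit$converged) {
    qc <- qc_report_failure("fit_failure")
    return(frap_result(NA_real_, fit, frac$M, qc, trace, error = "fit did not converge"))
  }
  D <- diffusion_coefficient(fit$t_half, trace$geometry$w)
  qc <- apply_qc(trace$geometry, fit, frac$M, movement = trace$movement,
                 rules = rules)
  frap_result(D, fit, frac$M, qc, trace)
}

frap_result <- function(D, fit, M, qc, trace, error = NULL) {
  structure(list(D = D, fit = fit, M = M, qc = qc,
                 condition = trace$condition, vesicle_id = trace$vesicle_id,
                 error = error),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("<frap_result> %s: D = %s um^2/s, M = %s, QC %s\n",
              ifelse(is.na(x$vesicle_id), "unnamed", x$vesicle_id),
              format(x$D, digits = 3), format(x$M, digits = 3),
              if (isTRUE(x$qc$pass)) "pass" else
                paste("fail:", paste(x$qc$excluded_reasons, collapse = ","))))
  invisible(x)
}

#' Analyze a batch of FRAP traces into a results table
#'
#' @param traces list of [frap_trace()] objects.
#' @param rules a [qc_rules()] object applied to every trace.
#' @return A data frame with one row per trace: `vesicle_id`,
#'   `condition`, `D_um2_s`, `t_half_s`, `a_per_s`, `y0`, `M`,
#'   `qc_pass`, `qc_reasons`.
#' @export
analyze_cohort <- function(traces, rules = qc_rules()) {
  if (!length(traces)) stopf("no traces supplied")
  rows <- lapply(traces, function(tr) {
    res <- analyze_trace(tr, rules)
    data.frame(
      vesicle_id = res$vesicle_id, condition = res$condition,
      D_um2_s = res$D,
      t_half_s = if (is.null(res$fit)) NA_real_ else res$fit$t_half,
      a_per_s = if (is.null(res$fit)) NA_real_ else res$fit$a,
      y0 = if (is.null(res$fit)) NA_real_ else res$fit$y0,
      M = res$M,
      qc_pass = isTRUE(res$qc$pass),
      qc_reasons = paste(res$qc$excluded_reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
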