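#' Inclusion rules for FRAP measurements
#'
#' The standard acceptance rules for spot-bleach diffusion
#' measurements:
#' * geometry — the bleached spot must be small relative to the
#'   observed membrane area: `sqrt(A/pi) / w >= area_ratio_min`;
#' * bleach pulse — the pulse must be short relative to the recovery:
#'   `t_B <= pulse_ratio_max * t_half`;
#' * mobile fraction — the trace must recover at least
#'   `mobile_min` of the pre-bleach deficit (`M >= mobile_min`);
#' * movement — the vesicle must not have drifted more than
#'   `movement_max_displacement` during the measurement.
#'
#' All comparisons are inclusive.
#'
#' @param area_ratio_min minimum effective-radius ratio (default 5).
#' @param pulse_ratio_max maximum `t_B / t_half` (default 1/10).
#' @param mobile_min minimum mobile fraction (default 0.75).
#' @param movement_max_displacement maximum drift in um (default 1,
#'   half the default spot radius).
#' @return An object of class `qc_rules`.
#' @export
qc_rules <- function(area_ratio_min = 5, pulse_ratio_max = 1 / 10,
                     mobile_min = 0.75, movement_max_displacement = 1) {
  vals <- c(area_ratio_min, pulse_ratio_max, mobile_min,
            movement_max_displacement)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all QC thresholds must be positive numbers")
  structure(list(area_ratio_min = area_ratio_min,
                 pulse_ratio_max = pulse_ratio_max,
                 mobile_min = mobile_min,
                 movement_max_displacement = movement_max_displacement),
            class = "qc_rules")
}

#' Apply the FRAP quality-control checks
#'
#' Evaluates the four inclusion rules of [qc_rules()] for one
#' measurement.  When no movement information is available the movement
#' check is skipped with a warning and does not count against the
#' verdict (matching visual-inspection practice, where absence of a
#' flag means no movement was seen).  A missing or unconverged fit
#' makes the pulse check not evaluable and fails the report.
#'
#' @param geometry a [spot_geometry()].
#' @param fit a [fit_recovery()] result, or `NULL`.
#' @param M mobile fraction.
#' @param movement observed displacement (um), a logical exclusion
#'   flag, or `NULL` when unknown.
#' @param rules a [qc_rules()] object.
#' @return An object of class `qc_report`: `pass` (flag), `checks`
#'   (data frame `name,value,threshold,pass`), `excluded_reasons`.
#' @export
apply_qc <- function(geometry, fit, M, movement = NULL, rules = qc_rules()) {
  stopifnot(inherits(geometry, "spot_geometry"), inherits(rules, "qc_rules"))

  checks <- data.frame(name = character(), value = numeric(),
                       threshold = numeric(), pass = logical(),
                       stringsAsFactors = FALSE)
  add <- function(name, value, threshold, pass) {
    rbind(checks, data.frame(name = name, value = value,
                             threshold = threshold, pass = pass,
                             stringsAsFactors = FALSE))
  }

  ratio <- sqrt(geometry$area / pi) / geometry$w
  checks <- add("area_ratio", ratio, rules$area_ratio_min,
                ratio >= rules$area_ratio_min)

  if (is.null(fit) || !isTRUE(fit$converged) || !is.finite(fit$t_half)) {
    checks <- add("pulse_ratio", NA_real_, rules$pulse_ratio_max, FALSE)
  } else {
    pr <- geometry$t_B / fit$t_half
    checks <- add("pulse_ratio", pr, rules$pulse_ratio_max,
                  pr <= rules$pulse_ratio_max)
  }

  checks <- add("mobile_fraction", M, rules$mobile_min,
                is.finite(M) && M >= rules$mobile_min)

  if (is.null(movement)) {
    warnf("no movement information for this trace; movement check skipped")
  } else if (is.logical(movement)) {
    checks <- add("movement", as.numeric(movement),
                  rules$movement_max_displacement, !movement)
  } else {
    checks <- add("movement", movement, rules$movement_max_displacement,
                  movement <= rules$movement_max_displacement)
  }

  structure(list(pass = all(checks$pass),
                 checks = checks,
                 excluded_reasons = checks$name[!checks$pass]),
            class = "qc_report")
}

# report used when the pipeline fails before QC can be evaluated
qc_report_failure <- function(reason) {
  structure(list(pass = FALSE,
                 checks = data.frame(name = reason, value = NA_real_,
                                     threshold = NA_real_, pass = FALSE,
                                     stringsAsFactors = FALSE),
                 excluded_reasons = reason),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", if (x$pass) "PASS" else
    paste("FAIL:", paste(x$excluded_reasons, collapse = ", "))))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
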