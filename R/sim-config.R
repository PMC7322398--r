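#' Bleach-spot geometry
#'
#' @param w bleach-spot radius (um), `> 0`.
#' @param area observed membrane disc area A (um^2), `> 0`; may be `Inf`
#'   for an effectively unbounded reservoir.
#' @param t_B bleach pulse duration (s), `>= 0`.
#' @return An object of class `spot_geometry`.
#' @export
spot_geometry <- function(w, area, t_B = 0.1) {
  if (!is_num1(w) || w <= 0) stopf("w must be > 0 (um)")
  if (!(is_num1(area) || identical(area, Inf)) || area <= 0)
    stopf("area must be > 0 (um^2)")
  if (!is_num1(t_B) || t_B < 0) stopf("t_B must be >= 0 (s)")
  structure(list(w = w, area = area, t_B = t_B), class = "spot_geometry")
}

#' Configuration for a simulated FRAP measurement
#'
#' Bundles the physical ground truth (diffusion coefficient, bleach
#' depth, mobile fraction), the detector model (pre-bleach intensity,
#' additive noise), the geometry (spot radius, finite membrane-disc
#' reservoir) and the frame schedule of one simulated vesicle.
#'
#' `curve_model` selects the shape of the noise-free recovery:
#' `"closed_form"` uses the uniform-disk recovery curve (the physics),
#' `"exponential_model"` uses `1 - exp(-a t)` with the rate chosen so
#' the half-crossing time matches the closed form (the same family the
#' analysis pipeline fits, so parameter recovery is unbiased), and
#' `"lattice"` defers to the Brownian particle simulator
#' [simulate_lattice_frap()].
#'
#' @param D_true lateral diffusion coefficient (um^2/s), `> 0`.
#' @param w bleach-spot radius (um); default 2 um (a 4 um diameter spot).
#' @param beta bleach depth in `(0, 1]`: fraction of spot fluorescence
#'   destroyed by the pulse.
#' @param M_true mobile fraction in `[0, 1]`.
#' @param F_pre pre-bleach intensity (a.u.).
#' @param sigma_noise additive Gaussian noise sd on ROI means (a.u.).
#' @param reservoir_radius membrane disc radius R (um, `> w`) or `Inf`.
#' @param curve_model one of `"closed_form"`, `"exponential_model"`,
#'   `"lattice"`.
#' @param schedule a [frame_schedule()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#'   Identical seed and configuration give bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(D_true,
                       w = 2,
                       beta = 0.8,
                       M_true = 0.95,
                       F_pre = 100,
                       sigma_noise = 0,
                       reservoir_radius = 10 * w,
                       curve_model = c("closed_form", "exponential_model", "lattice"),
                       schedule = frame_schedule(),
                       seed = NULL) {
  curve_model <- match.arg(curve_model)
  if (!is_num1(D_true) || D_true <= 0) stopf("D_true must be > 0 (um^2/s)")
  if (!is_num1(w) || w <= 0) stopf("w must be > 0 (um)")
  if (!is_num1(beta) || beta <= 0 || beta > 1) stopf("beta must be in (0, 1]")
  if (!is_num1(M_true) || M_true < 0 || M_true > 1) stopf("M_true must be in [0, 1]")
  if (!is_num1(F_pre) || F_pre <= 0) stopf("F_pre must be > 0 (a.u.)")
  if (!is_num1(sigma_noise) || sigma_noise < 0) stopf("sigma_noise must be >= 0")
  if (!(identical(reservoir_radius, Inf) || is_num1(reservoir_radius)))
    stopf("reservoir_radius must be a number or Inf")
  if (reservoir_radius <= w) stopf("reservoir_radius must exceed w")
  if (!inherits(schedule, "frame_schedule")) stopf("schedule must be a frame_schedule")
  if (!is.null(seed) && !is_count(seed)) stopf("seed must be an integer or NULL")
  structure(list(D_true = D_true, w = w, beta = beta, M_true = M_true,
                 F_pre = F_pre, sigma_noise = sigma_noise,
                 reservoir_radius = reservoir_radius,
                 curve_model = curve_model, schedule = schedule,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Built-in FRAP condition presets
#'
#' The experimental condition grid for GUV lateral-diffusion
#' measurements: DOPC and POPC vesicles made by electroformation or by
#' octanol-assisted liposome assembly (OLA), with and without 50 mg/mL
#' encapsulated poloxamer P-188, plus the electroformed-DOPC
#' glycerol/temperature series.  `D` and `sd` are the reported condition
#' means and standard deviations (um^2/s) and `N` the reported number of
#' vesicles; they serve as generator ground truths for recovery
#' simulations.
#'
#' @return A data frame with columns `condition`, `technique`, `lipid`,
#'   `p188_encapsulated`, `glycerol_pct`, `temperature_C`, `D`, `sd`, `N`.
#' @export
frap_presets <- function() {
  data.frame(
    condition = c("electro_DOPC", "OLA_DOPC",
                  "electro_DOPC_P188", "OLA_DOPC_P188",
                  "electro_POPC", "OLA_POPC",
                  "electro_POPC_P188", "OLA_POPC_P188",
                  "electro_DOPC_gly0_20C", "electro_DOPC_gly15_37C",
                  "electro_DOPC_gly0_37C"),
    technique = c("electroformation", "OLA", "electroformation", "OLA",
                  "electroformation", "OLA", "electroformation", "OLA",
                  "electroformation", "electroformation", "electroformation"),
    lipid = c("DOPC", "DOPC", "DOPC", "DOPC",
              "POPC", "POPC", "POPC", "POPC",
              "DOPC", "DOPC", "DOPC"),
    p188_encapsulated = c(FALSE, FALSE, TRUE, TRUE,
                          FALSE, FALSE, TRUE, TRUE,
                          FALSE, FALSE, FALSE),
    glycerol_pct = c(15, NA, NA, NA, NA, NA, NA, NA, 0, 15, 0),
    temperature_C = c(20, 20, 20, 20, 20, 20, 20, 20, 20, 37, 37),
    D = c(1.0, 1.1, 1.2, 1.0, 0.8, 1.0, 1.3, 0.9, 1.6, 1.9, 2.2),
    sd = c(0.2, 0.2, 0.4, 0.3, 0.2, 0.3, 0.4, 0.3, 0.2, 0.6, 0.5),
    N = c(17L, 34L, 14L, 30L, 28L, 49L, 20L, 27L, 12L, 19L, 7L),
    stringsAsFactors = FALSE
  )
}
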