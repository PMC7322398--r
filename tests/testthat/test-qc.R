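ok_fit <- function(t_half = 1.2) {
  structure(list(y0 = 1, a = log(2) / t_half, t_half = t_half, rss = 0,
                 converged = TRUE), class = "recovery_fit")
}

test_that("geometry check compares effective membrane radius to spot radius", {
  geo <- spot_geometry(w = 2, area = 400, t_B = 0.1)
  rep <- apply_qc(geo, ok_fit(), M = 0.9, movement = 0, rules = qc_rules())
  area_row <- rep$checks[rep$checks$name == "area_ratio", ]
  expect_equal(area_row$value, sqrt(400 / pi) / 2, tolerance = 1e-10)  # ~5.64
  expect_true(area_row$pass)

  small <- apply_qc(spot_geometry(2, 100, 0.1), ok_fit(), 0.9, 0, qc_rules())
  expect_false(small$checks$pass[small$checks$name == "area_ratio"])
  expect_true("area_ratio" %in% small$excluded_reasons)
})

test_that("bleach pulse must be short relative to the half-life", {
  geo <- spot_geometry(2, 400, t_B = 0.1)
  # t_half = 1.2 s: 0.1 <= 0.12, passes
  expect_true(apply_qc(geo, ok_fit(1.2), 0.9, 0, qc_rules())$pass)
  # t_half = 0.9 s: 0.1 > 0.09, fails
  rep <- apply_qc(geo, ok_fit(0.9), 0.9, 0, qc_rules())
  expect_false(rep$pass)
  expect_identical(rep$excluded_reasons, "pulse_ratio")
  # exact boundary is inclusive: t_half = 1.0 s gives ratio exactly 1/10
  expect_true(apply_qc(geo, ok_fit(1.0), 0.9, 0, qc_rules())$pass)
})

test_that("mobile-fraction threshold is inclusive at 75%", {
  geo <- spot_geometry(2, 400, 0.1)
  expect_false(apply_qc(geo, ok_fit(), 0.6, 0, qc_rules())$pass)
  expect_true(apply_qc(geo, ok_fit(), 0.75, 0, qc_rules())$pass)
})

test_that("movement handling: displacement, flag, or skipped with a warning", {
  geo <- spot_geometry(2, 400, 0.1)
  expect_false(apply_qc(geo, ok_fit(), 0.9, movement = 2.5, rules = qc_rules())$pass)
  expect_true(apply_qc(geo, ok_fit(), 0.9, movement = 0.5, rules = qc_rules())$pass)
  expect_false(apply_qc(geo, ok_fit(), 0.9, movement = TRUE, rules = qc_rules())$pass)
  expect_warning(rep <- apply_qc(geo, ok_fit(), 0.9, movement = NULL,
                                 rules = qc_rules()),
                 "movement")
  expect_true(rep$pass)
  expect_false("movement" %in% rep$checks$name)
})

test_that("a missing or unconverged fit fails the report", {
  geo <- spot_geometry(2, 400, 0.1)
  rep <- apply_qc(geo, NULL, 0.9, 0, qc_rules())
  expect_false(rep$pass)
  expect_true("pulse_ratio" %in% rep$excluded_reasons)
})

test_that("relaxing any threshold never turns a pass into a fail", {
  geo <- spot_geometry(2, 150, 0.1)
  base_rules <- qc_rules()
  set.seed(31)
  for (i in 1:25) {
    M <- runif(1, 0.5, 1)
    th <- runif(1, 0.5, 2)
    mv <- runif(1, 0, 2)
    before <- apply_qc(geo, ok_fit(th), M, mv, base_rules)$pass
    relaxed <- qc_rules(area_ratio_min = base_rules$area_ratio_min / 2,
                        pulse_ratio_max = base_rules$pulse_ratio_max * 2,
                        mobile_min = base_rules$mobile_min / 2,
                        movement_max_displacement =
                          base_rules$movement_max_displacement * 2)
    after <- apply_qc(geo, ok_fit(th), M, mv, relaxed)$pass
    expect_true(!before || after)
  }
})

test_that("planted QC violations are excluded in exactly the planted numbers", {
  # baseline: slow diffusion so the 0.1 s pulse is comfortably short
  base <- function(...) sim_config(D_true = 0.5, sigma_noise = 0.5,
                                   curve_model = "exponential_model", ...)
  set.seed(12)
  traces <- c(
    lapply(1:6, function(i) generate_trace(base())),
    lapply(1:3, function(i) generate_trace(base(M_true = 0.5))),       # mobile
    lapply(1:2, function(i) {                                          # area
      tr <- generate_trace(base())
      tr$geometry <- spot_geometry(2, area = 40, t_B = 0.1)
      tr
    }),
    lapply(1:4, function(i) {                                          # pulse
      tr <- generate_trace(base(schedule = frame_schedule(t_bleach = 1)))
      tr
    }))
  res <- suppressWarnings(analyze_cohort(traces))
  expect_equal(sum(!res$qc_pass), 9)
  expect_equal(sum(grepl("mobile_fraction", res$qc_reasons)), 3)
  expect_equal(sum(grepl("area_ratio", res$qc_reasons)), 2)
  expect_equal(sum(grepl("pulse_ratio", res$qc_reasons)), 4)
})

test_that("QC thresholds must be positive", {
  expect_error(qc_rules(mobile_min = 0), "positive")
  expect_error(qc_rules(area_ratio_min = -1), "positive")
})
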