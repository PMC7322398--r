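make_raw_trace <- function(intensities, n_pre = 8, dt = 0.2, t_bleach = 0.1,
                           w = 2, area = 400) {
  n_post <- length(intensities) - n_pre
  sched <- frame_schedule(n_pre, t_bleach, n_post, dt)
  ft <- frame_times(sched)
  frap_trace(ft$time_s, intensities, sched, spot_geometry(w, area, t_bleach))
}

test_that("fractional recovery uses the three reference intensities", {
  # Fpre = 100, F0 = 20, Finf = 90 (last 8 frames at 90)
  post <- c(20, 55, seq(70, 88, length.out = 10), rep(90, 8))
  tr <- make_raw_trace(c(rep(100, 8), post))
  frac <- fractional_recovery(tr)
  expect_equal(frac$Fpre, 100)
  expect_equal(frac$F0, 20)
  expect_equal(frac$Finf, 90)
  expect_equal(frac$f_values[1], 0)            # first recovery frame
  expect_equal(frac$f_values[2], 0.5)          # frame at F = 55
  expect_equal(tail(frac$f_values, 1), 1)      # plateau frame at F = 90
  expect_equal(mean(tail(frac$f_values, 8)), 1)
  expect_equal(frac$M, (90 - 20) / (100 - 20)) # 0.875
})

test_that("degenerate traces raise classed errors", {
  flat <- make_raw_trace(c(rep(100, 8), rep(20, 20)))
  expect_error(fractional_recovery(flat), class = "guvfrap_degenerate")
  nobleach <- make_raw_trace(c(rep(100, 8), 100, seq(101, 120, 1)))
  expect_error(fractional_recovery(nobleach), class = "guvfrap_degenerate")
  short <- generate_trace(sim_config(1, curve_model = "exponential_model",
                                     schedule = frame_schedule(n_pre = 2,
                                                               n_post = 20)))
  expect_error(fractional_recovery(short), ">= 8 pre-bleach")
})

test_that("fractional recovery is invariant under affine intensity rescaling", {
  tr <- generate_trace(sim_config(1.2, sigma_noise = 3, seed = 17,
                                  curve_model = "closed_form"))
  frac0 <- fractional_recovery(tr)
  set.seed(99)
  for (i in 1:10) {
    gain <- runif(1, 0.1, 10)
    offset <- runif(1, -50, 50)
    tr2 <- tr
    tr2$intensities <- gain * tr$intensities + offset
    frac2 <- fractional_recovery(tr2)
    expect_equal(frac2$f_values, frac0$f_values, tolerance = 1e-10)
    expect_equal(frac2$M, frac0$M, tolerance = 1e-10)
  }
})

test_that("exponential fit recovers exact-model parameters", {
  t <- seq(0, 19.8, 0.2)
  sched <- frame_schedule()
  frac <- structure(list(times = t, f_values = 1 - exp(-2 * t),
                         F0 = 20, Finf = 100, Fpre = 100, M = 1),
                    class = "fractional_trace")
  fit <- fit_recovery(frac)
  expect_true(fit$converged)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$y0, 1, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) / 2, tolerance = 1e-6)

  frac$f_values <- 0.9 * (1 - exp(-t))
  fit2 <- fit_recovery(frac)
  expect_equal(fit2$y0, 0.9, tolerance = 1e-6)
  expect_equal(fit2$t_half, log(2), tolerance = 1e-6)
})

test_that("exponential fit of the physical curve has a bounded, pinned bias", {
  t <- seq(0, 19.8, 0.2)
  frac <- structure(list(times = t,
                         f_values = soumpasis_fractional(t, 2, 1),
                         F0 = 20, Finf = 100, Fpre = 100, M = 1),
                    class = "fractional_trace")
  fit <- fit_recovery(frac)
  # true half-crossing of the sampled curve, by grid interpolation
  t_dense <- seq(0.01, 19.8, 1e-3)
  t_true <- t_dense[which.min(abs(soumpasis_fractional(t_dense, 2, 1) - 0.5))]
  expect_equal(fit$t_half, t_true, tolerance = 0.20)
  # regression pin: the whole-pipeline estimate on this curve
  D_est <- diffusion_coefficient(fit$t_half, 2)
  expect_lt(abs(D_est - 1), 0.2)
  expect_equal(D_est, 0.8775, tolerance = 2e-3)
})

test_that("end-to-end analysis recovers the truth and applies QC", {
  tr <- make_exp_trace(D_true = 1)
  res <- suppressWarnings(analyze_trace(tr))
  expect_equal(res$D, 1, tolerance = 0.01)
  expect_equal(res$M, 0.95, tolerance = 1e-6)

  # low mobile fraction flagged as excluded
  tr_low <- generate_trace(sim_config(0.5, M_true = 0.6,
                                      curve_model = "exponential_model"))
  res_low <- suppressWarnings(analyze_trace(tr_low))
  expect_false(res_low$qc$pass)
  expect_true("mobile_fraction" %in% res_low$qc$excluded_reasons)
})

test_that("a batch with one degenerate trace still yields a full results table", {
  traces <- generate_cohort(data.frame(condition = "c1", D = 0.5),
                            n_per_condition = 9, seed = 8,
                            curve_model = "exponential_model",
                            sigma_noise = 1)
  flat <- make_raw_trace(c(rep(100, 8), rep(20, 100)))
  flat$vesicle_id <- "flat_001"
  traces <- c(traces, list(flat))
  res <- suppressWarnings(analyze_cohort(traces))
  expect_equal(nrow(res), 10)
  expect_equal(sum(res$qc_reasons == "degenerate_trace"), 1)
  expect_true(is.na(res$D_um2_s[res$vesicle_id == "flat_001"]))
})
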