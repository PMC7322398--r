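test_that("ring intensity is measured at the right radius after background subtraction", {
  img <- make_ring_fixture(ring_value = 50, background = 5, radius = 20)
  m <- measure_ring_intensity(img)
  expect_equal(m$radius, 20, tolerance = 1)
  expect_equal(m$mean_intensity, 45, tolerance = 2)
  expect_equal(m$background, 5)
})

test_that("ring detection errors on uniform images and warns on nested rings", {
  expect_error(measure_ring_intensity(matrix(3, 40, 40)), "no ring")
  nested <- make_ring_fixture(50, 0, radius = 20) +
    make_ring_fixture(30, 0, radius = 10)
  expect_warning(m <- measure_ring_intensity(nested), "candidate rings")
  expect_equal(m$radius, 20, tolerance = 1)   # brighter ring wins
})

test_that("ring measurement survives realistic noise", {
  set.seed(6)
  img <- make_ring_fixture(50, 5, radius = 20) +
    matrix(rnorm(64^2, sd = 2), 64, 64)
  m <- measure_ring_intensity(img)
  expect_equal(m$radius, 20, tolerance = 1)
  expect_equal(m$mean_intensity, 45, tolerance = 6)
})

test_that("zero-intercept slope matches closed-form arithmetic and lm", {
  recs <- function(x, I) data.frame(x_rel = x, intensity = I)
  expect_equal(fit_zero_intercept(recs(c(1, 2, 3), c(10, 20, 30))), 10)
  expect_equal(fit_zero_intercept(recs(c(1, 2, 3), c(12, 20, 30))), 142 / 14)
  expect_equal(fit_zero_intercept(recs(c(2, 2), c(19, 21))), 10)

  # cross-check against the generic fixed-zero-intercept regression
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:3, 30, replace = TRUE)
    I <- 7 * x + rnorm(30)
    d <- recs(x, I)
    expect_equal(fit_zero_intercept(d),
                 unname(coef(lm(intensity ~ 0 + x_rel, data = d))),
                 tolerance = 1e-12)
  }

  expect_error(fit_zero_intercept(recs(1, 10)), "at least 2")
  expect_error(fit_zero_intercept(recs(c(0, 0), c(1, 2))), "zero")
})

test_that("slope normalization gives the expected 1-2-3 scaling", {
  ds <- generate_composition_dataset(
    composition_sim_config(sigma_noise = 0, brightness_per_unit = 7,
                           n_per_group = 4))
  norm <- normalize_intensities(ds)
  expect_equal(attr(norm, "slope"), 7)
  expect_equal(sort(unique(norm$normalized)), c(1, 2, 3))

  d <- data.frame(x_rel = c(1, 2, 3), intensity = c(12, 20, 30),
                  group = c("3:1", "2:2", "1:3"))
  norm2 <- normalize_intensities(d)
  expect_equal(norm2$normalized, c(1.1831, 1.9718, 2.9577), tolerance = 1e-4)

  # global gain invariance
  d_scaled <- d
  d_scaled$intensity <- d$intensity * 17.3
  expect_equal(normalize_intensities(d_scaled)$normalized, norm2$normalized,
               tolerance = 1e-12)
  expect_error(normalize_intensities(d, slope = -1), "slope")
})

test_that("post-normalization regression slope equals one by construction", {
  set.seed(22)
  ds <- generate_composition_dataset(
    composition_sim_config(n_per_group = 40, sigma_noise = 2, seed = 22))
  norm <- normalize_intensities(ds)
  renorm <- data.frame(x_rel = norm$x_rel, intensity = norm$normalized)
  expect_equal(fit_zero_intercept(renorm), 1, tolerance = 1e-12)
})

test_that("group summaries report boxplot statistics and keep outliers", {
  d <- data.frame(group = "g", x_rel = 1, normalized = c(1, 2, 3))
  s <- summarize_composition(d)
  expect_equal(s$median, 2)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 3)

  with_outlier <- data.frame(group = "g", x_rel = 1,
                             normalized = c(rep(1, 10), 50))
  s2 <- summarize_composition(with_outlier)
  expect_equal(s2$n_outliers, 1)
  expect_equal(s2$mean, mean(c(rep(1, 10), 50)))   # outlier retained
  expect_equal(s2$n, 11)

  # an unformable group is simply absent from the table
  two <- data.frame(group = rep(c("2:2", "1:3"), each = 3),
                    x_rel = rep(c(2, 3), each = 3),
                    normalized = c(2, 2, 2, 3, 3, 3))
  expect_equal(nrow(summarize_composition(two)), 2)
})

test_that("end-to-end composition recovery is unbiased within 3 SEM", {
  ds <- generate_composition_dataset(
    composition_sim_config(n_per_group = 50, sigma_noise = 1,
                           brightness_per_unit = 10, seed = 33))
  norm <- normalize_intensities(ds)
  s <- summarize_composition(norm)
  for (i in seq_len(nrow(s))) {
    x <- unique(norm$x_rel[norm$group == s$group[i]])
    expect_lt(abs(s$mean[i] - x), 3 * s$sd[i] / sqrt(s$n[i]))
  }
})
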