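toy_points <- function(n = 60, sigma = 0, window = 0, seed = 1L) {
  dat <- make_laa("RGM", rgm_truth, n = n, sigma = sigma,
                  age_range = c(0, 40), seed = seed)
  data.frame(individual_id = dat$individual_id,
             min_age_years = pmax(0, dat$age_years - window),
             max_age_years = dat$age_years + window,
             tl_cm = dat$tl_cm)
}

test_that("the shortest-window HPD matches exhaustive enumeration", {
  expect_equal(hpd_interval(1:100, 0.95), c(1, 95))
  expect_equal(hpd_interval(1:100, 0.95), hpd_by_enumeration(1:100, 0.95))
  set.seed(5)
  for (i in 1:10) {
    s <- rgamma(80, shape = 2)  # skewed, so HPD differs from central interval
    expect_equal(hpd_interval(s, 0.9), hpd_by_enumeration(s, 0.9))
  }
  expect_equal(hpd_interval(rep(3.2, 25)), c(3.2, 3.2))
  expect_error(hpd_interval(1:10), "at least 20")
  expect_error(hpd_interval(1:100, mass = 1.2), "mass")
})

test_that("the HPD of a large normal sample approaches the closed form", {
  set.seed(11)
  s <- rnorm(1e5)
  h <- hpd_interval(s, 0.95)
  expect_lt(abs(h[1L] + 1.96), 0.05)
  expect_lt(abs(h[2L] - 1.96), 0.05)
  # contains the median of a unimodal sample
  expect_lt(h[1L], median(s))
  expect_gt(h[2L], median(s))
})

test_that("rectangular resampling respects its box bounds", {
  pts <- data.frame(individual_id = "d1", min_age_years = 2,
                    max_age_years = 4, tl_cm = 200)
  spec <- error_spec(max_length_frac_error = 0.0127, n_iter = 1)
  set.seed(3)
  draws <- do.call(rbind, lapply(1:2000, function(i) resample_dataset(pts, spec)))
  expect_true(all(draws$age_years >= 2 & draws$age_years <= 4))
  expect_true(all(draws$tl_cm >= 197.46 & draws$tl_cm <= 202.54))
  # uniform-moment check on the age window
  se <- (2 / sqrt(12)) / sqrt(2000)
  expect_lt(abs(mean(draws$age_years) - 3), 3 * se)
})

test_that("a zero-error box is the identity on the data", {
  pts <- toy_points(n = 30, window = 0, seed = 2)
  spec <- error_spec(max_length_frac_error = 0, n_iter = 1)
  set.seed(1)
  out <- resample_dataset(pts, spec)
  expect_equal(out$age_years, pts$min_age_years, tolerance = 1e-12)
  expect_equal(out$tl_cm, pts$tl_cm, tolerance = 1e-12)
})

test_that("inverted age windows are a data error naming the record", {
  pts <- data.frame(individual_id = "bad-one", min_age_years = 5,
                    max_age_years = 3, tl_cm = 200)
  expect_error(resample_dataset(pts, error_spec()), "bad-one")
})

test_that("zero-error sensitivity reproduces the baseline exactly", {
  pts <- toy_points(n = 50, sigma = 1, window = 0, seed = 4)
  spec <- error_spec(max_length_frac_error = 0, n_iter = 30, seed = 6)
  res <- run_sensitivity(pts, "RGM", spec)
  expect_equal(res$n_failed, 0L)
  # every draw identical, HPD width zero, equal to the baseline prediction
  base_pred <- predict(res$baseline, spec$ages)
  for (j in seq_along(spec$ages)) {
    expect_equal(unname(res$summary$hpd_hi[j] - res$summary$hpd_lo[j]), 0,
                 tolerance = 1e-9)
    expect_equal(unname(res$summary$median[j]), base_pred[j],
                 tolerance = 1e-9)
  }
})

test_that("sensitivity output is reproducible for a fixed seed", {
  pts <- toy_points(n = 50, sigma = 1.5, window = 0.5, seed = 8)
  spec <- error_spec(n_iter = 40, seed = 21)
  r1 <- run_sensitivity(pts, "RGM", spec)
  r2 <- run_sensitivity(pts, "RGM", spec)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$summary, r2$summary)
})

test_that("widening the error box does not narrow the HPD intervals", {
  widths <- function(frac, seed) {
    pts <- toy_points(n = 60, sigma = 1.5, window = 1, seed = seed)
    spec <- error_spec(max_length_frac_error = frac, n_iter = 80, seed = 17)
    res <- run_sensitivity(pts, "RGM", spec)
    mean(res$summary$hpd_hi - res$summary$hpd_lo)
  }
  for (s in c(31, 32, 33)) {
    expect_gte(widths(0.0254, s), widths(0.0127, s))
  }
})

test_that("endpoint age resampling only visits window endpoints", {
  pts <- data.frame(individual_id = c("a", "b"), min_age_years = c(1, 4),
                    max_age_years = c(2, 8), tl_cm = c(150, 200))
  spec <- error_spec(max_length_frac_error = 0, age_mode = "endpoints")
  set.seed(12)
  for (i in 1:20) {
    out <- resample_dataset(pts, spec)
    expect_true(all(out$age_years %in% c(1, 2, 4, 8)))
  }
})
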