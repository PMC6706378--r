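sw_small <- function(n = 40, seed = 1L, ...) {
  sw_population_config(n_individuals = n, seed = seed, ...)
}

test_that("generation is deterministic for a fixed seed", {
  a <- generate_population(sw_small(seed = 13))
  b <- generate_population(sw_small(seed = 13))
  expect_identical(a, b)
  pairs1 <- generate_calibration_pairs(n = 12, seed = 5)
  pairs2 <- generate_calibration_pairs(n = 12, seed = 5)
  expect_identical(pairs1, pairs2)
})

test_that("age windows bracket the true age and respect the lifespan cap", {
  pop <- generate_population(sw_small(n = 300, seed = 2))
  m <- merge(pop$records, pop$truth, by = "individual_id")
  expect_true(all(m$min_age_years <= m$true_age + 1e-12))
  expect_true(all(m$max_age_years >= m$true_age - 1e-12))
  expect_true(all(m$min_age_years >= 0))
  open <- m[m$accuracy_class == "open", ]
  expect_gt(nrow(open), 0)
  expect_true(all(open$max_age_years == 45))
  expect_equal(open$min_age_years, open$true_age)

  # all mass on the open class -> every animal capped at 45
  all_open <- generate_population(
    sw_small(n = 25, seed = 3, accuracy_mix = c(open = 1), open_min_age = 0))
  expect_true(all(all_open$records$max_age_years == 45))

  # young animals are never assigned an open-ended window
  young_open <- m[m$true_age < 15 & m$accuracy_class == "open", ]
  expect_equal(nrow(young_open), 0L)
})

test_that("true ages follow the configured uniform distribution", {
  pop <- generate_population(
    sw_small(n = 1000, seed = 17, age_distribution = c(0, 40)))
  se <- (40 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(pop$truth$true_age) - 20), 3 * se)
})

test_that("an invalid accuracy mix is a configuration error", {
  expect_error(sw_small(accuracy_mix = c(day = 0.5, open = 0.4)), "sum to 1")
  expect_error(sw_small(accuracy_mix = c(foo = 1)), "classes among")
  expect_error(sw_small(measurement_cv = -0.1), "measurement_cv")
})

test_that("noiseless measurements round-trip to the true total length", {
  cfg <- sw_small(n = 30, seed = 6, measurement_cv = 0)
  cal <- allometric_calibration()
  pop <- generate_population(cfg, cal)
  photos <- generate_measurements(pop$records, pop$truth, cfg, cal)
  per <- photo_lengths(photos, cal)
  true_tl <- pop$truth$true_tl[match(per$individual_id,
                                     pop$truth$individual_id)]
  expect_equal(per$tl_cm, true_tl, tolerance = 1e-9)
})

test_that("repeat-measurement CV converges to the configured error", {
  cfg <- sw_small(n = 200, seed = 23, measurement_cv = 0.019,
                  photos_per_individual = c(5, 9))
  cal <- allometric_calibration()
  pop <- generate_population(cfg, cal)
  photos <- generate_measurements(pop$records, pop$truth, cfg, cal)
  est <- length_estimates(photos, cal)
  mean_cv <- mean(est$cv_percent, na.rm = TRUE)
  expect_gt(mean_cv, 1.5)
  expect_lt(mean_cv, 2.4)
})

test_that("foreshortening compresses the landmark by the cosine of the angle", {
  cfg <- sw_small(n = 20, seed = 9, measurement_cv = 0)
  cal <- allometric_calibration()
  pop <- generate_population(cfg, cal)
  photos <- generate_measurements(pop$records, pop$truth, cfg, cal,
                                  foreshortening = TRUE, angle_deg = 15)
  measured <- pixels_to_cm(photos$bhdf_px, photos$laser_px, 10)
  true_bhdf <- pop$truth$true_bhdf[match(photos$individual_id,
                                         pop$truth$individual_id)]
  expect_equal(measured, true_bhdf * cos(15 * pi / 180), tolerance = 1e-9)
})

test_that("calibration pairs lie on the configured line when noiseless", {
  pairs <- generate_calibration_pairs(n = 10, noise_sd = 0, seed = 2)
  cal <- fit_allometry(pairs)
  expect_equal(cal$intercept_cm, 5.0583, tolerance = 1e-9)
  expect_equal(cal$slope, 3.17, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  # sampling-error check at the post-mortem sample size
  noisy <- generate_calibration_pairs(n = 12, noise_sd = 2, seed = 3)
  expect_lt(abs(fit_allometry(noisy)$slope - 3.17), 0.3)
  expect_error(generate_calibration_pairs(n = 2), "n >= 3")
})

test_that("maturity statuses follow the logistic truth and coding rules", {
  cfg <- sw_small(n = 2000, seed = 41, age_distribution = c(0, 10),
                  true_a50_indep = 3.0, logistic_slope_indep = 2)
  pop <- generate_population(cfg)
  rec <- generate_maturity_status(pop$records, pop$truth, cfg)
  expect_true(all(rec$independent %in% c(0L, 1L)))
  expect_true(all(is.na(rec$reproduced[rec$sex != "F"])))
  expect_true(all(rec$reproduced[rec$sex == "F"] %in% c(0L, 1L)))

  # closed-loop: refitting the logistic on true ages recovers A50
  fit <- fit_logistic(pop$truth$true_age, rec$independent)
  expect_lt(abs(x50(fit$alpha, fit$beta1) - 3.0), 0.3)

  # a very steep slope makes status a step function at A50
  steep <- sw_small(n = 400, seed = 42, age_distribution = c(0, 10),
                    true_a50_indep = 3.0, logistic_slope_indep = 1e6)
  pop2 <- generate_population(steep)
  rec2 <- generate_maturity_status(pop2$records, pop2$truth, steep)
  expect_true(all(rec2$independent[pop2$truth$true_age > 3.01] == 1L))
  expect_true(all(rec2$independent[pop2$truth$true_age < 2.99] == 0L))
})

test_that("simulate_study writes the four standard CSV tables", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(sw_small(n = 15, seed = 4), out_dir = dir)
  for (f in c("individuals.csv", "photos.csv", "calibration.csv", "truth.csv")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  ind <- read.csv(file.path(dir, "individuals.csv"))
  expect_setequal(names(ind), c("individual_id", "region", "sex",
                                "min_age_years", "max_age_years",
                                "accuracy_class", "independent", "reproduced"))
  expect_equal(nrow(ind), 15L)
})
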