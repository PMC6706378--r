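sim_logistic <- function(n, alpha, beta1, x_range = c(0, 10), seed = 1L) {
  set.seed(seed)
  x <- runif(n, x_range[1L], x_range[2L])
  y <- rbinom(n, 1L, plogis(alpha + beta1 * x))
  list(x = x, y = y)
}

test_that("the 50% point inverts the logistic curve", {
  expect_equal(x50(alpha = -6, beta1 = 2), 3)
  expect_equal(x50(alpha = 0, beta1 = 1, p = 0.75), log(3))
  # at p = 0.5 the log-odds term vanishes for any parameters
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(1); b <- runif(1, 0.1, 3)
    expect_equal(x50(a, b), -a / b, tolerance = 1e-12)
  }
  expect_error(x50(1, 0), "slope is zero")
  expect_error(x50(1, 1, p = 1), "strictly")
})

test_that("maximum-likelihood logistic fits recover the truth", {
  d <- sim_logistic(2000, alpha = -6, beta1 = 2, seed = 7)
  fit <- fit_logistic(d$x, d$y)
  expect_lt(abs(fit$alpha - (-6)) / 6, 0.10)
  expect_lt(abs(fit$beta1 - 2) / 2, 0.10)
  # fitted probability is exactly one half at the 50% point
  est <- x50(fit$alpha, fit$beta1)
  expect_equal(plogis(fit$alpha + fit$beta1 * est), 0.5, tolerance = 1e-9)
})

test_that("flat outcomes yield small slopes under the null", {
  # y independent of x: the slope estimate should hover near zero
  reject <- vapply(1:40, function(s) {
    d <- sim_logistic(400, alpha = 0, beta1 = 0, seed = 100 + s)
    fit <- fit_logistic(d$x, d$y)
    p <- summary(fit$fit)$coefficients["x", "Pr(>|z|)"]
    p < 0.05
  }, logical(1))
  expect_lte(sum(reject), 6)  # ~5% type-I error over 40 replicates
})

test_that("degenerate logistic inputs are rejected with explanations", {
  expect_error(fit_logistic(1:10, rep(1, 10)), "both outcome classes")
  expect_error(fit_logistic(rep(2, 10), rep(c(0, 1), 5)), "variance")
  # perfectly separated toy data
  expect_error(fit_logistic(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)),
               "separation")
})

test_that("x50 is equivariant under affine rescaling of the predictor", {
  d <- sim_logistic(600, alpha = -4, beta1 = 1.5, seed = 9)
  f1 <- fit_logistic(d$x, d$y)
  f2 <- fit_logistic(2.5 * d$x + 7, d$y)
  expect_equal(x50(f2$alpha, f2$beta1), 2.5 * x50(f1$alpha, f1$beta1) + 7,
               tolerance = 1e-6)
})

test_that("maturity estimation closes the loop on synthetic truth", {
  # day/week accuracy only, so the minimum-age convention introduces no
  # appreciable shift relative to the true ages driving the statuses
  cfg <- sw_population_config(n_individuals = 500, seed = 19,
                              age_distribution = c(0, 10),
                              accuracy_mix = c(day = 0.5, week = 0.5),
                              true_a50_indep = 3.0)
  sim <- simulate_study(cfg)
  cal <- fit_allometry(sim$calibration_pairs)
  est <- length_estimates(sim$photos, cal)
  res <- estimate_maturity(sim$records, est, "independence", "age",
                           n_iter = 300, seed = 3)
  expect_lt(abs(res$x50 - 3.0), 0.3)
  expect_lte(res$ci[1L], 3.0)
  expect_gte(res$ci[2L], 3.0)
  expect_equal(res$n_success + res$n_failure, 500L)
})

test_that("first reproduction is restricted to females", {
  cfg <- sw_population_config(n_individuals = 400, seed = 29,
                              age_distribution = c(0, 25))
  sim <- simulate_study(cfg)
  cal <- fit_allometry(sim$calibration_pairs)
  est <- length_estimates(sim$photos, cal)
  res <- estimate_maturity(sim$records, est, "first_reproduction", "age",
                           n_iter = 50, seed = 3)
  n_female <- sum(sim$records$sex == "F" & !is.na(sim$records$reproduced))
  expect_equal(res$n_success + res$n_failure, n_female)
})

test_that("sparse status classes are refused with guidance", {
  rec <- data.frame(individual_id = sprintf("i%d", 1:20), sex = "F",
                    min_age_years = 1:20,
                    independent = c(rep(0L, 18), 1L, 1L),
                    reproduced = NA_integer_)
  est <- data.frame(individual_id = rec$individual_id, tl_cm = 100 + 1:20)
  expect_error(estimate_maturity(rec, est, "independence", "age"),
               "at least 5")
})

test_that("bootstrap interval width shrinks with sample size", {
  width_at <- function(n, seed) {
    cfg <- sw_population_config(n_individuals = n, seed = seed,
                                age_distribution = c(0, 10))
    sim <- simulate_study(cfg)
    cal <- fit_allometry(sim$calibration_pairs)
    est <- length_estimates(sim$photos, cal)
    res <- estimate_maturity(sim$records, est, "independence", "age",
                             n_iter = 200, seed = 5)
    diff(res$ci)
  }
  expect_lt(width_at(1000, 31), width_at(100, 31))
})
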