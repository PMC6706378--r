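# Minimal sensitivity-result stand-in for comparison tests.
fake_sens <- function(draws, ages = as.numeric(sub("age_", "", colnames(draws)))) {
  structure(list(ages = ages, draws = draws,
                 summary = data.frame(age = ages,
                                      median = apply(draws, 2, median))),
            class = "sensitivity_result")
}

test_that("the Welch test matches its hand-computed formula", {
  w <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  oracle <- welch_by_hand(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, oracle$t, tolerance = 1e-9)
  expect_equal(w$df, oracle$df, tolerance = 1e-9)
  expect_equal(w$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(round(w$t, 3), -3.674)
  expect_equal(w$df, 4)
  expect_equal(w$p_value, 0.0213, tolerance = 1e-3)

  set.seed(8)
  x <- rnorm(40, 2, 3); y <- rnorm(25, 1, 0.5)
  w2 <- welch_t_test(x, y); o2 <- welch_by_hand(x, y)
  expect_equal(w2$t, o2$t, tolerance = 1e-9)
  expect_equal(w2$df, o2$df, tolerance = 1e-9)
})

test_that("the Welch test handles identical and degenerate samples", {
  x <- c(1, 2, 3, 4)
  w <- welch_t_test(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p_value, 1)
  deg <- welch_t_test(rep(2, 5), rep(7, 5))
  expect_false(deg$performed)
  expect_equal(deg$difference, -5)
  expect_true(is.na(deg$p_value))
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("the Welch test is antisymmetric and holds its size", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(20, 0.5)
  a <- welch_t_test(x, y); b <- welch_t_test(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)

  # type-I error near the nominal 5% under the null
  set.seed(91)
  rej <- vapply(1:1000, function(i) {
    welch_t_test(rnorm(50), rnorm(50))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("growth increments report absolute and relative first-year growth", {
  inc_sw <- growth_increment(107.6, 155.9)
  expect_equal(unname(inc_sw["increment_cm"]), 48.3, tolerance = 1e-9)
  inc_sb <- growth_increment(102.8, 120.1)
  expect_equal(unname(inc_sb["increment_cm"]), 17.3, tolerance = 1e-9)
  expect_equal(unname(growth_increment(100, 100)), c(0, 0))
  # the percentage is invariant to a common rescaling
  for (c in c(0.5, 2, 10)) {
    expect_equal(unname(growth_increment(107.6 * c, 155.9 * c)["percent"]),
                 unname(inc_sw["percent"]), tolerance = 1e-9)
  }
  expect_error(growth_increment(-1, 100), "positive")
})

test_that("identical regions show zero differences and no significance", {
  set.seed(4)
  draws <- matrix(rnorm(400, 200, 2), ncol = 4,
                  dimnames = list(NULL, paste0("age_", c(1, 3, 12, 25))))
  cmp <- compare_regions(fake_sens(draws), fake_sens(draws))
  expect_equal(cmp$comparisons$difference_cm, rep(0, 4))
  expect_false(any(cmp$comparisons$significant))
})

test_that("regional differences are summarised and sign-symmetric", {
  set.seed(6)
  ages <- c(1, 3, 12, 25)
  shift <- c(35.8, 36.0, 37.6, 39.2)
  base <- matrix(rnorm(4000, 160, 0.5), ncol = 4,
                 dimnames = list(NULL, paste0("age_", ages)))
  tall <- sweep(base, 2, shift, "+")
  cmp <- compare_regions(fake_sens(tall), fake_sens(base), ages = ages)
  expect_equal(cmp$comparisons$difference_cm, shift, tolerance = 0.1)
  expect_equal(cmp$summary$median, median(shift), tolerance = 0.1)
  expect_equal(cmp$summary$range, range(shift), tolerance = 0.1)
  expect_true(all(cmp$comparisons$significant))
  # difference_cm is exactly median_a - median_b
  expect_equal(cmp$comparisons$difference_cm,
               cmp$comparisons$median_a - cmp$comparisons$median_b,
               tolerance = 1e-9)

  swapped <- compare_regions(fake_sens(base), fake_sens(tall), ages = ages)
  expect_equal(swapped$comparisons$difference_cm,
               -cmp$comparisons$difference_cm, tolerance = 1e-9)
  expect_equal(swapped$summary$median, -cmp$summary$median, tolerance = 1e-9)

  expect_error(compare_regions(fake_sens(base), fake_sens(base),
                               ages = c(1, 7)), "missing")
})
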