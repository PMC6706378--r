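# Shared fixtures built in code.

# Length-at-age data simulated from a named growth model with additive
# Gaussian noise; one row per individual.
make_laa <- function(model, params, n = 130, sigma = 2, age_range = c(0, 40),
                     seed = 1L) {
  set.seed(seed)
  age <- runif(n, age_range[1L], age_range[2L])
  tl <- growth_length(model, params, age) + rnorm(n, 0, sigma)
  data.frame(individual_id = sprintf("ID%03d", seq_len(n)),
             age_years = age, tl_cm = tl, stringsAsFactors = FALSE)
}

# Spec-style Richards truth used across fitting tests.
rgm_truth <- list(L_inf = 245, K = 0.5, t0 = -0.5, p_shape = 2.0)

# Hand Welch t-test: independent oracle for the packaged version.
welch_by_hand <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Enumerated shortest-window HPD: independent oracle.
hpd_by_enumeration <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- NULL
  for (i in seq_len(n - m + 1L)) {
    w <- s[i + m - 1L] - s[i]
    if (is.null(best) || w < best$w) best <- list(w = w, lo = s[i], hi = s[i + m - 1L])
  }
  c(best$lo, best$hi)
}
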