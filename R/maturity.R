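#' Binomial-logit regression of a binary status on a single predictor
#'
#' Maximum-likelihood logistic fit `logit(p) = alpha + beta1 * x` via
#' [stats::glm()]. Inputs with a single outcome class, zero predictor
#' variance, or complete separation are rejected: under separation the
#' 50% point degenerates to a boundary of the data and the MLE does not
#' exist.
#'
#' @param x Numeric predictor (age in years or length in cm).
#' @param y Binary outcome coded 0/1.
#' @return List with `alpha`, `beta1`, `converged` and the underlying
#'   `glm` object.
#' @export
fit_logistic <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (stats::var(x) <= 0) stop("predictor has no variance", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (all(abs(y - mu) < 1e-6)) {
    stop("complete separation: the outcome is perfectly predicted, so the ",
         "50% point degenerates to a data boundary", call. = FALSE)
  }
  co <- stats::coef(fit)
  list(alpha = unname(co[1L]), beta1 = unname(co[2L]),
       converged = fit$converged, fit = fit)
}

#' Predictor value at a given success probability
#'
#' Inverts the logistic curve: `x_p = (logit(p) - alpha) / beta1`. At
#' `p = 0.5` the log-odds term vanishes and the expression reduces to
#' `-alpha / beta1`, the conventional A50 / L50 estimator.
#'
#' @param alpha Logistic intercept.
#' @param beta1 Logistic slope (non-zero).
#' @param p Target probability in (0, 1); default 0.5.
#' @return Predictor value (years or cm).
#' @export
#' @examples
#' x50(alpha = -6, beta1 = 2)  # 3
x50 <- function(alpha, beta1, p = 0.5) {
  if (beta1 == 0) stop("x50 undefined: logistic slope is zero", call. = FALSE)
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)", call. = FALSE)
  (stats::qlogis(p) - alpha) / beta1
}

#' Estimate age or length at 50% independence or first reproduction
#'
#' Merges individual records with their length estimates, fits a
#' binomial-logit regression of the chosen status on the chosen predictor
#' (minimum age estimate in years, or estimated total length in cm),
#' derives the 50% point, and quantifies its uncertainty by bootstrap
#' resampling of individuals with a percentile interval. First
#' reproduction is restricted to females. Bootstrap iterations suffering
#' one-class resamples or complete separation are dropped and counted.
#'
#' @param records Data frame with `individual_id`, `sex`,
#'   `min_age_years`, and status columns `independent` / `reproduced`
#'   (0/1, `NA` allowed).
#' @param estimates Per-individual length estimates (columns
#'   `individual_id`, `tl_cm`), e.g. from [length_estimates()].
#' @param outcome `"independence"` or `"first_reproduction"`.
#' @param predictor `"age"` or `"length"`.
#' @param n_iter Bootstrap iterations (1000 in routine use).
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return Object of class `logistic_fit_result`: predictor, outcome,
#'   `alpha`, `beta1`, `x50`, `ci`, class counts, the number of dropped
#'   bootstrap iterations and the x50 draws.
#' @export
estimate_maturity <- function(records, estimates,
                              outcome = c("independence", "first_reproduction"),
                              predictor = c("age", "length"),
                              n_iter = 1000, seed = 1L, conf = 0.95) {
  outcome <- match.arg(outcome)
  predictor <- match.arg(predictor)
  dat <- merge(records, estimates[, c("individual_id", "tl_cm")],
               by = "individual_id")
  if (outcome == "first_reproduction") {
    dat <- dat[dat$sex == "F", , drop = FALSE]
    y <- dat$reproduced
  } else {
    y <- dat$independent
  }
  xvals <- if (predictor == "age") dat$min_age_years else dat$tl_cm
  keep <- is.finite(xvals) & is.finite(y)
  xvals <- xvals[keep]; y <- y[keep]
  n_success <- sum(y == 1); n_failure <- sum(y == 0)
  if (min(n_success, n_failure) < 5L) {
    stop("need at least 5 individuals in each status class (have ",
         n_success, " successes, ", n_failure, " failures); collect more ",
         "data or pool regions", call. = FALSE)
  }
  point <- fit_logistic(xvals, y)
  est <- x50(point$alpha, point$beta1)

  set.seed(seed)
  n <- length(y)
  draws <- rep(NA_real_, n_iter)
  for (b in seq_len(n_iter)) {
    i <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_logistic(xvals[i], y[i]), error = function(e) NULL)
    if (is.null(fb) || fb$beta1 == 0) next
    draws[b] <- x50(fb$alpha, fb$beta1)
  }
  ok <- is.finite(draws)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- if (any(ok)) unname(stats::quantile(draws[ok], probs)) else
    c(NA_real_, NA_real_)
  structure(list(
    predictor = predictor,
    outcome = outcome,
    alpha = point$alpha,
    beta1 = point$beta1,
    x50 = est,
    ci = ci,
    conf = conf,
    n_success = n_success,
    n_failure = n_failure,
    n_iter = n_iter,
    n_dropped = sum(!ok),
    draws = draws[ok]
  ), class = "logistic_fit_result")
}

#' @export
print.logistic_fit_result <- function(x, ...) {
  unit <- if (x$predictor == "age") "years" else "cm"
  lab <- if (x$predictor == "age") "A50" else "L50"
  cat(sprintf("%s at %s: %.2f %s (%.0f%% CI %.2f-%.2f)\n",
              lab, x$outcome, x$x50, unit, 100 * x$conf, x$ci[1L], x$ci[2L]))
  cat(sprintf("  logit(p) = %.3f + %.3f x; %d successes, %d failures; %d/%d bootstrap iterations dropped\n",
              x$alpha, x$beta1, x$n_success, x$n_failure, x$n_dropped, x$n_iter))
  invisible(x)
}
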