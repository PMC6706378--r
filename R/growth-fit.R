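#' Fit a growth model by non-linear least squares
#'
#' Minimises the residual sum of squares of observed total length against
#' the growth function using bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]). Any subset of parameters may be held fixed at
#' supplied constants, which is the conventional guard against
#' over-parameterisation of the Richards model. When the first start fails
#' to converge, a small set of deterministically jittered starts is tried.
#'
#' @param data Data frame with numeric columns `age_years` and `tl_cm`
#'   (one row per measurement used in the fit).
#' @param model One of [growth_models()].
#' @param start Named list of starting values; defaults per
#'   [growth_param_names()] are the maximum observed length for `L_inf`,
#'   the minimum for `L0`, 0.5/y for rates, -0.1 y for `t0` and 1.5 for
#'   `p_shape`.
#' @param fixed Named list of parameters to hold constant (e.g.
#'   `list(p_shape = 1)`).
#' @param max_iter Maximum optimiser iterations.
#' @param tol Convergence tolerance passed to the optimiser.
#' @return An object of class `growth_fit`: list with elements `model`,
#'   `params` (all parameters, fixed ones included), `fixed` (names),
#'   `rss` (cm^2), `n`, `k_params` (free parameters + 1 for the error
#'   variance), `converged`, and the data used.
#' @export
fit_growth <- function(data, model, start = NULL, fixed = list(),
                       max_iter = 200, tol = 1e-10) {
  model <- match.arg(model, growth_models())
  stopifnot(is.data.frame(data), all(c("age_years", "tl_cm") %in% names(data)))
  data <- data[is.finite(data$age_years) & is.finite(data$tl_cm), , drop = FALSE]
  nm <- growth_param_names(model)
  if (length(fixed) > 0L && !all(names(fixed) %in% nm)) {
    stop("fixed parameter(s) not used by model ", model, ": ",
         paste(setdiff(names(fixed), nm), collapse = ", "), call. = FALSE)
  }
  free <- setdiff(nm, names(fixed))
  n <- nrow(data)
  if (n < length(free) + 2L) {
    stop("need at least ", length(free) + 2L, " observations to fit ", model,
         " with ", length(free), " free parameter(s); got ", n, call. = FALSE)
  }
  if (diff(range(data$age_years)) <= 0) {
    stop("ages must span a positive range", call. = FALSE)
  }

  start_full <- default_growth_start(model, data)
  if (!is.null(start)) start_full[names(start)] <- start
  start_full[names(fixed)] <- fixed
  bounds <- growth_param_bounds(model, data)

  resid_fun <- function(par_free) {
    params <- start_full
    params[free] <- as.list(par_free)
    pred <- growth_length(model, params, data$age_years)
    r <- data$tl_cm - pred
    r[!is.finite(r)] <- 1e6  # penalise non-physical regions (e.g. RGM base < 0)
    r
  }

  # deterministic jitter factors for restarts (multiplicative on scale
  # parameters, additive shift on t0)
  jitters <- list(1, c(0.6, 1.5), c(1.6, 0.7))
  best <- NULL
  for (j in jitters) {
    par0 <- unlist(start_full[free])
    if (!identical(j, 1)) {
      fac <- rep_len(j, length(par0))
      par0 <- ifelse(names(par0) == "t0", par0 - (fac - 1), par0 * fac)
    }
    par0 <- pmin(pmax(par0, bounds$lower[free] + 1e-8), bounds$upper[free] - 1e-8)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fun,
        lower = unname(bounds$lower[free]), upper = unname(bounds$upper[free]),
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol, ptol = tol
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4 && is.finite(fit$deviance)
    if (is.null(best) || (ok && fit$deviance < best$deviance)) {
      best <- fit
    }
    if (ok) break
  }

  params <- start_full
  converged <- FALSE
  rss <- NA_real_
  diagnostics <- NULL
  if (!is.null(best)) {
    params[free] <- as.list(best$par)
    rss <- best$deviance
    converged <- best$info %in% 1:4 && is.finite(rss)
    diagnostics <- list(info = best$info, message = best$message,
                        niter = best$niter)
  }

  structure(list(
    model = model,
    params = params,
    fixed = names(fixed),
    free = free,
    rss = rss,
    n = n,
    k_params = length(free) + 1L,
    converged = converged,
    diagnostics = diagnostics,
    data = data
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: %s (n = %d, %s)\n", x$model, x$n,
              if (x$converged) "converged" else "NOT converged"))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  if (length(x$fixed) > 0L) cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g cm^2, k = %d\n", x$rss, x$k_params))
  invisible(x)
}

#' Predict length-at-age from a fitted growth model
#'
#' @param object A `growth_fit`.
#' @param ages Ages in years.
#' @param ... Ignored.
#' @return Numeric vector of predicted lengths (cm).
#' @export
predict.growth_fit <- function(object, ages, ...) {
  growth_length(object$model, object$params, ages)
}

#' Small-sample corrected Akaike information criterion
#'
#' Gaussian least-squares form with the error variance profiled out:
#' `AIC = n log(rss/n) + 2k`, `AICc = AIC + 2k(k+1)/(n-k-1)`, where `k`
#' counts the free parameters plus one for the error variance.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param k_params Number of estimated parameters including the error
#'   variance.
#' @return AICc value.
#' @export
#' @examples
#' aicc(rss = 100, n = 50, k_params = 4)
aicc <- function(rss, n, k_params) {
  stopifnot(is.numeric(rss), is.numeric(n), is.numeric(k_params))
  if (rss <= 0) stop("rss must be positive", call. = FALSE)
  if (n <= k_params + 1) {
    stop("AICc undefined: need n > k_params + 1 (got n = ", n,
         ", k = ", k_params, ")", call. = FALSE)
  }
  n * log(rss / n) + 2 * k_params + (2 * k_params * (k_params + 1)) / (n - k_params - 1)
}

#' Akaike weights from a set of AICc values
#'
#' Relative evidence weights `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with
#' `d_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector of AICc values (at least one finite).
#' @return Numeric vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(100, 102))  # ~ 0.731, 0.269
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0L || !any(is.finite(aicc_values))) {
    stop("need at least one finite AICc value", call. = FALSE)
  }
  delta <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-delta / 2)
  w / sum(w, na.rm = TRUE)
}

#' Select one measurement per individual
#'
#' Growth curves are fitted to a single randomly selected measurement per
#' individual, so repeated photographs of the same animal do not enter the
#' fit as pseudo-replicates.
#'
#' @param measurements Data frame with at least an `individual_id` column;
#'   typically per-photo length estimates.
#' @param seed Integer seed making the selection reproducible.
#' @return Data frame with exactly one row per individual, in order of
#'   first appearance.
#' @export
select_one_per_individual <- function(measurements, seed = 1L) {
  stopifnot(is.data.frame(measurements), "individual_id" %in% names(measurements))
  set.seed(seed)
  ids <- unique(measurements$individual_id)
  rows <- vapply(ids, function(id) {
    i <- which(measurements$individual_id == id)
    if (length(i) == 1L) i else sample(i, 1L)
  }, integer(1))
  measurements[rows, , drop = FALSE]
}

#' Fit and rank candidate growth models by AICc
#'
#' Fits each requested model, drops non-converged fits, and ranks the rest
#' by AICc with delta-AICc and Akaike weights attached.
#'
#' @inheritParams fit_growth
#' @param models Character vector of model codes (default all four).
#' @param starts Optional named list of per-model starting-value lists.
#' @param fixings Optional named list of per-model fixed-parameter lists,
#'   e.g. `list(RGM = list(t0 = -0.1))`.
#' @return An object of class `growth_ranking`: list with `fits` (named
#'   list of `growth_fit`s) and `table` (data frame sorted by AICc with
#'   columns model, converged, rss, n, k_params, aicc, delta_aicc,
#'   akaike_weight).
#' @export
rank_models <- function(data, models = growth_models(), starts = list(),
                        fixings = list()) {
  fits <- lapply(models, function(m) {
    tryCatch(
      fit_growth(data, m, start = starts[[m]], fixed = fixings[[m]] %||% list()),
      error = function(e) structure(list(model = m, converged = FALSE,
                                         error = conditionMessage(e)),
                                    class = "growth_fit")
    )
  })
  names(fits) <- models
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < 2L) {
    bad <- models[!ok]
    stop("fewer than two models converged; failures: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(
    model = models[ok],
    rss = vapply(fits[ok], function(f) f$rss, numeric(1)),
    n = vapply(fits[ok], function(f) f$n, numeric(1)),
    k_params = vapply(fits[ok], function(f) f$k_params, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$aicc <- mapply(aicc, tab$rss, tab$n, tab$k_params)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$akaike_weight <- akaike_weights(tab$aicc)
  tab <- tab[order(tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab,
                 not_converged = models[!ok],
                 best = tab$model[1L]),
            class = "growth_ranking")
}

#' @export
print.growth_ranking <- function(x, ...) {
  cat("Growth model ranking (best first):\n")
  tab <- x$table
  tab$aicc <- round(tab$aicc, 2)
  tab$delta_aicc <- round(tab$delta_aicc, 2)
  tab$akaike_weight <- round(tab$akaike_weight, 3)
  print(tab, row.names = FALSE)
  if (length(x$not_converged) > 0L) {
    cat("not converged:", paste(x$not_converged, collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap a growth fit over individuals
#'
#' Resamples individuals with replacement, refits the model each iteration
#' (re-drawing one measurement per individual when repeated photographs are
#' present), and summarises the asymptotic length and predicted
#' length-at-age by medians with percentile confidence intervals.
#'
#' @param data Data frame with columns `individual_id`, `age_years`,
#'   `tl_cm`; may contain several rows (photographs) per individual.
#' @param model One of [growth_models()].
#' @param n_iter Number of bootstrap iterations (1000 in routine use).
#' @param ages_to_predict Ages (years) at which to summarise predicted
#'   length.
#' @param seed Integer seed.
#' @param start,fixed Passed to [fit_growth()]; the baseline estimates are
#'   used as starting values for the resampled refits.
#' @param conf Confidence level for the percentile intervals.
#' @return Object of class `growth_boot`: baseline fit, `L_inf` summary
#'   (median, lo, hi), `laa` data frame (age, median, lo, hi), raw draws,
#'   and the count of non-converged iterations (these are dropped; a
#'   warning field is set when they exceed 20%).
#' @export
bootstrap_growth <- function(data, model, n_iter = 1000,
                             ages_to_predict = c(1, 3, 12, 25), seed = 1L,
                             start = NULL, fixed = list(), conf = 0.95) {
  stopifnot(is.data.frame(data),
            all(c("individual_id", "age_years", "tl_cm") %in% names(data)))
  set.seed(seed)
  by_id <- split(seq_len(nrow(data)), data$individual_id)
  one_per <- vapply(by_id, function(i) if (length(i) == 1L) i else sample(i, 1L),
                    integer(1))
  baseline <- fit_growth(data[one_per, , drop = FALSE], model,
                         start = start, fixed = fixed)
  if (!baseline$converged) {
    stop("baseline growth fit did not converge; cannot bootstrap", call. = FALSE)
  }
  start_boot <- baseline$params[baseline$free]

  n_id <- length(by_id)
  linf_draws <- rep(NA_real_, n_iter)
  laa_draws <- matrix(NA_real_, nrow = n_iter, ncol = length(ages_to_predict),
                      dimnames = list(NULL, paste0("age_", ages_to_predict)))
  for (b in seq_len(n_iter)) {
    pick <- sample.int(n_id, n_id, replace = TRUE)
    rows <- vapply(by_id[pick], function(i) {
      if (length(i) == 1L) i else sample(i, 1L)
    }, integer(1))
    fit <- tryCatch(
      fit_growth(data[rows, , drop = FALSE], model,
                 start = start_boot, fixed = fixed),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    linf_draws[b] <- fit$params$L_inf
    laa_draws[b, ] <- predict(fit, ages_to_predict)
  }
  ok <- is.finite(linf_draws) & apply(is.finite(laa_draws), 1L, all)
  n_failed <- sum(!ok)
  if (n_failed == n_iter) stop("all bootstrap iterations failed", call. = FALSE)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  qs <- apply(laa_draws[ok, , drop = FALSE], 2, stats::quantile, probs = probs)
  laa <- data.frame(
    age = ages_to_predict,
    median = apply(laa_draws[ok, , drop = FALSE], 2, stats::median),
    lo = qs[1L, ],
    hi = qs[2L, ],
    row.names = NULL
  )
  res <- list(
    baseline = baseline,
    L_inf = c(median = stats::median(linf_draws[ok]),
              lo = unname(stats::quantile(linf_draws[ok], probs[1L])),
              hi = unname(stats::quantile(linf_draws[ok], probs[2L]))),
    laa = laa,
    draws = list(L_inf = linf_draws[ok], laa = laa_draws[ok, , drop = FALSE]),
    n_iter = n_iter,
    n_failed = n_failed,
    conf = conf,
    warning = if (n_failed > 0.2 * n_iter) {
      sprintf("%d of %d bootstrap iterations failed to converge", n_failed, n_iter)
    }
  )
  class(res) <- "growth_boot"
  res
}

#' @export
print.growth_boot <- function(x, ...) {
  cat(sprintf("Bootstrap of %s fit (%d iterations, %d failed)\n",
              x$baseline$model, x$n_iter, x$n_failed))
  cat(sprintf("  L_inf median %.1f cm (%.0f%% CI %.1f-%.1f)\n",
              x$L_inf["median"], 100 * x$conf, x$L_inf["lo"], x$L_inf["hi"]))
  print(round(x$laa, 2), row.names = FALSE)
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}
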