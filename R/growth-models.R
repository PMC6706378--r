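#' Growth model identifiers
#'
#' The four candidate length-at-age growth functions: the original von
#' Bertalanffy (`"OvB"`, parameterised by length at birth), the typical von
#' Bertalanffy (`"TvB"`, parameterised by the zero-length age t0), the
#' Gompertz function (`"GOM"`) and the Richards growth model (`"RGM"`,
#' a shape-flexible generalisation of TvB).
#'
#' @return Character vector of the four model codes.
#' @export
growth_models <- function() c("OvB", "TvB", "GOM", "RGM")

#' Parameter names required by a growth model
#'
#' @param model One of [growth_models()].
#' @return Character vector of parameter names:
#'   * `L_inf` — asymptotic average length (cm), all models;
#'   * `K` — Brody growth rate coefficient (1/years), OvB, TvB, RGM;
#'   * `L0` — mean length at birth (cm), OvB only;
#'   * `t0` — age at which average length would be zero, or the inflection
#'     locator (years), TvB, GOM, RGM;
#'   * `gi` — instantaneous growth rate at the inflection (1/years), GOM;
#'   * `p_shape` — dimensionless curve-shape parameter, RGM.
#' @export
growth_param_names <- function(model) {
  model <- match.arg(model, growth_models())
  switch(model,
    OvB = c("L_inf", "K", "L0"),
    TvB = c("L_inf", "K", "t0"),
    GOM = c("L_inf", "gi", "t0"),
    RGM = c("L_inf", "K", "t0", "p_shape")
  )
}

check_growth_params <- function(model, params) {
  need <- growth_param_names(model)
  params <- as.list(params)
  miss <- setdiff(need, names(params))
  if (length(miss) > 0L) {
    stop("model ", model, " requires parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(params[need], function(v) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("growth parameters must be finite scalars", call. = FALSE)
    }
  })
  params[need]
}

#' Evaluate a growth function at given ages
#'
#' Predicted mean total length at age `t` under one of the four candidate
#' models:
#' \deqn{OvB: L_t = L_\infty - (L_\infty - L_0) e^{-Kt}}
#' \deqn{TvB: L_t = L_\infty (1 - e^{-K(t - t_0)})}
#' \deqn{GOM: L_t = L_\infty e^{-e^{-g_i(t - t_0)}}}
#' \deqn{RGM: L_t = L_\infty (1 - e^{-K(t - t_0)})^p}
#'
#' Ages below `t0` are permitted; TvB then returns negative (non-physical)
#' lengths and RGM returns `NaN` because a negative base cannot be raised to
#' a fractional power.
#'
#' @param model One of [growth_models()].
#' @param params Named numeric vector or list holding the parameters the
#'   model requires (see [growth_param_names()]).
#' @param t Ages in years (vectorised).
#' @return Numeric vector of lengths in cm, same length as `t`.
#' @export
#' @examples
#' growth_length("TvB", c(L_inf = 245, K = 0.3, t0 = -1), t = c(0, 1, 5))
growth_length <- function(model, params, t) {
  model <- match.arg(model, growth_models())
  p <- check_growth_params(model, params)
  switch(model,
    OvB = p$L_inf - (p$L_inf - p$L0) * exp(-p$K * t),
    TvB = p$L_inf * (1 - exp(-p$K * (t - p$t0))),
    GOM = p$L_inf * exp(-exp(-p$gi * (t - p$t0))),
    RGM = {
      base <- 1 - exp(-p$K * (t - p$t0))
      out <- rep(NaN, length(t))
      ok <- base >= 0
      out[ok] <- p$L_inf * base[ok]^p$p_shape
      out
    }
  )
}

# Default starting values: asymptote from the largest observed animal,
# birth length from the smallest, moderate rates, near-zero t0.
default_growth_start <- function(model, data) {
  full <- list(
    L_inf = max(data$tl_cm), K = 0.5, t0 = -0.1,
    L0 = min(data$tl_cm), gi = 0.5, p_shape = 1.5
  )
  full[growth_param_names(model)]
}

growth_param_bounds <- function(model, data) {
  max_tl <- max(data$tl_cm)
  lower <- c(L_inf = 1e-6, K = 1e-6, t0 = -50, L0 = 1e-6, gi = 1e-6,
             p_shape = 1e-6)
  upper <- c(L_inf = 2 * max_tl, K = 5, t0 = 50, L0 = 2 * max_tl, gi = 5,
             p_shape = 20)
  nm <- growth_param_names(model)
  list(lower = lower[nm], upper = upper[nm])
}
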