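#' Convert a landmark pixel distance to centimetres
#'
#' The paired laser dots project a known scale (10 cm by default) into each
#' photograph; a landmark distance in pixels is converted as
#' `laser_spacing_cm * bhdf_px / laser_px`. The conversion is invariant to
#' rescaling both pixel distances by the same factor, so image resolution
#' and range to the animal drop out.
#'
#' @param bhdf_px Landmark (blowhole to dorsal fin) distance in pixels.
#' @param laser_px Laser-dot separation in pixels.
#' @param laser_spacing_cm Physical laser spacing in cm (default 10).
#' @return Distance in cm (vectorised).
#' @export
#' @examples
#' pixels_to_cm(350, 100)  # 35 cm
pixels_to_cm <- function(bhdf_px, laser_px, laser_spacing_cm = 10) {
  if (any(bhdf_px <= 0) || any(laser_px <= 0) || any(laser_spacing_cm <= 0)) {
    stop("pixel distances and laser spacing must be positive", call. = FALSE)
  }
  laser_spacing_cm * bhdf_px / laser_px
}

#' Construct an allometric calibration
#'
#' Linear relationship `TL = intercept + slope * BH-DF` used to convert a
#' blowhole-to-dorsal-fin length into a total-length estimate. The default
#' constants are the published post-mortem calibration for Indo-Pacific
#' bottlenose dolphins (TL = 5.0583 + 3.17 x BH-DF, R^2 = 0.992, n = 12),
#' used when no calibration pairs of one's own are available.
#'
#' @param intercept_cm Intercept in cm.
#' @param slope Dimensionless slope (> 0).
#' @param r_squared Coefficient of determination of the underlying fit.
#' @param n_pairs Number of calibration pairs behind the fit.
#' @return Object of class `allometric_calibration`.
#' @export
allometric_calibration <- function(intercept_cm = 5.0583, slope = 3.17,
                                   r_squared = 0.992, n_pairs = 12L) {
  if (slope <= 0) stop("allometric slope must be positive", call. = FALSE)
  if (r_squared < 0 || r_squared > 1) stop("r_squared must lie in [0, 1]",
                                           call. = FALSE)
  structure(list(intercept_cm = intercept_cm, slope = slope,
                 r_squared = r_squared, n_pairs = as.integer(n_pairs)),
            class = "allometric_calibration")
}

#' @export
print.allometric_calibration <- function(x, ...) {
  cat(sprintf("TL = %.4f + %.4f x BH-DF  (R^2 = %.3f, n = %d)\n",
              x$intercept_cm, x$slope, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Fit the BH-DF to total-length allometry
#'
#' Ordinary least squares of total length on blowhole-to-dorsal-fin length
#' over post-mortem calibration pairs.
#'
#' @param pairs Data frame with columns `bhdf_cm` and `tl_cm`.
#' @return An [allometric_calibration()] carrying the fitted intercept,
#'   slope, R^2 and n.
#' @export
fit_allometry <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("bhdf_cm", "tl_cm") %in% names(pairs)))
  if (nrow(pairs) < 3L) {
    stop("need at least 3 calibration pairs", call. = FALSE)
  }
  if (stats::var(pairs$bhdf_cm) <= 0) {
    stop("degenerate calibration design: BH-DF values are all equal",
         call. = FALSE)
  }
  fit <- stats::lm(tl_cm ~ bhdf_cm, data = pairs)
  co <- stats::coef(fit)
  allometric_calibration(
    intercept_cm = unname(co[1L]),
    slope = unname(co[2L]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_pairs = nrow(pairs)
  )
}

#' Predict total length from BH-DF
#'
#' @param calibration An [allometric_calibration()].
#' @param bhdf_cm Blowhole-to-dorsal-fin length in cm (vectorised).
#' @return Total length in cm.
#' @export
predict_tl <- function(calibration, bhdf_cm) {
  stopifnot(inherits(calibration, "allometric_calibration"))
  if (any(bhdf_cm < 0)) stop("BH-DF must be non-negative", call. = FALSE)
  calibration$intercept_cm + calibration$slope * bhdf_cm
}

#' Per-photo length estimates
#'
#' Converts every photograph's pixel distances to a BH-DF and total-length
#' estimate, keeping one row per photo (no per-individual averaging).
#'
#' @param photos Data frame with columns `individual_id`, `laser_px`,
#'   `bhdf_px` and optionally `photo_id`.
#' @param calibration An [allometric_calibration()].
#' @param laser_spacing_cm Laser spacing in cm.
#' @return Data frame: `photo_id`, `individual_id`, `bhdf_cm`, `tl_cm`.
#' @export
photo_lengths <- function(photos, calibration = allometric_calibration(),
                          laser_spacing_cm = 10) {
  stopifnot(is.data.frame(photos),
            all(c("individual_id", "laser_px", "bhdf_px") %in% names(photos)))
  bhdf <- pixels_to_cm(photos$bhdf_px, photos$laser_px, laser_spacing_cm)
  data.frame(
    photo_id = if ("photo_id" %in% names(photos)) photos$photo_id else
      seq_len(nrow(photos)),
    individual_id = photos$individual_id,
    bhdf_cm = bhdf,
    tl_cm = predict_tl(calibration, bhdf),
    stringsAsFactors = FALSE
  )
}

#' Summarise repeated measurements of one individual
#'
#' Converts each photograph of one individual to a total-length estimate,
#' and reports the mean together with the coefficient of variation of the
#' repeats (sample SD over mean, in percent). The CV is `NA` when only a
#' single photograph is available.
#'
#' @param measurements Data frame of photographs of a single individual
#'   (columns `individual_id`, `laser_px`, `bhdf_px`).
#' @param calibration An [allometric_calibration()].
#' @param laser_spacing_cm Laser spacing in cm.
#' @return One-row data frame: `individual_id`, `bhdf_cm_mean`, `tl_cm`,
#'   `n_photos`, `cv_percent`.
#' @export
summarize_individual <- function(measurements,
                                 calibration = allometric_calibration(),
                                 laser_spacing_cm = 10) {
  if (nrow(measurements) == 0L) stop("no measurements supplied", call. = FALSE)
  id <- unique(measurements$individual_id)
  if (length(id) != 1L) {
    stop("summarize_individual expects measurements of a single individual",
         call. = FALSE)
  }
  per <- photo_lengths(measurements, calibration, laser_spacing_cm)
  n <- nrow(per)
  data.frame(
    individual_id = id,
    bhdf_cm_mean = mean(per$bhdf_cm),
    tl_cm = mean(per$tl_cm),
    n_photos = n,
    cv_percent = if (n >= 2L) 100 * stats::sd(per$tl_cm) / mean(per$tl_cm)
                 else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-individual length estimates for a whole photo table
#'
#' @param photos Data frame with columns `individual_id`, `laser_px`,
#'   `bhdf_px` (and optionally `photo_id`).
#' @inheritParams summarize_individual
#' @return Data frame with one row per individual, as in
#'   [summarize_individual()].
#' @export
length_estimates <- function(photos, calibration = allometric_calibration(),
                             laser_spacing_cm = 10) {
  pieces <- split(photos, photos$individual_id)
  out <- do.call(rbind, lapply(pieces, summarize_individual,
                               calibration = calibration,
                               laser_spacing_cm = laser_spacing_cm))
  rownames(out) <- NULL
  out[order(out$individual_id), , drop = FALSE]
}

#' Measurement-precision summary over individuals
#'
#' Mean and range of the per-individual CV of repeated total-length
#' estimates (individuals with at least two photographs), and the mean
#' number of photographs per individual with its standard error.
#'
#' @param estimates Per-individual estimates from [length_estimates()].
#' @return List with `mean_cv_percent`, `cv_range`, `n_with_repeats`,
#'   `mean_photos`, `se_photos`, `n_individuals`. CV fields are `NULL`
#'   when no individual has repeats.
#' @export
precision_report <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("n_photos", "cv_percent") %in% names(estimates)))
  cvs <- estimates$cv_percent[estimates$n_photos >= 2L]
  cvs <- cvs[is.finite(cvs)]
  n <- nrow(estimates)
  list(
    mean_cv_percent = if (length(cvs) > 0L) mean(cvs) else NULL,
    cv_range = if (length(cvs) > 0L) range(cvs) else NULL,
    n_with_repeats = length(cvs),
    mean_photos = mean(estimates$n_photos),
    se_photos = if (n >= 2L) stats::sd(estimates$n_photos) / sqrt(n) else NA_real_,
    n_individuals = n
  )
}
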