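ACCURACY_CLASSES <- c("day", "week", "month", "year", "three_year", "open")

# Half-widths (years) of the age window for each accuracy class; "open"
# animals keep their minimum age and are capped at the accepted maximum
# life expectancy of 45 years.
ACCURACY_HALF_WIDTH <- c(day = 7 / 365, week = 28 / 365, month = 1 / 12,
                         year = 0.5, three_year = 1.5, open = NA_real_)

MAX_LIFESPAN_YEARS <- 45

#' Configuration of a synthetic regional population
#'
#' Bundles everything the generator needs for one region: the true growth
#' model and parameters, the age distribution and the mix of
#' age-estimation accuracy classes, photogrammetric measurement error, and
#' the logistic curves driving independence and first-reproduction
#' statuses. All randomness derives from the single integer `seed`.
#'
#' @param region_label Short region name (e.g. `"SW"`).
#' @param n_individuals Number of animals (>= 1).
#' @param true_model One of [growth_models()].
#' @param true_params Named list of parameters for `true_model` (cm,
#'   1/years, years; see [growth_param_names()]).
#' @param sex_ratio Proportion female among sexed animals, in \[0, 1\].
#' @param unknown_sex_frac Fraction of animals of unknown sex.
#' @param age_distribution `c(min, max)` years for uniform age sampling.
#' @param accuracy_mix Named proportions over the age-accuracy classes
#'   `r paste(ACCURACY_CLASSES, collapse = ", ")`; must sum to 1. The
#'   "open" class (minimum age kept, maximum capped at 45 years) describes
#'   animals first sighted as adults, so it is only assigned to animals at
#'   least `open_min_age` old; younger animals drawing it fall back to the
#'   three-year class.
#' @param open_min_age Youngest true age (years) eligible for the "open"
#'   accuracy class; default 15, the age by which growth has essentially
#'   ceased.
#' @param measurement_cv Fractional SD of the multiplicative (log-normal)
#'   per-photo length error (e.g. 0.019 for a 1.9% repeat CV).
#' @param photos_per_individual `c(min, max)` integer photographs per
#'   animal.
#' @param laser_px_range `c(min, max)` pixel separation of the 10 cm laser
#'   scale, emulating variable range to the animal.
#' @param true_a50_indep,true_a50_repro True ages (years) at 50%
#'   independence / first reproduction.
#' @param logistic_slope_indep,logistic_slope_repro Logistic slopes
#'   (1/years) of the status curves.
#' @param seed Integer seed.
#' @return Object of class `population_config` (a validated list).
#' @export
population_config <- function(region_label,
                              n_individuals,
                              true_model = "RGM",
                              true_params,
                              sex_ratio = 0.5,
                              unknown_sex_frac = 0.15,
                              age_distribution = c(0, 30),
                              accuracy_mix = c(day = 0.15, week = 0.15,
                                               month = 0.2, year = 0.2,
                                               three_year = 0.1, open = 0.2),
                              open_min_age = 15,
                              measurement_cv = 0.019,
                              photos_per_individual = c(3, 10),
                              laser_px_range = c(60, 200),
                              true_a50_indep = 3.0,
                              true_a50_repro = 10.3,
                              logistic_slope_indep = 2.0,
                              logistic_slope_repro = 1.0,
                              seed = 1L) {
  true_model <- match.arg(true_model, growth_models())
  check_growth_params(true_model, true_params)
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be >= 1", call. = FALSE)
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]",
                                           call. = FALSE)
  if (unknown_sex_frac < 0 || unknown_sex_frac > 1) {
    stop("unknown_sex_frac must lie in [0, 1]", call. = FALSE)
  }
  if (length(age_distribution) != 2L || age_distribution[1L] < 0 ||
      diff(age_distribution) < 0) {
    stop("age_distribution must be c(min, max) with 0 <= min <= max",
         call. = FALSE)
  }
  if (is.null(names(accuracy_mix)) ||
      !all(names(accuracy_mix) %in% ACCURACY_CLASSES)) {
    stop("accuracy_mix must be named with classes among: ",
         paste(ACCURACY_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(accuracy_mix) - 1) > 1e-9) {
    stop("accuracy_mix proportions must sum to 1 (got ",
         format(sum(accuracy_mix)), ")", call. = FALSE)
  }
  if (measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)
  if (length(photos_per_individual) != 2L ||
      photos_per_individual[1L] < 1 ||
      photos_per_individual[1L] > photos_per_individual[2L]) {
    stop("photos_per_individual must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  structure(list(
    region_label = region_label,
    n_individuals = as.integer(n_individuals),
    true_model = true_model,
    true_params = as.list(true_params),
    sex_ratio = sex_ratio,
    unknown_sex_frac = unknown_sex_frac,
    age_distribution = age_distribution,
    accuracy_mix = accuracy_mix,
    open_min_age = open_min_age,
    measurement_cv = measurement_cv,
    photos_per_individual = as.integer(photos_per_individual),
    laser_px_range = laser_px_range,
    true_a50_indep = true_a50_indep,
    true_a50_repro = true_a50_repro,
    logistic_slope_indep = logistic_slope_indep,
    logistic_slope_repro = logistic_slope_repro,
    seed = as.integer(seed)
  ), class = "population_config")
}

#' Preset configuration resembling the south-western population
#'
#' Richards truth with an asymptote of 245 cm and parameters chosen so the
#' true curve passes through a 107.6 cm birth length, 155.9 cm at age 1
#' and 187.1 cm at age 3. A fifth of animals are first sighted as adults
#' ("open" age class, capped at 45 years).
#'
#' @param n_individuals Sample size (129 mirrors the study).
#' @param seed Integer seed.
#' @param ... Overrides passed to [population_config()].
#' @return A `population_config`.
#' @export
sw_population_config <- function(n_individuals = 129, seed = 1L, ...) {
  defaults <- list(
    region_label = "SW",
    n_individuals = n_individuals,
    true_model = "RGM",
    true_params = list(L_inf = 245, K = 0.0971, t0 = -0.1821, p_shape = 0.2035),
    age_distribution = c(0, 30),
    accuracy_mix = c(day = 0.15, week = 0.15, month = 0.2, year = 0.2,
                     three_year = 0.1, open = 0.2),
    measurement_cv = 0.019,
    photos_per_individual = c(3, 10),
    true_a50_indep = 3.0,
    true_a50_repro = 10.3,
    seed = seed
  )
  do.call(population_config, utils::modifyList(defaults, list(...)))
}

#' Preset configuration resembling the Shark Bay population
#'
#' Richards truth with a 200 cm asymptote passing close to a 102.8 cm
#' birth length, 120.1 cm at age 1 and 149.5 cm at age 3. All animals have
#' closed age windows (accurate to within three years at worst), matching
#' a long-running monitored population.
#'
#' @inheritParams sw_population_config
#' @return A `population_config`.
#' @export
sb_population_config <- function(n_individuals = 74, seed = 2L, ...) {
  defaults <- list(
    region_label = "SB",
    n_individuals = n_individuals,
    true_model = "RGM",
    true_params = list(L_inf = 200, K = 0.2621, t0 = -7.638, p_shape = 4.609),
    age_distribution = c(0, 40),
    accuracy_mix = c(day = 0.3, week = 0.3, month = 0.2, year = 0.1,
                     three_year = 0.1),
    measurement_cv = 0.017,
    photos_per_individual = c(2, 8),
    true_a50_indep = 4.8,
    true_a50_repro = 11.9,
    seed = seed
  )
  do.call(population_config, utils::modifyList(defaults, list(...)))
}

#' Generate a synthetic population with age-uncertainty windows
#'
#' Draws each animal's true age uniformly from the configured range,
#' assigns an age-accuracy class and the corresponding min/max age window
#' (centred on the true age; "open" animals keep their minimum age and are
#' capped at 45 years), a sex, and the true total length from the
#' configured growth curve, together with the true blowhole-to-dorsal-fin
#' length implied by inverting the allometric calibration.
#'
#' @param config A [population_config()].
#' @param calibration [allometric_calibration()] used to derive the true
#'   BH-DF from the true TL.
#' @return List with `records` (data frame: individual_id, region, sex,
#'   min_age_years, max_age_years, accuracy_class) and `truth` (data
#'   frame: individual_id, true_age, true_tl, true_bhdf).
#' @export
generate_population <- function(config,
                                calibration = allometric_calibration()) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  true_age <- stats::runif(n, config$age_distribution[1L],
                           config$age_distribution[2L])
  classes <- sample(names(config$accuracy_mix), n, replace = TRUE,
                    prob = config$accuracy_mix)
  # only animals first sighted as adults carry an open-ended age window
  classes[classes == "open" & true_age < config$open_min_age] <- "three_year"
  hw <- ACCURACY_HALF_WIDTH[classes]
  min_age <- ifelse(classes == "open", true_age, pmax(0, true_age - hw))
  max_age <- ifelse(classes == "open", MAX_LIFESPAN_YEARS, true_age + hw)
  sex_draw <- stats::runif(n)
  sex <- ifelse(sex_draw < config$unknown_sex_frac, "U",
                ifelse(stats::runif(n) < config$sex_ratio, "F", "M"))
  true_tl <- growth_length(config$true_model, config$true_params, true_age)
  true_bhdf <- (true_tl - calibration$intercept_cm) / calibration$slope
  ids <- sprintf("%s-%03d", config$region_label, seq_len(n))
  list(
    records = data.frame(
      individual_id = ids,
      region = config$region_label,
      sex = sex,
      min_age_years = min_age,
      max_age_years = max_age,
      accuracy_class = classes,
      stringsAsFactors = FALSE
    ),
    truth = data.frame(
      individual_id = ids,
      true_age = true_age,
      true_tl = true_tl,
      true_bhdf = true_bhdf,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate repeated photogrammetric measurements
#'
#' For each animal, draws a number of photographs uniformly from the
#' configured range. Each photograph gets a laser-dot pixel separation
#' (representing the 10 cm scale at a random range to the animal) and a
#' BH-DF pixel distance equal to the true BH-DF scaled by the same px/cm
#' factor, perturbed by multiplicative log-normal error with SD
#' `measurement_cv`. An optional foreshortening mode additionally
#' multiplies the landmark distance by cos(theta) for a horizontal angle
#' theta (drawn uniformly up to `max_angle_deg`, or fixed at
#' `angle_deg`).
#'
#' @param records,truth Output of [generate_population()].
#' @param config The [population_config()].
#' @param calibration The same calibration used to derive true BH-DF.
#' @param laser_spacing_cm Physical laser spacing (cm).
#' @param foreshortening Logical; apply a horizontal-angle projection.
#' @param angle_deg Fixed foreshortening angle in degrees (overrides the
#'   uniform draw).
#' @param max_angle_deg Upper bound of the uniform angle draw (<= 15 in
#'   routine use, matching image-selection practice).
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return Data frame: photo_id, individual_id, laser_px, bhdf_px.
#' @export
generate_measurements <- function(records, truth, config,
                                  calibration = allometric_calibration(),
                                  laser_spacing_cm = 10,
                                  foreshortening = FALSE,
                                  angle_deg = NULL,
                                  max_angle_deg = 15,
                                  seed = config$seed + 1L) {
  stopifnot(inherits(config, "population_config"))
  bad <- truth$individual_id[truth$true_bhdf <= 0]
  if (length(bad) > 0L) {
    stop("non-positive true BH-DF for individual(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  pr <- config$photos_per_individual
  k <- sample(seq(pr[1L], pr[2L]), nrow(records), replace = TRUE)
  idx <- rep(seq_len(nrow(records)), k)
  n_photo <- length(idx)
  laser_px <- stats::runif(n_photo, config$laser_px_range[1L],
                           config$laser_px_range[2L])
  err <- exp(stats::rnorm(n_photo, 0, config$measurement_cv))
  proj <- 1
  if (foreshortening) {
    theta <- if (!is.null(angle_deg)) rep(angle_deg, n_photo) else
      stats::runif(n_photo, 0, max_angle_deg)
    proj <- cos(theta * pi / 180)
  }
  px_per_cm <- laser_px / laser_spacing_cm
  data.frame(
    photo_id = sprintf("%s-P%02d", records$individual_id[idx],
                       sequence(k)),
    individual_id = records$individual_id[idx],
    laser_px = laser_px,
    bhdf_px = truth$true_bhdf[idx] * px_per_cm * err * proj,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic post-mortem calibration pairs
#'
#' BH-DF values spread uniformly over a range, with total length following
#' the linear allometry plus Gaussian noise.
#'
#' @param n Number of pairs (>= 3; the regression and R^2 need at least
#'   three points).
#' @param intercept,slope True line (defaults are the published
#'   calibration constants).
#' @param noise_sd SD (cm) of additive Gaussian noise on TL.
#' @param seed Integer seed.
#' @param bhdf_range `c(min, max)` cm for the BH-DF spread.
#' @return Data frame: bhdf_cm, tl_cm.
#' @export
generate_calibration_pairs <- function(n = 12, intercept = 5.0583,
                                       slope = 3.17, noise_sd = 2,
                                       seed = 1L, bhdf_range = c(30, 75)) {
  if (n < 3) stop("need n >= 3 calibration pairs for a regression with R^2",
                  call. = FALSE)
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  set.seed(seed)
  bhdf <- stats::runif(n, bhdf_range[1L], bhdf_range[2L])
  data.frame(
    bhdf_cm = bhdf,
    tl_cm = intercept + slope * bhdf + stats::rnorm(n, 0, noise_sd)
  )
}

#' Assign independence and first-reproduction statuses
#'
#' Independence status is a Bernoulli draw with success probability
#' `plogis(slope_indep * (true_age - a50_indep))`; first-reproduction
#' status is drawn analogously but assigned to females only (males and
#' unknown-sex animals get `NA`). Statuses are coded 0/1.
#'
#' @param records,truth Output of [generate_population()].
#' @param config The [population_config()].
#' @param seed Integer seed (defaults to `config$seed + 2`).
#' @return `records` with integer columns `independent` and `reproduced`
#'   appended.
#' @export
generate_maturity_status <- function(records, truth, config,
                                     seed = config$seed + 2L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(seed)
  age <- truth$true_age[match(records$individual_id, truth$individual_id)]
  p_ind <- stats::plogis(config$logistic_slope_indep *
                           (age - config$true_a50_indep))
  records$independent <- stats::rbinom(nrow(records), 1L, p_ind)
  p_rep <- stats::plogis(config$logistic_slope_repro *
                           (age - config$true_a50_repro))
  repro <- stats::rbinom(nrow(records), 1L, p_rep)
  repro[records$sex != "F"] <- NA_integer_
  records$reproduced <- repro
  records
}

#' Simulate a complete regional study
#'
#' Chains population, measurement, calibration-pair and maturity-status
#' generation for one region, optionally writing the four standard CSV
#' tables (individuals.csv, photos.csv, calibration.csv, truth.csv).
#'
#' @param config A [population_config()].
#' @param calibration An [allometric_calibration()] defining the true
#'   allometry.
#' @param calibration_n,calibration_noise_sd Size and noise of the
#'   synthetic post-mortem sample.
#' @param out_dir Optional directory for CSV output.
#' @return List with `records`, `truth`, `photos`, `calibration_pairs`,
#'   `config`.
#' @export
simulate_study <- function(config,
                           calibration = allometric_calibration(),
                           calibration_n = 12,
                           calibration_noise_sd = 2,
                           out_dir = NULL) {
  pop <- generate_population(config, calibration)
  pop$records <- generate_maturity_status(pop$records, pop$truth, config)
  photos <- generate_measurements(pop$records, pop$truth, config, calibration)
  pairs <- generate_calibration_pairs(
    n = calibration_n, intercept = calibration$intercept_cm,
    slope = calibration$slope, noise_sd = calibration_noise_sd,
    seed = config$seed + 3L
  )
  out <- list(records = pop$records, truth = pop$truth, photos = photos,
              calibration_pairs = pairs, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pop$records, file.path(out_dir, "individuals.csv"),
                     row.names = FALSE)
    utils::write.csv(photos, file.path(out_dir, "photos.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(pop$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}
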