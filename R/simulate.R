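#' Default biomarker panel
#'
#' The twelve measurables of the liquid-biopsy panel: the four comet-assay
#' DNA-damage class fractions (class I = mostly intact DNA, class IV = heavily
#' damaged), six leucocyte protein expression read-outs and two serum
#' metalloproteinase activities.
#'
#' @return Character vector of column names.
#' @export
default_biomarkers <- function() {
  c("comet_i", "comet_ii", "comet_iii", "comet_iv",
    "s100", "catalase", "profilin", "rhoa", "sod2", "thioredoxin",
    "mmp2", "mmp9")
}

comet_classes <- function(biomarkers) {
  intersect(c("comet_i", "comet_ii", "comet_iii", "comet_iv"), biomarkers)
}

default_subgroup_means <- function() {
  bm <- default_biomarkers()
  m <- matrix(0, nrow = 3, ncol = length(bm), dimnames = list(NULL, bm))
  # comet class mean fractions per latent subgroup: the poor-prognosis group
  # carries heavy DNA damage (classes III/IV), the good-prognosis group mostly
  # intact DNA (class I)
  m[, c("comet_i", "comet_ii", "comet_iii", "comet_iv")] <- rbind(
    c(0.15, 0.15, 0.30, 0.40),
    c(0.40, 0.25, 0.20, 0.15),
    c(0.70, 0.17, 0.08, 0.05))
  # protein / activity markers in standardised units: adjacent subgroups are
  # separated by 3x the noise SD on the six prognostic markers, poor-prognosis
  # group highest; catalase and MMP-2 carry no subgroup signal
  signal <- c("s100", "profilin", "rhoa", "sod2", "thioredoxin", "mmp9")
  m[, signal] <- matrix(rep(c(6, 3, 0), length(signal)), nrow = 3)
  m
}

default_hazard_coefficients <- function() {
  bm <- default_biomarkers()
  beta <- setNames(numeric(length(bm)), bm)
  beta[c("s100", "profilin", "sod2")] <- 0.05
  beta[c("rhoa", "thioredoxin", "mmp9")] <- 0.025
  beta["comet_iv"] <- 1.0
  beta["comet_i"] <- -0.4
  beta
}

default_confounder_coefficients <- function() {
  list(age = 0.015, gender = c(male = 0.0),
       therapy = c(TACE = 0.1),
       diagnosis = c(CRC = 0.1, breast = -0.1, other = 0.05))
}

#' Configure a synthetic palliative-cohort simulation
#'
#' Describes a cohort with latent patient subgroups, subgroup-shifted biomarker
#' distributions, proportional-hazards survival times driven by the biomarkers
#' and confounders, and right censoring (random plus administrative). The
#' defaults describe the validation scenario used throughout the package:
#' `n_patients = 108`, three latent subgroups, a twelve-biomarker panel in which
#' six prognostic markers are shifted by three noise standard deviations between
#' adjacent subgroups, a Weibull baseline hazard (shape 1.2, scale 24 months),
#' a target censored fraction of 30% and administrative censoring at 60 months
#' (five years of follow-up).
#'
#' @param n_patients Number of patients.
#' @param n_subgroups Number of latent subgroups.
#' @param biomarker_names Biomarker column names. Names starting with
#'   `comet_` are treated as a compositional group and drawn from a Dirichlet
#'   distribution (fractions summing to one per patient).
#' @param subgroup_biomarker_means `n_subgroups x biomarkers` matrix of
#'   subgroup means: mean class fractions for the comet columns, standardised
#'   means for the continuous columns.
#' @param biomarker_noise_sd Gaussian noise SD for the continuous biomarkers.
#' @param comet_precision Dirichlet precision (sum of concentration parameters)
#'   for the comet class fractions.
#' @param hazard_coefficients Named per-biomarker log hazard ratios per unit.
#' @param confounder_coefficients List with `age` (log HR per year, age centred
#'   at 65) and named contrasts for `gender`, `therapy`, `diagnosis`.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (scale in months).
#' @param censoring_rate Target fraction of right-censored patients, in
#'   \eqn{[0,1]}.
#' @param admin_censor_time Administrative censoring horizon in months.
#' @param confounded If `TRUE`, therapy assignment depends on the latent
#'   subgroup (robustness mode); by default confounders are independent of the
#'   subgroups.
#' @param seed Integer seed for reproducible generation.
#'
#' @return A `simulation_config` object (validated list).
#' @export
simulation_config <- function(n_patients = 108L,
                              n_subgroups = 3L,
                              biomarker_names = default_biomarkers(),
                              subgroup_biomarker_means = NULL,
                              biomarker_noise_sd = 1,
                              comet_precision = 50,
                              hazard_coefficients = NULL,
                              confounder_coefficients = default_confounder_coefficients(),
                              baseline_shape = 1.2,
                              baseline_scale = 24,
                              censoring_rate = 0.3,
                              admin_censor_time = 60,
                              confounded = FALSE,
                              seed = 1L) {
  if (is.null(subgroup_biomarker_means)) {
    rc_assert(identical(biomarker_names, default_biomarkers()) && n_subgroups == 3L,
              "subgroup_biomarker_means must be supplied for a non-default panel")
    subgroup_biomarker_means <- default_subgroup_means()
  }
  if (is.null(hazard_coefficients)) {
    hazard_coefficients <- if (identical(biomarker_names, default_biomarkers())) {
      default_hazard_coefficients()
    } else {
      setNames(numeric(length(biomarker_names)), biomarker_names)
    }
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), n_subgroups = as.integer(n_subgroups),
    biomarker_names = biomarker_names,
    subgroup_biomarker_means = subgroup_biomarker_means,
    biomarker_noise_sd = biomarker_noise_sd, comet_precision = comet_precision,
    hazard_coefficients = hazard_coefficients,
    confounder_coefficients = confounder_coefficients,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    censoring_rate = censoring_rate, admin_censor_time = admin_censor_time,
    confounded = isTRUE(confounded), seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param config A `simulation_config` object or plain list.
#' @return The validated config, invisibly usable; errors name the violated
#'   field.
#' @export
validate_simulation_config <- function(config) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) rc_abort(sprintf("invalid `%s`: %s", field, what),
                              class = "riskclust_config_error")
  }
  chk(is.numeric(config$n_patients) && config$n_patients >= 1, "n_patients",
      "must be a positive integer")
  chk(is.numeric(config$n_subgroups) && config$n_subgroups >= 1, "n_subgroups",
      "must be a positive integer")
  m <- config$subgroup_biomarker_means
  chk(is.matrix(m) && nrow(m) == config$n_subgroups,
      "subgroup_biomarker_means", "must have one row per subgroup")
  chk(ncol(m) == length(config$biomarker_names) &&
        identical(colnames(m), config$biomarker_names),
      "subgroup_biomarker_means", "must have one named column per biomarker")
  chk(config$biomarker_noise_sd > 0, "biomarker_noise_sd", "must be positive")
  chk(config$baseline_shape > 0, "baseline_shape", "must be positive")
  chk(config$baseline_scale > 0, "baseline_scale", "must be positive")
  chk(config$censoring_rate >= 0 && config$censoring_rate <= 1,
      "censoring_rate", "must lie in [0, 1]")
  chk(config$admin_censor_time > 0, "admin_censor_time", "must be positive")
  chk(all(config$biomarker_names %in% names(config$hazard_coefficients)),
      "hazard_coefficients", "must name every biomarker")
  cc <- comet_classes(config$biomarker_names)
  if (length(cc) > 0) {
    chk(length(cc) == 4, "biomarker_names",
        "comet classes must be present as the full I-IV group or not at all")
    props <- m[, cc, drop = FALSE]
    chk(all(props >= 0) && all(abs(rowSums(props) - 1) < 1e-8),
        "subgroup_biomarker_means",
        "comet-class mean fractions must be non-negative and sum to 1 per subgroup")
  }
  invisible(config)
}

#' Draw survival times from a Weibull-baseline proportional-hazards model
#'
#' Latent event times are drawn by inverse-transform sampling from
#' \eqn{T = \lambda (-\log U / e^{\eta})^{1/\kappa}} with baseline shape
#' \eqn{\kappa} and scale \eqn{\lambda}, so proportional hazards holds exactly.
#' Right censoring combines an exponential censoring time, whose rate is
#' calibrated by bisection so the expected censored fraction matches
#' `config$censoring_rate`, with administrative censoring at
#' `config$admin_censor_time`.
#'
#' @param linear_predictors Finite numeric vector of log relative hazards.
#' @param config A [simulation_config()].
#' @return A tibble with columns `time` (months) and `event` (1 = death
#'   observed, 0 = right-censored).
#' @export
generate_survival_times <- function(linear_predictors, config) {
  rc_assert(all(is.finite(linear_predictors)),
            "linear_predictors must be finite")
  validate_simulation_config(config)
  n <- length(linear_predictors)
  u <- runif(n)
  latent <- config$baseline_scale *
    (-log(u) / exp(linear_predictors))^(1 / config$baseline_shape)
  horizon <- config$admin_censor_time
  # expected censored fraction given the latent times, as a function of the
  # exponential censoring rate r:  P(cens_i) = 1 - e^{-r T_i} 1[T_i <= horizon]
  cens_frac <- function(r) 1 - mean(exp(-r * latent) * (latent <= horizon))
  target <- config$censoring_rate
  if (target <= cens_frac(0) + 1e-12) {
    cens <- rep(horizon, n)
  } else {
    lo <- 0; hi <- 1
    while (cens_frac(hi) < target && hi < 1e6) hi <- hi * 2
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (cens_frac(mid) < target) lo <- mid else hi <- mid
    }
    cens <- pmin(rexp(n, rate = (lo + hi) / 2), horizon)
  }
  tibble::tibble(time = pmin(latent, cens),
                 event = as.integer(latent <= cens))
}

draw_confounders <- function(n, subgroup, confounded) {
  age <- pmin(pmax(round(rnorm(n, 67, 10)), 35), 90)
  gender <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.4, 0.6))
  if (confounded) {
    # therapy allocation tracks the latent subgroup (robustness mode)
    p_tace <- c(0.75, 0.5, 0.25)[pmin(subgroup, 3)]
    therapy <- ifelse(runif(n) < p_tace, "TACE", "SIRT")
  } else {
    therapy <- sample(c("SIRT", "TACE"), n, replace = TRUE)
  }
  diagnosis <- sample(c("HCC", "CRC", "breast", "other"), n, replace = TRUE,
                      prob = c(0.40, 0.30, 0.15, 0.15))
  comorbidities <- sample(c("none", "diabetes", "cardiovascular", "multiple"),
                          n, replace = TRUE, prob = c(0.40, 0.20, 0.25, 0.15))
  tibble::tibble(age = as.numeric(age), gender = gender, therapy = therapy,
                 diagnosis = diagnosis, comorbidities = comorbidities)
}

confounder_linear_predictor <- function(conf, coefs) {
  lp <- coefs$age * (conf$age - 65)
  pick <- function(x, contrasts) {
    out <- numeric(length(x))
    for (lev in names(contrasts)) out[x == lev] <- contrasts[[lev]]
    out
  }
  lp + pick(conf$gender, as.list(coefs$gender)) +
    pick(conf$therapy, as.list(coefs$therapy)) +
    pick(conf$diagnosis, as.list(coefs$diagnosis))
}

#' Generate a synthetic cohort with planted survival subgroups
#'
#' Draws a cohort table matching the structure the analysis pipeline assumes:
#' uniform latent subgroup labels; continuous biomarkers as subgroup mean plus
#' Gaussian noise; comet class fractions from a subgroup-specific Dirichlet
#' distribution (summing to one per patient); confounders from simple
#' categorical/normal distributions, independent of subgroup unless
#' `config$confounded`; and survival times from the Weibull-baseline
#' proportional-hazards model of [generate_survival_times()], with the linear
#' predictor assembled from the biomarker hazard coefficients and the
#' confounder coefficients. Identical configs (including `seed`) give
#' bit-identical tables.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A tibble with columns `patient_id`, `time`, `event`, the
#'   confounders (`age`, `gender`, `therapy`, `diagnosis`, `comorbidities`),
#'   one column per biomarker, and `true_subgroup`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  set.seed(as.integer(seed))
  n <- config$n_patients
  subgroup <- sample.int(config$n_subgroups, n, replace = TRUE)
  means <- config$subgroup_biomarker_means
  cc <- comet_classes(config$biomarker_names)
  bm <- matrix(NA_real_, n, length(config$biomarker_names),
               dimnames = list(NULL, config$biomarker_names))
  for (name in setdiff(config$biomarker_names, cc)) {
    bm[, name] <- means[subgroup, name] + rnorm(n, 0, config$biomarker_noise_sd)
  }
  if (length(cc) > 0) {
    alpha <- means[, cc, drop = FALSE] * config$comet_precision
    g <- matrix(rgamma(n * length(cc), shape = alpha[subgroup, ]), nrow = n)
    bm[, cc] <- g / rowSums(g)
  }
  conf <- draw_confounders(n, subgroup, config$confounded)
  beta <- config$hazard_coefficients[config$biomarker_names]
  lp <- drop(bm %*% beta) +
    confounder_linear_predictor(conf, config$confounder_coefficients)
  surv <- generate_survival_times(lp, config)
  dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("P%03d", seq_len(n))),
    surv, conf, tibble::as_tibble(bm),
    tibble::tibble(true_subgroup = subgroup))
}
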