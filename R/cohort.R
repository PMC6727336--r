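# Clustered lesion cohort generator.
#
# Lesion features are drawn from marginals patterned on a breast MRI cohort
# (~40% malignancy prevalence, 1-3 lesions per patient); malignancy is drawn
# from a logistic model on clinical/DCE features plus a patient-level random
# intercept; DTI features are drawn from class-conditional distributions.

COEF_FEATURES <- c("age", "post_menopausal", "known_cancer", "dense_breasts",
                   "bpe", "log_size", "mass", "washout", "birads5")

#' Configuration for a synthetic lesion cohort
#'
#' Defines the generative model for a clustered breast-lesion cohort:
#' patient-level clinical covariates, lesion-level DCE features, a logistic
#' outcome model with a patient-level Gaussian random intercept, and
#' class-conditional DTI feature distributions (linked by a Gaussian copula
#' so ADC and FA are negatively rank-correlated, as observed in vivo).
#'
#' Coefficient scale convention: `age` and `log_size` act per 1-SD of their
#' generating marginal; `bpe` acts per category (1-4); binary features
#' (`post_menopausal`, `known_cancer`, `dense_breasts`, `mass`, `washout`,
#' `birads5`) act per level. The intercept is calibrated numerically to the
#' target marginal prevalence unless supplied.
#'
#' @param n_patients Number of patients (>= 1).
#' @param lesions_per_patient_probs Probabilities of 1/2/3 lesions per
#'   patient (must sum to 1).
#' @param covariates List of marginal parameters; see defaults for the
#'   expected names (age mean/sd, Bernoulli probabilities, BPE category
#'   probabilities, log-normal lesion-size meanlog/sdlog, kinetic-class
#'   probabilities).
#' @param outcome_coefficients Named log-odds vector over a subset of
#'   `age, post_menopausal, known_cancer, dense_breasts, bpe, log_size,
#'   mass, washout, birads5`. Unknown names are a configuration error.
#' @param intercept Logistic intercept; `NULL` calibrates it to
#'   `target_prevalence` via [calibrate_intercept()].
#' @param target_prevalence Marginal lesion-level malignancy fraction used
#'   when `intercept` is `NULL`.
#' @param cluster_effect_sd SD of the patient-level random intercept on the
#'   logit scale.
#' @param dti Class-conditional DTI distribution parameters: `adc_malignant`
#'   and `adc_benign` as (mean, sd) in 1e-3 mm^2/s; `fa_*` as (mean, sd) per
#'   lesion type x class (log-normal, moment-matched); `copula_rho` is the
#'   latent normal correlation between ADC and FA.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 194L,
                          lesions_per_patient_probs = c(0.809, 0.155, 0.036),
                          covariates = list(),
                          outcome_coefficients = NULL,
                          intercept = NULL,
                          target_prevalence = 0.399,
                          cluster_effect_sd = 0.5,
                          dti = list(),
                          seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stopf("n_patients must be >= 1")
  p <- lesions_per_patient_probs
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stopf("lesions_per_patient_probs must be 3 non-negative values summing to 1")
  }
  cov_defaults <- list(
    age_mean = 51, age_sd = 11.8,
    post_menopausal = 0.521,
    known_cancer = 0.649,
    dense_breasts = 0.732,
    bpe_probs = c(0.299, 0.407, 0.191, 0.103),
    size_meanlog = log(1.1), size_sdlog = 0.85,
    mass = 0.567,
    kinetics_probs = c(persistent = 0.025, plateau = 0.143, washout = 0.832),
    birads5 = 0.084
  )
  unknown_cov <- setdiff(names(covariates), names(cov_defaults))
  if (length(unknown_cov)) {
    stopf("unknown covariate parameter(s): %s", paste(unknown_cov, collapse = ", "))
  }
  covariates <- utils::modifyList(cov_defaults, covariates)
  if (abs(sum(covariates$bpe_probs) - 1) > 1e-6 ||
      abs(sum(covariates$kinetics_probs) - 1) > 1e-6) {
    stopf("category probability vectors must sum to 1")
  }
  if (is.null(outcome_coefficients)) {
    outcome_coefficients <- c(
      age = log(1.17), post_menopausal = 0, known_cancer = log(1.88),
      dense_breasts = log(0.61), bpe = log(0.66), log_size = log(1.85),
      mass = log(1.89), washout = log(2.43), birads5 = log(2.36)
    )
  }
  unknown <- setdiff(names(outcome_coefficients), COEF_FEATURES)
  if (length(unknown)) {
    stopf("outcome_coefficients reference unknown feature(s): %s",
          paste(unknown, collapse = ", "))
  }
  if (cluster_effect_sd < 0) stopf("cluster_effect_sd must be >= 0")
  dti_defaults <- list(
    adc_malignant = c(1.26, 0.32), adc_benign = c(1.55, 0.30),
    fa_mass_malignant = c(0.31, 0.17), fa_mass_benign = c(0.21, 0.12),
    fa_nonmass_malignant = c(0.24, 0.11), fa_nonmass_benign = c(0.26, 0.14),
    copula_rho = 2 * sin(-0.5 * pi / 6)
  )
  unknown_dti <- setdiff(names(dti), names(dti_defaults))
  if (length(unknown_dti)) {
    stopf("unknown dti parameter(s): %s", paste(unknown_dti, collapse = ", "))
  }
  dti <- utils::modifyList(dti_defaults, dti)
  if (abs(dti$copula_rho) > 1) stopf("copula_rho must lie in [-1, 1]")

  structure(list(
    n_patients = n_patients,
    lesions_per_patient_probs = p,
    covariates = covariates,
    outcome_coefficients = outcome_coefficients,
    intercept = intercept,
    target_prevalence = target_prevalence,
    cluster_effect_sd = cluster_effect_sd,
    dti = dti,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw lesion-level covariates, the covariate part of the linear predictor,
# and per-lesion patient random effects. Used by both the simulator and the
# intercept calibration.
draw_cohort_frame <- function(config, n_patients) {
  cv <- config$covariates
  n_les_per_pat <- sample.int(3L, n_patients, replace = TRUE,
                              prob = config$lesions_per_patient_probs)
  patient <- rep(seq_len(n_patients), n_les_per_pat)
  n <- length(patient)

  age_p <- stats::rnorm(n_patients, cv$age_mean, cv$age_sd)
  meno_p <- stats::rbinom(n_patients, 1L, cv$post_menopausal)
  indic_p <- stats::rbinom(n_patients, 1L, cv$known_cancer)
  dense_p <- stats::rbinom(n_patients, 1L, cv$dense_breasts)
  bpe_p <- sample.int(4L, n_patients, replace = TRUE, prob = cv$bpe_probs)
  u_p <- stats::rnorm(n_patients, 0, config$cluster_effect_sd)

  size <- stats::rlnorm(n, cv$size_meanlog, cv$size_sdlog)
  mass <- stats::rbinom(n, 1L, cv$mass)
  kin <- sample(KINETIC_LEVELS, n, replace = TRUE, prob = cv$kinetics_probs)
  kin <- factor(kin, levels = KINETIC_LEVELS, ordered = TRUE)
  washout <- as.integer(kin == "washout")
  birads5 <- stats::rbinom(n, 1L, cv$birads5)

  df <- data.frame(
    patient_id = patient,
    lesion_id = seq_len(n),
    age = age_p[patient],
    post_menopausal = meno_p[patient],
    known_cancer = indic_p[patient],
    dense_breasts = dense_p[patient],
    bpe = bpe_p[patient],
    size_cm = size,
    mass = mass,
    kinetics = kin,
    washout = washout,
    birads5 = birads5
  )

  # analysis-scale design for the generating coefficients
  z <- cbind(
    age = (df$age - cv$age_mean) / cv$age_sd,
    post_menopausal = df$post_menopausal,
    known_cancer = df$known_cancer,
    dense_breasts = df$dense_breasts,
    bpe = df$bpe,
    log_size = (log(df$size_cm) - cv$size_meanlog) / cv$size_sdlog,
    mass = df$mass,
    washout = df$washout,
    birads5 = df$birads5
  )
  beta <- config$outcome_coefficients
  lp_cov <- as.vector(z[, names(beta), drop = FALSE] %*% beta)
  list(df = df, lp_cov = lp_cov, u = u_p[patient])
}

#' Calibrate the logistic intercept of a cohort configuration
#'
#' Numerically solves for the intercept b0 such that the marginal
#' lesion-level malignancy probability E[plogis(b0 + x'beta + u)] equals the
#' configured target prevalence. The expectation over covariates and the
#' random intercept is approximated by a large fixed-seed Monte-Carlo draw,
#' so the result is deterministic for a given configuration.
#'
#' @param config A [cohort_config()].
#' @param n_mc Monte-Carlo population size.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(config, n_mc = 20000L) {
  stopifnot(inherits(config, "cohort_config"))
  # the calibration depends on everything except n_patients and seed; cache it
  key <- paste(utils::capture.output(utils::str(config[
    c("lesions_per_patient_probs", "covariates", "outcome_coefficients",
      "target_prevalence", "cluster_effect_sd")], digits.d = 17)),
    n_mc, collapse = "|")
  hit <- get0(key, envir = .calibration_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  draw <- with_seed(9041L, draw_cohort_frame(config, n_mc))
  lp <- draw$lp_cov + draw$u
  f <- function(b0) mean(stats::plogis(b0 + lp)) - config$target_prevalence
  root <- stats::uniroot(f, c(-25, 25), tol = 1e-9)$root
  assign(key, root, envir = .calibration_cache)
  root
}

.calibration_cache <- new.env(parent = emptyenv())

# Moment-matched log-normal parameters for a positive feature
lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a clustered lesion cohort with known effect structure
#'
#' Generates a lesion-level cohort table: patients carry 1-3 lesions;
#' malignancy is drawn from a logistic model on clinical/DCE features plus a
#' patient-level Gaussian random intercept; ADC is drawn from
#' class-conditional normals (defaults: malignant 1.26 +/- 0.32, benign
#' 1.55 +/- 0.30, in 1e-3 mm^2/s) and FA from type- and class-conditional
#' log-normals, coupled to ADC through a Gaussian copula. Axial and radial
#' diffusivity and lambda1 - lambda3 are derived from (ADC, FA) through a
#' prolate tensor, which induces the strong collinearity seen among DTI
#' parameters in practice.
#'
#' @param config A [cohort_config()].
#' @return A list with `cohort` (lesion-level data frame; see Details for
#'   the column dictionary) and `truth` (generating intercept, coefficients,
#'   per-lesion linear predictor, random intercepts and the config).
#' @details Column dictionary: `patient_id`, `lesion_id`; clinical `age`
#'   (years), `post_menopausal`, `known_cancer` (MRI indication),
#'   `dense_breasts`, `bpe` (1-4); DCE `size_cm`, `mass`, `kinetics`
#'   (worst-curve class), `washout`, `birads5`; DTI `adc`, `axial`, `radial`,
#'   `lambda_diff` (1e-3 mm^2/s), `fa` (unitless); outcome `malignant` (0/1).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  b0 <- config$intercept %||% calibrate_intercept(config)
  with_seed(config$seed, {
    draw <- draw_cohort_frame(config, config$n_patients)
    df <- draw$df
    n <- nrow(df)
    lp <- b0 + draw$lp_cov + draw$u
    df$malignant <- stats::rbinom(n, 1L, stats::plogis(lp))

    # ADC | class and FA | (type, class), coupled by a Gaussian copula
    rho <- config$dti$copula_rho
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    adc_par <- rbind(benign = config$dti$adc_benign,
                     malignant = config$dti$adc_malignant)
    ap <- adc_par[df$malignant + 1L, , drop = FALSE]
    df$adc <- pmax(ap[, 1] + ap[, 2] * z1, 0.05)

    fa_key <- paste0("fa_", ifelse(df$mass == 1L, "mass", "nonmass"), "_",
                     ifelse(df$malignant == 1L, "malignant", "benign"))
    fa_par <- t(vapply(config$dti[unique(fa_key)], function(ms) {
      lnorm_params(ms[1], ms[2])
    }, numeric(2)))
    fp <- fa_par[match(fa_key, rownames(fa_par)), , drop = FALSE]
    df$fa <- pmin(stats::qlnorm(stats::pnorm(z2), fp[, 1], fp[, 2]), 0.99)

    ev <- eigenvalues_from_adc_fa(df$adc, df$fa)
    df$axial <- ev[, 1]
    df$radial <- (ev[, 2] + ev[, 3]) / 2
    df$lambda_diff <- ev[, 1] - ev[, 3]

    list(
      cohort = df,
      truth = list(intercept = b0,
                   coefficients = config$outcome_coefficients,
                   linear_predictor = lp,
                   random_intercepts = draw$u,
                   config = config)
    )
  })
}

#' Reconstruct DTI features for one lesion through the full imaging pipeline
#'
#' Integration-test path for the cohort generator: given a lesion's target
#' ADC and FA, builds the matching prolate tensor, simulates a homogeneous
#' DWI phantom, fits the tensor field, refines a central-slice ROI on the
#' combined b = 800 image and summarizes the scalar maps over it.
#'
#' @param adc,fa Target mean diffusivity (1e-3 mm^2/s) and FA.
#' @param scheme Gradient scheme; defaults to the 6-direction protocol.
#' @param grid_shape Phantom grid.
#' @param noise_sigma,s0,seed Passed to [phantom_config()].
#' @param threshold_fraction Passed to [refine_roi()].
#' @return The one-row feature data frame from [lesion_summary()], with ADC
#'   and diffusivities in 1e-3 mm^2/s (matching the cohort table units).
#' @export
simulate_lesion_phantom_features <- function(adc, fa,
                                             scheme = make_gradient_scheme(),
                                             grid_shape = c(6L, 6L, 3L),
                                             noise_sigma = 0, s0 = 1000,
                                             seed = 1L,
                                             threshold_fraction = 0.5) {
  ev <- eigenvalues_from_adc_fa(adc, fa) * 1e-3
  cfg <- phantom_config(grid_shape = grid_shape,
                        regions = list(tensor_region(ev, direction = c(1, 1, 1))),
                        s0 = s0, noise_sigma = noise_sigma, seed = seed)
  sim <- simulate_dwi_phantom(cfg, scheme)
  tm <- fit_tensor(sim$dwi)
  maps <- scalar_maps(tm)
  comb <- combined_dwi(sim$dwi, b_target = 800)
  mid <- ceiling(grid_shape[3] / 2)
  seed_region <- as.matrix(expand.grid(seq_len(grid_shape[1]),
                                       seq_len(grid_shape[2]), mid))
  roi <- refine_roi(comb, seed_region, threshold_fraction)
  out <- lesion_summary(maps, roi)
  for (col in c("mean_adc", "mean_axial", "mean_radial", "mean_lambda_diff")) {
    out[[col]] <- out[[col]] * 1e3
  }
  out
}
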