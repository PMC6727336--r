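make_fm <- function(n_patients = 200L, seed = 1L, dti = list()) {
  prepare_features(simulate_cohort(
    cohort_config(n_patients = n_patients, dti = dti, seed = seed))$cohort)
}

test_that("feature preparation applies log transforms and records SDs", {
  df <- data.frame(patient_id = 1:6, lesion_id = 1:6,
                   size_cm = c(1, exp(1), exp(2), 1, exp(1), exp(2)),
                   adc = c(1.2, 1.5, 1.3, 1.6, 1.1, 1.4),
                   mass = c(0, 1, 0, 1, 0, 1),
                   malignant = c(1, 0, 1, 0, 1, 0))
  fm <- prepare_features(df, log_features = "size_cm")
  expect_equal(fm$data$size_cm, rep(c(0, 1, 2), 2))
  expect_equal(fm$transforms, "size_cm")
  # binary features pass through untransformed and unscaled
  expect_equal(fm$data$mass, df$mass)
  expect_false("mass" %in% names(fm$sds))
  # SDs recorded on the analysis (log) scale
  expect_equal(fm$sds[["size_cm"]], sd(rep(c(0, 1, 2), 2)))
  # size_large derived before the log transform
  expect_equal(fm$data$size_large, rep(c(1, 1, 1), 2))
  # non-positive values in a log feature are a named error
  df$size_cm[3] <- 0
  expect_error(prepare_features(df, log_features = "size_cm"), "lesion")
})

test_that("per-1-SD OR equals exp(per-unit coefficient times SD)", {
  set.seed(4)
  n <- 400
  x <- rnorm(n, sd = 2)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x))
  r_sd <- univariate_cluster_logistic(x, y, seq_len(n), scale_per_sd = TRUE)
  r_unit <- univariate_cluster_logistic(x, y, seq_len(n), scale_per_sd = FALSE)
  expect_equal(r_sd$or, exp(r_unit$coef * sd(x)), tolerance = 1e-10)
  expect_equal(r_sd$sd_used, sd(x))
})

test_that("binary predictors reproduce the 2x2 cross-product odds ratio", {
  d <- binary_feature_cohort(87, 95, 111, 143)   # washout row counts
  r <- univariate_cluster_logistic(d$x, d$y, d$patient)
  expect_equal(r$or, (87 * 32) / (111 * 8), tolerance = 1e-8)
  set.seed(12)
  x <- rbinom(300, 1, 0.3); y <- rbinom(300, 1, plogis(-0.5 + x))
  r2 <- univariate_cluster_logistic(x, y, seq_along(x))
  tab <- table(x, y)
  expect_equal(r2$or, (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2]),
               tolerance = 1e-8)
})

test_that("perfect separation raises the infinite-OR marker", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  r <- suppressWarnings(univariate_cluster_logistic(x, y, seq_along(x)))
  expect_true(r$separation)
  expect_true(is.infinite(r$or))
})

test_that("Spearman matrix honors monotone invariance and flags constants", {
  set.seed(7)
  x <- rnorm(50)
  m <- spearman_matrix(data.frame(x = x, ex = exp(x), neg = -x))
  expect_equal(m["x", "ex"], 1)
  expect_equal(m["x", "neg"], -1)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(x = 1, ex = 1, neg = 1))
  expect_warning(m2 <- spearman_matrix(data.frame(x = x, k = rep(2, 50))),
                 "constant")
  expect_true(is.na(m2["x", "k"]))
})

test_that("a huge penalty zeroes everything; zero penalty matches the MLE", {
  fm <- make_fm(150L, seed = 2L)
  cand <- c("adc", "fa", "age", "washout")
  big <- lasso_logistic_lopo(fm, cand, penalty_grid = c(5, 10))
  expect_true(all(!big$selected))
  expect_true(all(big$coefficients[cand] == 0))

  zero <- lasso_logistic_lopo(fm, cand, penalty_grid = c(0, 0.5))
  if (zero$lambda == 0) {
    x <- as.matrix(fm$data[, cand])
    mle <- glm.fit(cbind(1, x), fm$outcome, family = binomial())$coefficients
    expect_equal(unname(zero$coefficients), unname(mle), tolerance = 1e-6)
    expect_equal(zero$engine, "glm")
  }
  # force the reduction regardless of which grid point CV picks
  zero2 <- lasso_logistic_lopo(fm, cand, penalty_grid = 0)
  x <- as.matrix(fm$data[, cand])
  mle <- glm.fit(cbind(1, x), fm$outcome, family = binomial())$coefficients
  expect_equal(unname(zero2$coefficients), unname(mle), tolerance = 1e-6)
})

test_that("reported LASSO ORs obey the per-1-SD scaling identity", {
  fm <- make_fm(150L, seed = 3L)
  fit <- lasso_logistic_lopo(fm, c("adc", "fa", "washout"))
  expect_equal(fit$or[["adc"]],
               exp(fit$coefficients[["adc"]] * fm$sds[["adc"]]),
               tolerance = 1e-12)
  # binary candidate: raw OR
  expect_equal(fit$or[["washout"]], exp(fit$coefficients[["washout"]]),
               tolerance = 1e-12)
  expect_equal(fit$n_parameters, 4L)
})

test_that("selected sets shrink monotonically along the penalty path", {
  fm <- make_fm(250L, seed = 6L)
  cand <- c("adc", "fa", "age", "size_cm", "washout", "bpe")
  fit <- lasso_logistic_lopo(fm, cand)
  x <- as.matrix(fm$data[, cand])
  path <- glmnet::glmnet(x, fm$outcome, family = "binomial",
                         lambda = fit$lambda_grid[fit$lambda_grid > 0])
  nz <- predict(path, type = "nonzero")
  sets <- lapply(seq_along(path$lambda), function(j) sort(nz[[j]]))
  for (j in seq_len(length(sets) - 1L)) {
    larger <- sets[[j]]        # larger penalty
    smaller <- sets[[j + 1L]]  # smaller penalty
    # the larger-penalty set must never strictly contain the smaller-penalty set
    expect_false(length(larger) > length(smaller) && all(smaller %in% larger))
  }
})

test_that("the 1-SE convention never picks a smaller penalty than the minimum", {
  fm <- make_fm(120L, seed = 9L)
  f_min <- lasso_logistic_lopo(fm, c("adc", "fa"), selection = "min")
  f_1se <- lasso_logistic_lopo(fm, c("adc", "fa"), selection = "1se")
  expect_gte(f_1se$lambda, f_min$lambda)
  expect_lte(sum(f_1se$selected), sum(f_min$selected))
})

test_that("interaction columns extend the design from 12 to 16 parameters", {
  fm <- make_fm(150L, seed = 4L)
  base <- c("age", "post_menopausal", "known_cancer", "dense_breasts", "bpe",
            "size_cm", "mass", "washout", "birads5", "adc", "fa")
  fit_base <- lasso_logistic_lopo(fm, base, penalty_grid = c(0.1))
  expect_equal(fit_base$n_parameters, 12L)
  fmi <- build_interactions(fm)
  cand <- c(base, "size_large_x_adc", "mass_x_adc", "size_large_x_fa",
            "mass_x_fa")
  fit_int <- lasso_logistic_lopo(fmi, cand, penalty_grid = c(0.1))
  expect_equal(fit_int$n_parameters, 16L)
  expect_error(build_interactions(fm, list(c("mass", "vegf"))), "unknown")
})

test_that("a constant moderator flags the degenerate interaction", {
  co <- simulate_cohort(cohort_config(n_patients = 60L, seed = 10L))$cohort
  co$mass <- 1L
  fm <- prepare_features(co)
  expect_warning(fmi <- build_interactions(fm, list(c("mass", "adc"))),
                 "degenerate|collinear")
  expect_equal(fmi$data$mass_x_adc, fmi$data$adc)
})

test_that("subgroup ORs reconstruct exp((main + interaction) * SD)", {
  fm <- make_fm(150L, seed = 5L)
  fmi <- build_interactions(fm)
  fake <- list(coefficients = c("(Intercept)" = 0, adc = -1.2,
                                mass_x_adc = 0.4, size_large_x_adc = -0.1))
  sd_adc <- fmi$sds[["adc"]]
  expect_equal(subgroup_or(fake, fmi, "adc", c(mass = 1, size_large = 0)),
               exp((-1.2 + 0.4) * sd_adc))
  expect_equal(subgroup_or(fake, fmi, "adc", c(mass = 0, size_large = 1)),
               exp((-1.2 - 0.1) * sd_adc))
})

test_that("identical subgroups by construction give a near-zero interaction", {
  # large cohort where the ADC effect is identical for masses and non-masses
  cc <- cohort_config(n_patients = 3000L,
                      dti = list(adc_malignant = c(1.26, 0.31),
                                 adc_benign = c(1.55, 0.31)),
                      seed = 14L)
  co <- simulate_cohort(cc)$cohort
  fit <- gee_logistic(malignant ~ adc * mass, co, "patient_id")
  w <- wald_compare_or(fit, "adc:mass")
  expect_lt(abs(w$estimate), 0.5)
  expect_gt(w$p, 0.01)
  expect_error(wald_compare_or(fit, "adc:size_large"), "missing interaction")
})

test_that("strong opposite FA effects by lesion type are detected", {
  # power fixture: FA clearly higher in malignant masses, lower in malignant
  # non-masses
  dti <- list(fa_mass_malignant = c(0.34, 0.13), fa_mass_benign = c(0.20, 0.10),
              fa_nonmass_malignant = c(0.18, 0.08),
              fa_nonmass_benign = c(0.30, 0.12), copula_rho = 0)
  hits <- vapply(1:12, function(s) {
    co <- simulate_cohort(cohort_config(n_patients = 600L, dti = dti,
                                        seed = s))$cohort
    co$log_fa <- log(co$fa)
    fit <- gee_logistic(malignant ~ log_fa * mass, co, "patient_id")
    wald_compare_or(fit, "log_fa:mass")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("predictions from a LASSO fit are plain logistic scores", {
  fm <- make_fm(100L, seed = 7L)
  fit <- lasso_logistic_lopo(fm, c("adc", "fa"))
  p <- predict(fit, fm)
  eta <- fit$coefficients[["(Intercept)"]] +
    as.matrix(fm$data[, c("adc", "fa")]) %*% fit$coefficients[c("adc", "fa")]
  expect_equal(p, drop(plogis(eta)))
  expect_true(all(p > 0 & p < 1))
})

test_that("generating coefficients are recovered with correct signs at large n", {
  nonzero <- c("age", "known_cancer", "dense_breasts", "bpe", "size_cm",
               "mass", "washout", "birads5")
  truth_sign <- c(1, 1, -1, -1, 1, 1, 1, 1)
  ok <- vapply(1:5, function(s) {
    fm <- make_fm(2000L, seed = 100L + s)
    fit <- lasso_logistic_lopo(fm, c(nonzero, "post_menopausal"))
    all(fit$selected[nonzero]) &&
      all(sign(fit$coefficients[nonzero]) == truth_sign)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
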