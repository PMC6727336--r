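test_that("AUC handles separation, reversal, ties and degenerate input", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5), y), 1)
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), y), 0)
  expect_equal(roc_auc(rep(1, 5), y), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "one outcome class")
  # binary predictor: AUC = (sensitivity + specificity) / 2
  d <- binary_feature_cohort(87, 95, 111, 143)
  expect_equal(roc_auc(d$x, d$y), (87 / 95 + 32 / 143) / 2, tolerance = 1e-12)
})

test_that("rank-based AUC agrees with pROC on tied and untied scores", {
  set.seed(15)
  for (i in 1:5) {
    y <- rbinom(80, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), 80, replace = TRUE)  # heavy ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("scores independent of the outcome give AUC near one half", {
  set.seed(19)
  y <- rbinom(10000, 1, 0.4)
  s <- rnorm(10000)
  expect_equal(roc_auc(s, y), 0.5, tolerance = 0.02 / 0.5)
})

test_that("ROC coordinates span (0,0) to (1,1) monotonically", {
  set.seed(25)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60)
  rc <- roc_coordinates(s, y)
  expect_equal(rc$sensitivity[1], 0)
  expect_equal(rc$one_minus_specificity[1], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 1)
  expect_equal(rc$one_minus_specificity[nrow(rc)], 1)
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$one_minus_specificity) >= 0))
})

test_that("a constant score cannot overfit: apparent equals adjusted at 0.5", {
  fm <- noise_feature_matrix(1L, n_patients = 60L)
  a <- bootstrap_optimism_auc(glm_spec(character(0)), fm, B = 50, seed = 2)
  expect_equal(a$apparent, 0.5)
  expect_equal(a$adjusted, 0.5)
  expect_equal(a$optimism, 0)
})

test_that("bootstrap estimates are reproducible given (data, B, seed)", {
  fm <- noise_feature_matrix(2L, n_patients = 50L, p = 3L)
  spec <- glm_spec(c("x1", "x2"))
  a <- bootstrap_optimism_auc(spec, fm, B = 60, seed = 7)
  b <- bootstrap_optimism_auc(spec, fm, B = 60, seed = 7)
  d <- bootstrap_optimism_auc(spec, fm, B = 60, seed = 8)
  expect_identical(a$adjusted, b$adjusted)
  expect_identical(a$ci, b$ci)
  expect_false(identical(a$adjusted, d$adjusted))
})

test_that("patient-level resampling widens CIs under within-patient duplication", {
  set.seed(33)
  n <- 120
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  base <- data.frame(x1 = c(x, x), patient_id = c(1:n, 1:n),
                     lesion_id = 1:(2 * n), malignant = c(y, y))
  clustered <- prepare_features(base, log_features = character(0))
  independent <- base
  independent$patient_id <- 1:(2 * n)
  independent <- prepare_features(independent, log_features = character(0))
  spec <- glm_spec("x1")
  ci_c <- bootstrap_optimism_auc(spec, clustered, B = 150, seed = 4)$ci
  ci_i <- bootstrap_optimism_auc(spec, independent, B = 150, seed = 4)$ci
  expect_gt(diff(ci_c), diff(ci_i))
})

test_that("comparing a model with itself gives zero difference everywhere", {
  fm <- noise_feature_matrix(3L, n_patients = 50L, p = 3L)
  spec <- glm_spec(c("x1", "x2"))
  d <- bootstrap_auc_diff(spec, spec, fm, B = 40, seed = 9)
  expect_equal(d$delta, 0)
  expect_true(all(d$boot_deltas == 0))
  expect_equal(d$p, 1)
})

test_that("adding a pure-noise feature to a nested model changes little", {
  set.seed(44)
  n_pat <- 120
  pid <- seq_len(n_pat)
  x <- rnorm(n_pat)
  y <- rbinom(n_pat, 1, plogis(1.2 * x))
  df <- data.frame(x1 = x, noise = rnorm(n_pat), patient_id = pid,
                   lesion_id = pid, malignant = y)
  fm <- prepare_features(df, log_features = character(0))
  d <- bootstrap_auc_diff(glm_spec(c("x1", "noise")), glm_spec("x1"), fm,
                          B = 150, seed = 10)
  expect_true(d$ci[1] <= 0 && d$ci[2] >= 0 + 1e-12 || abs(d$delta) < 0.05)
  expect_gt(d$p, 0.05)
})
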