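# Feature preparation and regression modeling: cluster-robust univariate
# logistic fits, Spearman correlation, and LASSO with leave-one-patient-out
# penalty selection.

#' Prepare a lesion feature matrix for modeling
#'
#' Applies natural-log transforms to right-skewed features (defaults: lesion
#' size, FA and lambda1 - lambda3), derives the `size_large` indicator
#' (>= 1 cm) used by interaction models, and records the per-feature SD on
#' the analysis scale so odds ratios can be reported per 1-SD increase.
#' Binary features pass through untransformed and unscaled; `bpe` is kept on
#' its ordinal 1-4 scale (per-category odds ratios).
#'
#' @param cohort Lesion-level data frame (see [simulate_cohort()] for the
#'   column dictionary).
#' @param log_features Features to log-transform; must be strictly positive.
#' @param outcome,cluster Names of the outcome (0/1) and patient-id columns.
#' @param unscaled Continuous features reported per unit rather than per SD.
#' @return An object of class `feature_matrix`: `data` (numeric, analysis
#'   scale), `outcome`, `cluster`, `sds` (per-SD-scaled features),
#'   `scaled`/`binary` flags, `transforms` and an (initially empty)
#'   interaction registry.
#' @export
prepare_features <- function(cohort,
                             log_features = c("size_cm", "fa", "lambda_diff"),
                             outcome = "malignant",
                             cluster = "patient_id",
                             unscaled = "bpe") {
  if (!outcome %in% names(cohort)) stopf("outcome column '%s' not found", outcome)
  if (!cluster %in% names(cohort)) stopf("cluster column '%s' not found", cluster)
  y <- cohort[[outcome]]
  if (!is_binary01(y)) stopf("outcome must be binary 0/1")
  cl <- cohort[[cluster]]

  drop_cols <- c(outcome, cluster, "lesion_id")
  dat <- cohort[, setdiff(names(cohort), drop_cols), drop = FALSE]
  dat <- dat[, vapply(dat, is.numeric, logical(1)), drop = FALSE]

  if ("size_cm" %in% names(dat) && !"size_large" %in% names(dat)) {
    dat$size_large <- as.numeric(dat$size_cm >= 1.0)
  }

  log_features <- intersect(log_features, names(dat))
  for (f in log_features) {
    bad <- which(dat[[f]] <= 0)
    if (length(bad)) {
      stopf("cannot log-transform '%s': non-positive value for lesion(s) %s",
            f, paste(utils::head(cohort$lesion_id[bad] %||% bad, 5), collapse = ", "))
    }
    dat[[f]] <- log(dat[[f]])
  }
  if (anyNA(dat)) stopf("feature matrix contains missing values after preparation")

  binary <- vapply(dat, is_binary01, logical(1))
  scaled <- !binary & !(names(dat) %in% unscaled)
  sds <- vapply(dat[scaled], stats::sd, numeric(1))
  if (any(sds <= 0)) {
    stopf("constant continuous feature(s): %s",
          paste(names(sds)[sds <= 0], collapse = ", "))
  }
  structure(list(
    data = dat,
    outcome = as.integer(y),
    cluster = cl,
    sds = sds,
    scaled = scaled,
    binary = binary,
    transforms = log_features,
    interactions = list()
  ), class = "feature_matrix")
}

#' @method print feature_matrix
#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d lesions, %d patients, %d features (%d log-transformed)\n",
              nrow(x$data), length(unique(x$cluster)), ncol(x$data),
              length(x$transforms)))
  invisible(x)
}

# SD used when converting a coefficient to a per-1-SD odds ratio; interaction
# columns inherit the SD of their continuous parent.
sd_for_feature <- function(fm, name) {
  if (name %in% names(fm$sds)) return(fm$sds[[name]])
  if (name %in% names(fm$interactions)) {
    parent <- fm$interactions[[name]]$feature
    if (parent %in% names(fm$sds)) return(fm$sds[[parent]])
  }
  1
}

#' Cluster-robust univariate logistic regression
#'
#' Logistic regression of malignancy on a single feature with an
#' independence working correlation and cluster-robust (sandwich) variance
#' by patient — the GEE-type analysis appropriate when several lesions come
#' from the same woman. For a single binary predictor the point estimate
#' equals the 2x2 cross-product odds ratio. Continuous features are scaled
#' so the OR corresponds to a 1-SD increase; `scale_per_sd = FALSE` reports
#' per-unit ORs.
#'
#' @param feature Numeric feature vector (analysis scale).
#' @param outcome Binary 0/1 outcome vector.
#' @param cluster Patient identifiers.
#' @param scale_per_sd `NULL` scales continuous features per SD and leaves
#'   binary ones raw; otherwise a logical.
#' @param conf_level Confidence level for the Wald interval.
#' @param auc_ci_B Patient-bootstrap replicates for the AUC CI (0 = none).
#' @param seed Seed for the AUC bootstrap.
#' @return An object of class `univariate_result`: `or`, `ci`, `p`, `coef`,
#'   `se` (robust), `auc`, `auc_ci`, `sd_used`, and a `separation` flag
#'   (infinite-OR marker when the outcome is perfectly separated).
#' @export
univariate_cluster_logistic <- function(feature, outcome, cluster,
                                        scale_per_sd = NULL,
                                        conf_level = 0.95,
                                        auc_ci_B = 0L, seed = NULL) {
  if (length(unique(outcome)) < 2L) stopf("both outcome classes must be present")
  if (is.null(scale_per_sd)) scale_per_sd <- !is_binary01(feature)
  sd_used <- if (scale_per_sd) stats::sd(feature) else 1
  if (sd_used <= 0) stopf("undefined: constant feature")
  x <- feature / sd_used

  dat <- data.frame(y = outcome, x = x)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = dat))
  beta <- stats::coef(fit)[["x"]]
  separation <- abs(beta) > 15 ||
    any(fit$fitted.values > 1 - 1e-9) && any(fit$fitted.values < 1e-9)
  V <- sandwich::vcovCL(fit, cluster = factor(cluster))
  se <- sqrt(V["x", "x"])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  # AUC of the model score (direction-aware, as diagnostic AUCs are reported)
  score <- if (beta < 0) -feature else feature
  auc_pt <- mw_auc(score, outcome)
  auc_ci <- if (auc_ci_B > 0L) {
    cluster_bootstrap_auc_ci(score, outcome, cluster, auc_ci_B, seed, conf_level)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(
    or = if (separation) Inf * sign(beta) else exp(beta),
    ci = if (separation) c(NA_real_, NA_real_) else exp(beta + c(-1, 1) * zq * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    coef = beta, se = se,
    auc = auc_pt, auc_ci = auc_ci,
    sd_used = sd_used, scaled = scale_per_sd,
    separation = separation, n = length(outcome)
  ), class = "univariate_result")
}

#' @method print univariate_result
#' @export
print.univariate_result <- function(x, ...) {
  cat(sprintf("OR %.3g (%.3g-%.3g), p = %.3g; AUC %.3f%s\n",
              x$or, x$ci[1], x$ci[2], x$p, x$auc,
              if (x$separation) " [separation: infinite OR]" else ""))
  invisible(x)
}

cluster_bootstrap_auc_ci <- function(feature, outcome, cluster, B, seed,
                                     conf_level) {
  with_seed(seed, {
    ids <- unique(cluster)
    idx_by_id <- split(seq_along(cluster), match(cluster, ids))
    reps <- vapply(seq_len(B), function(b) {
      rows <- unlist(idx_by_id[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      if (length(unique(outcome[rows])) < 2L) return(NA_real_)
      mw_auc(feature[rows], outcome[rows])
    }, numeric(1))
    alpha <- 1 - conf_level
    unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  })
}

#' Univariate association table for every feature
#'
#' Runs [univariate_cluster_logistic()] per feature of a prepared matrix and
#' assembles an association table (AUC, OR per 1-SD or per level, robust CI,
#' p-value) of the shape used to report univariate analyses.
#'
#' @param fm A [prepare_features()] object.
#' @param features Features to include; default all except `size_large`.
#' @param conf_level,auc_ci_B,seed Passed through.
#' @return A data frame with one row per feature.
#' @export
univariate_table <- function(fm, features = NULL, conf_level = 0.95,
                             auc_ci_B = 0L, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  features <- features %||% setdiff(names(fm$data), "size_large")
  rows <- lapply(features, function(f) {
    r <- univariate_cluster_logistic(fm$data[[f]], fm$outcome, fm$cluster,
                                     scale_per_sd = if (fm$binary[[f]] ||
                                                        !fm$scaled[[f]]) FALSE else TRUE,
                                     conf_level = conf_level,
                                     auc_ci_B = auc_ci_B, seed = seed)
    data.frame(feature = f, auc = r$auc, auc_lo = r$auc_ci[1],
               auc_hi = r$auc_ci[2], or = r$or, or_lo = r$ci[1],
               or_hi = r$ci[2], p = r$p, separation = r$separation)
  })
  do.call(rbind, rows)
}

#' Pairwise Spearman rank correlations
#'
#' Symmetric matrix of Spearman correlations between continuous features;
#' constant features yield `NA` entries (undefined correlation) with a
#' warning.
#'
#' @param features Numeric data frame or matrix (>= 3 rows).
#' @return Correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3L) stopf("at least 3 lesions are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("constant feature(s) have undefined correlation: %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}

#' Logistic regression with cluster-robust inference
#'
#' Fits an ordinary logistic model (independence working correlation) and
#' attaches a cluster-robust sandwich covariance by patient, the combination
#' used for all unpenalized inference in this package.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param cluster Cluster (patient) identifiers, or the name of a column of
#'   `data`.
#' @return An object of class `gee_fit` wrapping the `glm` fit and its
#'   robust covariance.
#' @export
gee_logistic <- function(formula, data, cluster) {
  if (is.character(cluster) && length(cluster) == 1L) cluster <- data[[cluster]]
  fit <- suppressWarnings(stats::glm(formula, family = stats::binomial(), data = data))
  V <- sandwich::vcovCL(fit, cluster = factor(cluster))
  structure(list(fit = fit, vcov = V), class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' Coefficient table with robust standard errors
#'
#' @param object A [gee_logistic()] fit.
#' @return Data frame of estimates, robust SEs, z and two-sided p-values.
#' @export
robust_coefs <- function(object) {
  stopifnot(inherits(object, "gee_fit"))
  b <- stats::coef(object$fit)
  se <- sqrt(diag(object$vcov))
  z <- b / se
  data.frame(term = names(b), estimate = unname(b), robust_se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
}

#' @method print gee_fit
#' @export
print.gee_fit <- function(x, ...) {
  cat("Cluster-robust logistic fit\n")
  print(robust_coefs(x), digits = 4)
  invisible(x)
}

#' Wald comparison of subgroup odds ratios
#'
#' Tests whether a feature's association with malignancy differs between two
#' subgroups (e.g. masses vs non-masses) via a z-test on the corresponding
#' interaction coefficient with its cluster-robust standard error.
#'
#' @param fit A [gee_logistic()] fit containing the interaction term.
#' @param interaction Name of the interaction coefficient.
#' @return A list with `estimate`, `se`, `z`, two-sided `p` and the ratio of
#'   subgroup ORs `exp(estimate)`.
#' @export
wald_compare_or <- function(fit, interaction) {
  stopifnot(inherits(fit, "gee_fit"))
  b <- stats::coef(fit$fit)
  if (!interaction %in% names(b)) {
    stopf("missing interaction term '%s' in the fit", interaction)
  }
  est <- b[[interaction]]
  se <- sqrt(fit$vcov[interaction, interaction])
  z <- est / se
  list(term = interaction, estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), or_ratio = exp(est))
}

#' Append subgroup interaction columns to a feature matrix
#'
#' Adds product columns between a binary moderator (lesion size >= 1 cm or
#' mass vs non-mass type) and a continuous DTI feature on its analysis
#' scale, so subgroup-specific odds ratios are recoverable as
#' exp((main + interaction) x SD). The default pairs are size x ADC,
#' type x ADC, size x FA and type x FA; a base model with 12 parameters
#' (intercept included) gains 4, giving 16.
#'
#' @param fm A [prepare_features()] object.
#' @param pairs List of character pairs `c(moderator, feature)`.
#' @return The feature matrix with interaction columns named
#'   `<moderator>_x_<feature>` and a populated interaction registry.
#' @export
build_interactions <- function(fm,
                               pairs = list(c("size_large", "adc"),
                                            c("mass", "adc"),
                                            c("size_large", "fa"),
                                            c("mass", "fa"))) {
  stopifnot(inherits(fm, "feature_matrix"))
  for (pr in pairs) {
    if (length(pr) != 2L || !all(pr %in% names(fm$data))) {
      stopf("unknown interaction pair: (%s)", paste(pr, collapse = ", "))
    }
    mod <- pr[1]; feat <- pr[2]
    if (!is_binary01(fm$data[[mod]])) {
      stopf("moderator '%s' must be binary 0/1", mod)
    }
    if (length(unique(fm$data[[mod]])) == 1L) {
      warnf("degenerate subgroup: moderator '%s' is constant; interaction '%s_x_%s' is collinear with '%s'",
            mod, mod, feat, feat)
    }
    nm <- paste0(mod, "_x_", feat)
    fm$data[[nm]] <- fm$data[[mod]] * fm$data[[feat]]
    fm$binary[nm] <- FALSE
    fm$scaled[nm] <- FALSE
    fm$interactions[[nm]] <- list(moderator = mod, feature = feat)
  }
  fm
}

#' Subgroup odds ratio implied by a fitted interaction model
#'
#' @param fit A `lasso_fit` (or any object with named `coefficients`).
#' @param fm The feature matrix the model was fit on (for SDs and the
#'   interaction registry).
#' @param feature Continuous feature name.
#' @param moderators Named 0/1 vector fixing each moderator level, e.g.
#'   `c(mass = 1, size_large = 0)`.
#' @return Odds ratio per 1-SD of `feature` within the subgroup.
#' @export
subgroup_or <- function(fit, fm, feature, moderators) {
  b <- fit$coefficients
  slope <- b[[feature]] %||% 0
  for (m in names(moderators)) {
    nm <- paste0(m, "_x_", feature)
    if (nm %in% names(b)) slope <- slope + moderators[[m]] * b[[nm]]
  }
  exp(slope * sd_for_feature(fm, feature))
}

# ---- LASSO with leave-one-patient-out penalty selection ---------------------

#' L1-penalized logistic regression with leave-one-patient-out CV
#'
#' Fits the LASSO path for a candidate feature set, selecting the penalty
#' that minimizes the total held-out binomial deviance when each patient
#' (cluster) is left out in turn — so lesions from one woman are never split
#' between training and validation. Features are standardized to unit SD
#' inside the solver; reported odds ratios are per 1-SD for scaled
#' continuous features and per level/category otherwise. A penalty of
#' exactly 0 reduces to the unpenalized maximum-likelihood fit.
#'
#' The default grid is 100 log-spaced penalties from the smallest penalty
#' that zeroes every coefficient down to 1e-4 of it.
#'
#' Two selection conventions are available. `"min"` takes the strict
#' deviance minimum; because the cross-validated deviance curve is typically
#' very flat near its minimum, this rule retains null predictors with
#' appreciable probability (it is model-selection inconsistent). `"1se"`
#' takes the largest penalty whose total held-out deviance is within one
#' standard error (across patient folds) of the minimum — the standard
#' convention for sparse variable selection.
#'
#' @param fm A [prepare_features()] object (with interactions appended if
#'   desired).
#' @param candidates Candidate feature names; default every column.
#' @param penalty_grid Optional explicit penalty grid (may include 0).
#' @param nlambda,lambda_min_ratio Grid size and lower-range ratio used when
#'   `penalty_grid` is `NULL`.
#' @param selection Penalty-selection convention, `"min"` or `"1se"`.
#' @return An object of class `lasso_fit`: `coefficients` (original scale,
#'   intercept included), `or` (per-1-SD where applicable), logical
#'   `selected` markers (`FALSE` = candidate not selected, the "NS" state),
#'   the chosen `lambda`, the `lambda_grid` and CV `cv_deviance` path, and
#'   `n_parameters` (candidate count + intercept).
#' @export
lasso_logistic_lopo <- function(fm, candidates = NULL, penalty_grid = NULL,
                                nlambda = 100L, lambda_min_ratio = 1e-4,
                                selection = c("min", "1se")) {
  selection <- match.arg(selection)
  stopifnot(inherits(fm, "feature_matrix"))
  candidates <- candidates %||% names(fm$data)
  missing_c <- setdiff(candidates, names(fm$data))
  if (length(missing_c)) {
    stopf("unknown candidate feature(s): %s", paste(missing_c, collapse = ", "))
  }
  x <- as.matrix(fm$data[, candidates, drop = FALSE])
  y <- fm$outcome
  cl <- fm$cluster
  ids <- unique(cl)
  if (length(ids) < 2L) stopf("leave-one-patient-out CV requires >= 2 patients")

  if (is.null(penalty_grid)) {
    # smallest penalty zeroing all coefficients, on glmnet's standardized scale
    lam_max <- glmnet::glmnet(x, y, family = "binomial", nlambda = 3L)$lambda[1]
    penalty_grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                            length.out = nlambda))
  }
  penalty_grid <- sort(unique(penalty_grid), decreasing = TRUE)
  pos <- penalty_grid[penalty_grid > 0]
  has_zero <- any(penalty_grid == 0)

  idx_by_id <- split(seq_along(cl), match(cl, ids))
  n_grid <- length(penalty_grid)
  dev_fold <- matrix(NA_real_, length(idx_by_id), n_grid)
  dev_ok <- rep(TRUE, n_grid)

  for (i in seq_along(idx_by_id)) {
    fold <- idx_by_id[[i]]
    xt <- x[-fold, , drop = FALSE]; yt <- y[-fold]
    xv <- x[fold, , drop = FALSE]; yv <- y[fold]
    if (length(pos)) {
      fit <- tryCatch(
        glmnet::glmnet(xt, yt, family = "binomial", lambda = pos,
                       standardize = TRUE),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        warnf("LASSO path failed for one left-out patient; fold skipped")
        next
      }
      if (length(fit$lambda) == length(pos)) {
        # direct linear predictor; avoids S4 predict dispatch in the hot loop
        eta <- xv %*% as.matrix(fit$beta) +
          matrix(fit$a0, nrow(xv), length(pos), byrow = TRUE)
        p <- clamp_prob(1 / (1 + exp(-eta)))
      } else {
        # early-stopped path: interpolate at the requested penalties
        p <- clamp_prob(stats::predict(fit, xv, type = "response", s = pos))
      }
      dev_fold[i, seq_along(pos)] <-
        colSums(-2 * (yv * log(p) + (1 - yv) * log(1 - p)))
    }
    if (has_zero) {
      g0 <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(1, xt), yt,
                                        family = stats::binomial())),
        error = function(e) NULL
      )
      if (is.null(g0)) {
        dev_ok[n_grid] <- FALSE
        warnf("unpenalized fit failed for one left-out patient; grid point skipped")
      } else {
        eta <- drop(cbind(1, xv) %*% g0$coefficients)
        dev_fold[i, n_grid] <- binomial_deviance(yv, stats::plogis(eta))
      }
    }
  }

  dev_total <- colSums(dev_fold)
  dev_total[!dev_ok | is.na(dev_total)] <- Inf
  i_min <- which.min(dev_total)         # ties resolve to the larger penalty
  sel <- if (selection == "min") {
    i_min
  } else {
    # SE of the total held-out deviance across patient folds at the minimum
    se_min <- stats::sd(dev_fold[, i_min], na.rm = TRUE) *
      sqrt(sum(!is.na(dev_fold[, i_min])))
    which(dev_total <= dev_total[i_min] + se_min)[1]
  }
  lambda_sel <- penalty_grid[sel]

  if (lambda_sel > 0) {
    full <- glmnet::glmnet(x, y, family = "binomial", lambda = pos,
                           standardize = TRUE)
    j <- which(abs(full$lambda - lambda_sel) < 1e-12 * max(lambda_sel, 1))[1]
    cf <- if (!is.na(j)) {
      stats::setNames(c(full$a0[[j]], as.matrix(full$beta)[, j]),
                      c("(Intercept)", candidates))
    } else {
      drop(as.matrix(stats::coef(full, s = lambda_sel, exact = FALSE)))
    }
    engine <- "glmnet"
  } else {
    g <- suppressWarnings(stats::glm.fit(cbind("(Intercept)" = 1, x), y,
                                         family = stats::binomial()))
    cf <- stats::setNames(g$coefficients, c("(Intercept)", candidates))
    engine <- "glm"
  }
  beta <- cf[candidates]
  selected <- abs(beta) > 0
  sds_used <- vapply(candidates, function(nm) sd_for_feature(fm, nm), numeric(1))
  or <- exp(beta * sds_used)

  structure(list(
    coefficients = cf,
    or = or,
    selected = selected,
    lambda = lambda_sel,
    lambda_grid = penalty_grid,
    cv_deviance = unname(dev_total),
    candidates = candidates,
    sds_used = sds_used,
    n_parameters = length(candidates) + 1L,
    selection = selection,
    engine = engine
  ), class = "lasso_fit")
}

#' @method print lasso_fit
#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("LASSO logistic fit: %d candidates, %d selected (lambda = %.4g)\n",
              length(x$candidates), sum(x$selected), x$lambda))
  or_txt <- ifelse(x$selected, sprintf("%.2f", x$or), "NS")
  print(stats::setNames(or_txt, x$candidates), quote = FALSE)
  invisible(x)
}

#' Predicted malignancy probabilities from a LASSO fit
#'
#' @param object A `lasso_fit`.
#' @param newdata A `feature_matrix`, data frame or matrix containing the
#'   candidate columns on the analysis scale.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  dat <- if (inherits(newdata, "feature_matrix")) newdata$data else newdata
  xx <- as.matrix(as.data.frame(dat)[, object$candidates, drop = FALSE])
  eta <- drop(object$coefficients[["(Intercept)"]] +
                xx %*% object$coefficients[object$candidates])
  stats::plogis(eta)
}
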