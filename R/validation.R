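# ROC/AUC computation and bootstrap internal validation: optimism-adjusted
# AUC (Harrell-style) and patient-clustered bootstrap comparison of models.

# Rank-based (Mann-Whitney) AUC; ties counted half.
mw_auc <- function(scores, outcome) {
  y <- as.integer(outcome)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stopf("undefined AUC: only one outcome class present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score for a binary outcome, with ties
#' counted half; equals (sensitivity + specificity)/2 for a binary predictor.
#'
#' @param scores Numeric risk scores (higher = more suspicious).
#' @param outcome Binary 0/1 outcome.
#' @return The AUC (scalar in [0, 1]).
#' @export
roc_auc <- function(scores, outcome) mw_auc(scores, outcome)

#' ROC curve coordinates
#'
#' Sensitivity and 1 - specificity at every observed threshold, for plotting
#' or export.
#'
#' @param scores,outcome As in [roc_auc()].
#' @return Data frame with `threshold`, `sensitivity`, `one_minus_specificity`.
#' @export
roc_coordinates <- function(scores, outcome) {
  y <- as.integer(outcome)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[y == 0L] >= t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, one_minus_specificity = fpr)
}

# ---- model specifications for refit-able validation -------------------------

#' Model specifications for bootstrap validation
#'
#' A model specification bundles a candidate feature set with a fitting
#' engine so the *entire* fitting procedure (including LASSO penalty
#' re-selection by leave-one-patient-out CV) can be rerun on every bootstrap
#' resample. `lasso_spec()` uses [lasso_logistic_lopo()]; `glm_spec()` fits
#' an unpenalized logistic model (an empty candidate set gives an
#' intercept-only model, i.e. a constant score).
#'
#' @param candidates Candidate feature names.
#' @param nlambda,lambda_min_ratio,penalty_grid,selection Passed to
#'   [lasso_logistic_lopo()].
#' @return An object of class `model_spec`.
#' @export
lasso_spec <- function(candidates, nlambda = 100L, lambda_min_ratio = 1e-4,
                       penalty_grid = NULL, selection = "min") {
  structure(list(engine = "lasso", candidates = candidates, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 penalty_grid = penalty_grid, selection = selection),
            class = "model_spec")
}

#' @rdname lasso_spec
#' @export
glm_spec <- function(candidates = character(0)) {
  structure(list(engine = "glm", candidates = candidates),
            class = "model_spec")
}

#' Fit a model specification to a feature matrix
#'
#' @param spec A [lasso_spec()] or [glm_spec()].
#' @param fm A [prepare_features()] object.
#' @return A fitted model usable with [predict_spec()].
#' @export
fit_model_spec <- function(spec, fm) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$engine == "lasso") {
    lasso_logistic_lopo(fm, candidates = spec$candidates,
                        penalty_grid = spec$penalty_grid,
                        nlambda = spec$nlambda,
                        lambda_min_ratio = spec$lambda_min_ratio,
                        selection = spec$selection %||% "min")
  } else {
    x <- as.matrix(fm$data[, spec$candidates, drop = FALSE])
    g <- suppressWarnings(stats::glm.fit(cbind(1, x), fm$outcome,
                                         family = stats::binomial()))
    structure(list(coefficients = stats::setNames(
      g$coefficients, c("(Intercept)", spec$candidates)),
      candidates = spec$candidates), class = "glm_score_fit")
  }
}

#' Predicted probabilities from a fitted model specification
#'
#' @param fit Result of [fit_model_spec()].
#' @param fm Feature matrix to score.
#' @return Vector of malignancy probabilities.
#' @export
predict_spec <- function(fit, fm) {
  dat <- if (inherits(fm, "feature_matrix")) fm$data else as.data.frame(fm)
  x <- as.matrix(dat[, fit$candidates, drop = FALSE])
  stats::plogis(drop(fit$coefficients[["(Intercept)"]] +
                       x %*% fit$coefficients[fit$candidates]))
}

# Patient-level resample of a feature matrix. Each patient draw becomes a
# distinct cluster in the resample (standard Efron convention): the refit
# procedure, including its leave-one-patient-out CV, treats the resample
# exactly as it would a fresh cohort of the original size.
resample_patients_fm <- function(fm) {
  ids <- unique(fm$cluster)
  idx_by_id <- split(seq_along(fm$cluster), match(fm$cluster, ids))
  draws <- idx_by_id[sample.int(length(ids), replace = TRUE)]
  rows <- unlist(draws, use.names = FALSE)
  out <- fm
  out$data <- fm$data[rows, , drop = FALSE]
  out$outcome <- fm$outcome[rows]
  out$cluster <- rep(seq_along(draws), lengths(draws))
  out
}

#' Bootstrap optimism-adjusted AUC
#'
#' Harrell-style internal validation with resampling by patient rather than
#' by lesion: for each of B bootstrap resamples of patients (with
#' replacement) the full fitting procedure — including LASSO penalty
#' selection — is rerun; the optimism of that refit is its AUC on the
#' resample minus its AUC on the original data, and the adjusted AUC is the
#' apparent AUC minus the mean optimism. The percentile CI comes from the
#' resample apparent AUCs. Resamples with a single outcome class are redrawn
#' (counted in `redraws`).
#'
#' @param spec A [lasso_spec()] or [glm_spec()].
#' @param fm A [prepare_features()] object.
#' @param B Number of bootstrap replicates (>= 1; 1000 by default).
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `auc_estimate`: `apparent`, `adjusted`,
#'   `optimism` (mean), `ci`, `B`, `seed`, `redraws`.
#' @export
bootstrap_optimism_auc <- function(spec, fm, B = 1000L, seed = NULL,
                                   conf_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"), inherits(fm, "feature_matrix"))
  if (B < 1L) stopf("B must be >= 1")
  fit0 <- fit_model_spec(spec, fm)
  apparent <- mw_auc(predict_spec(fit0, fm), fm$outcome)

  with_seed(seed, {
    boot_auc <- numeric(B)
    optimism <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        fmb <- resample_patients_fm(fm)
        if (length(unique(fmb$outcome)) > 1L) break
        redraws <- redraws + 1L
        if (redraws > 100L * B) stopf("bootstrap cannot produce two-class resamples")
      }
      fitb <- fit_model_spec(spec, fmb)
      auc_b <- mw_auc(predict_spec(fitb, fmb), fmb$outcome)
      auc_o <- mw_auc(predict_spec(fitb, fm), fm$outcome)
      boot_auc[b] <- auc_b
      optimism[b] <- auc_b - auc_o
    }
    alpha <- 1 - conf_level
    structure(list(
      apparent = apparent,
      adjusted = apparent - mean(optimism),
      optimism = mean(optimism),
      ci = unname(stats::quantile(boot_auc, c(alpha / 2, 1 - alpha / 2))),
      boot_auc = boot_auc,
      B = B, seed = seed, redraws = redraws
    ), class = "auc_estimate")
  })
}

#' @method print auc_estimate
#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC: apparent %.3f, optimism-adjusted %.3f (95%% CI %.3f-%.3f; B = %d)\n",
              x$apparent, x$adjusted, x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Patient-clustered bootstrap comparison of two model AUCs
#'
#' Both specifications are refit on the same patient-level resamples
#' (paired), their AUC difference recorded per resample, and the two-sided
#' p-value taken from the tail mass of the bootstrap distribution beyond 0
#' (doubled and capped at 1). When a tail is empty the p-value falls back to
#' a normal approximation from the bootstrap mean and SD, flagged by
#' `normal_approx`.
#'
#' @param spec_a,spec_b Model specifications ([lasso_spec()]/[glm_spec()]).
#' @param fm A [prepare_features()] object.
#' @param B Number of paired bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `auc_difference`: `delta` (apparent AUC_A -
#'   AUC_B), `ci`, `p`, `normal_approx`, `B`, `seed`.
#' @export
bootstrap_auc_diff <- function(spec_a, spec_b, fm, B = 1000L, seed = NULL,
                               conf_level = 0.95) {
  stopifnot(inherits(spec_a, "model_spec"), inherits(spec_b, "model_spec"),
            inherits(fm, "feature_matrix"))
  fit_a <- fit_model_spec(spec_a, fm)
  fit_b <- fit_model_spec(spec_b, fm)
  delta <- mw_auc(predict_spec(fit_a, fm), fm$outcome) -
    mw_auc(predict_spec(fit_b, fm), fm$outcome)

  with_seed(seed, {
    deltas <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        fmb <- resample_patients_fm(fm)
        if (length(unique(fmb$outcome)) > 1L) break
        redraws <- redraws + 1L
        if (redraws > 100L * B) stopf("bootstrap cannot produce two-class resamples")
      }
      fa <- fit_model_spec(spec_a, fmb)
      fb <- fit_model_spec(spec_b, fmb)
      deltas[b] <- mw_auc(predict_spec(fa, fmb), fmb$outcome) -
        mw_auc(predict_spec(fb, fmb), fmb$outcome)
    }
    alpha <- 1 - conf_level
    lo_tail <- mean(deltas <= 0)
    hi_tail <- mean(deltas >= 0)
    normal_approx <- FALSE
    if (min(lo_tail, hi_tail) == 0) {
      s <- stats::sd(deltas)
      if (s == 0) {
        # identical models on every resample: no evidence against equality
        p <- 1
      } else {
        normal_approx <- TRUE
        p <- 2 * stats::pnorm(-abs(mean(deltas) / s))
      }
    } else {
      p <- min(1, 2 * min(lo_tail, hi_tail))
    }
    structure(list(
      delta = delta,
      ci = unname(stats::quantile(deltas, c(alpha / 2, 1 - alpha / 2))),
      p = p, normal_approx = normal_approx,
      boot_deltas = deltas, B = B, seed = seed, redraws = redraws
    ), class = "auc_difference")
  })
}

#' @method print auc_difference
#' @export
print.auc_difference <- function(x, ...) {
  cat(sprintf("Delta AUC = %.3f (95%% CI %.3f to %.3f), p = %.3g%s\n",
              x$delta, x$ci[1], x$ci[2], x$p,
              if (x$normal_approx) " [normal approximation]" else ""))
  invisible(x)
}
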