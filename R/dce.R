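KINETIC_LEVELS <- c("persistent", "plateau", "washout")

#' Classify voxel enhancement kinetics
#'
#' Categorizes the delayed-phase enhancement curve of each voxel from the
#' relative signal change between the initial (120 s) and final (480 s)
#' post-contrast scans: a decrease of more than 10% is washout, an increase
#' of more than 10% is persistent, and anything in between (boundaries
#' included) is plateau. Suspicion ranks as washout > plateau > persistent.
#'
#' @param s_initial Signal at the initial post-contrast time point (> 0).
#' @param s_final Signal at the final post-contrast time point.
#' @return An ordered factor with levels persistent < plateau < washout,
#'   vectorized over the inputs.
#' @examples
#' classify_voxel_kinetics(100, 85)   # washout
#' classify_voxel_kinetics(100, 120)  # persistent
#' classify_voxel_kinetics(100, 90)   # plateau (boundary, exactly -10%)
#' @export
classify_voxel_kinetics <- function(s_initial, s_final) {
  if (any(s_initial <= 0)) {
    stopf("unenhanced voxel: initial post-contrast signal must be > 0")
  }
  r <- (s_final - s_initial) / s_initial
  cls <- ifelse(r < -0.10, "washout", ifelse(r > 0.10, "persistent", "plateau"))
  factor(cls, levels = KINETIC_LEVELS, ordered = TRUE)
}

#' Most suspicious kinetic class in a lesion
#'
#' The lesion-level "worst curve" is the maximum of the per-voxel classes
#' under the suspicion ordering washout > plateau > persistent.
#'
#' @param classes Ordered factor (or character vector) of kinetic classes.
#' @return A single ordered factor level.
#' @export
worst_curve <- function(classes) {
  if (!length(classes)) stopf("worst_curve requires at least one kinetic class")
  if (!is.factor(classes)) {
    classes <- factor(classes, levels = KINETIC_LEVELS, ordered = TRUE)
  }
  if (anyNA(classes)) stopf("unknown kinetic class in input")
  classes[which.max(as.integer(classes))]
}

#' Simulate per-voxel DCE enhancement curves of a known kinetic class
#'
#' Generates signal at the pre-contrast (0 s) and three post-contrast
#' (120, 300, 480 s) time points. Noiseless class templates satisfy the
#' classification inequalities with margin: washout falls 20% from 120 s to
#' 480 s, persistent rises 30%, plateau is flat.
#'
#' @param kinetic_class One of `"persistent"`, `"plateau"`, `"washout"`.
#' @param n_voxels Number of voxels to simulate.
#' @param noise_sigma Gaussian noise SD added to every sample (signal units).
#' @param seed Integer seed.
#' @param s_pre Pre-contrast signal level.
#' @param enhancement Peak enhancement ratio at 120 s relative to `s_pre`.
#' @return A list of class `dce_curves`: `curves` (n_voxels x 4 matrix with
#'   columns t0, t120, t300, t480), `times`, and the generating `class`.
#' @export
simulate_dce_lesion <- function(kinetic_class = c("washout", "plateau", "persistent"),
                                n_voxels = 25L, noise_sigma = 0, seed = 1L,
                                s_pre = 100, enhancement = 2.0) {
  kinetic_class <- match.arg(kinetic_class)
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  s120 <- s_pre * enhancement
  shape <- switch(kinetic_class,
    washout    = c(1, 0.90, 0.80),
    plateau    = c(1, 1.00, 1.00),
    persistent = c(1, 1.15, 1.30)
  )
  base <- c(s_pre, s120 * shape)
  curves <- matrix(rep(base, each = n_voxels), n_voxels, 4L)
  curves <- with_seed(seed, {
    if (noise_sigma > 0) {
      curves + matrix(stats::rnorm(n_voxels * 4L, 0, noise_sigma), n_voxels, 4L)
    } else {
      curves
    }
  })
  colnames(curves) <- c("t0", "t120", "t300", "t480")
  structure(list(curves = curves, times = c(0, 120, 300, 480),
                 class = kinetic_class),
            class = "dce_curves")
}

#' Lesion-level kinetic assessment of a curve set
#'
#' Classifies every voxel curve and reduces to the lesion's worst (most
#' suspicious) class. The binary "washout on delayed phase" feature used in
#' modeling is `worst == "washout"`.
#'
#' @param curves A `dce_curves` object or an n x 4 matrix with columns
#'   t0, t120, t300, t480.
#' @return A list with `voxel_classes`, `worst` and logical `washout`.
#' @export
lesion_kinetics <- function(curves) {
  m <- if (inherits(curves, "dce_curves")) curves$curves else as.matrix(curves)
  if (ncol(m) != 4L) stopf("curves must have 4 time points (t0, t120, t300, t480)")
  cls <- classify_voxel_kinetics(m[, 2], m[, 4])
  w <- worst_curve(cls)
  list(voxel_classes = cls, worst = w, washout = w == "washout")
}
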