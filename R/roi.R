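#' Refine a seed lesion region by low-signal exclusion
#'
#' Mirrors a semi-automated lesion ROI workflow on the combined
#' diffusion-weighted image: starting from a manually seeded single-slice
#' region, voxels whose combined-DWI intensity falls below
#' `threshold_fraction` times the maximum intensity within the seed are
#' excluded (they typically correspond to adipose or normal fibroglandular
#' tissue). The absolute threshold used is recorded for provenance.
#'
#' @param combined 3D array, e.g. from [combined_dwi()].
#' @param seed_region n x 3 integer matrix of 1-based voxel indices; all rows
#'   must share one slice (third index).
#' @param threshold_fraction Fraction of the in-seed maximum in [0, 1).
#' @return An object of class `lesion_roi`: `voxels` (retained n x 3 index
#'   matrix), `slice`, `threshold` (absolute), `threshold_fraction`,
#'   `n_seed`, `n_excluded`, and logical `empty`. An all-excluded seed yields
#'   `empty = TRUE` (the caller decides whether the lesion is non-evaluable).
#' @examples
#' img <- array(0, c(3, 1, 1)); img[, 1, 1] <- c(10, 100, 120)
#' roi <- refine_roi(img, cbind(1:3, 1, 1), 0.5)  # keeps the 100 and 120 voxels
#' @export
refine_roi <- function(combined, seed_region, threshold_fraction = 0.5) {
  seed_region <- as.matrix(seed_region)
  storage.mode(seed_region) <- "integer"
  if (!nrow(seed_region) || ncol(seed_region) != 3L) {
    stopf("seed_region must be a non-empty n x 3 voxel index matrix")
  }
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    stopf("threshold_fraction must lie in [0, 1)")
  }
  dims <- dim(combined)
  if (length(dims) != 3L) stopf("combined must be a 3D image")
  if (any(seed_region < 1L) ||
      any(seed_region > matrix(dims, nrow(seed_region), 3L, byrow = TRUE))) {
    stopf("seed_region contains voxels outside the image bounds")
  }
  slices <- unique(seed_region[, 3])
  if (length(slices) != 1L) {
    stopf("multi-slice seed region (slices %s): ROIs are defined on the central slice only",
          paste(slices, collapse = ", "))
  }
  vals <- combined[seed_region]
  threshold <- threshold_fraction * max(vals)
  keep <- vals >= threshold
  structure(list(
    voxels = seed_region[keep, , drop = FALSE],
    slice = slices,
    threshold = threshold,
    threshold_fraction = threshold_fraction,
    n_seed = nrow(seed_region),
    n_excluded = sum(!keep),
    empty = !any(keep)
  ), class = "lesion_roi")
}

#' @method print lesion_roi
#' @export
print.lesion_roi <- function(x, ...) {
  cat(sprintf("Lesion ROI: slice %d, %d/%d voxels kept (threshold %.4g)%s\n",
              x$slice, nrow(x$voxels), x$n_seed, x$threshold,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

#' Summarize scalar maps over a lesion ROI
#'
#' Propagates the refined ROI to every scalar parametric map and computes the
#' arithmetic mean voxel value per map. FA is averaged voxel-wise (the mean
#' of per-voxel FA, never the FA of mean eigenvalues).
#'
#' @param maps A `scalar_maps` object from [scalar_maps()].
#' @param roi A `lesion_roi` from [refine_roi()].
#' @return A one-row data frame with `mean_adc`, `mean_fa`, `mean_axial`,
#'   `mean_radial`, `mean_lambda_diff` and `n_voxels`.
#' @export
lesion_summary <- function(maps, roi) {
  stopifnot(inherits(maps, "scalar_maps"), inherits(roi, "lesion_roi"))
  if (roi$empty || !nrow(roi$voxels)) {
    stopf("empty ROI: no voxels survived refinement; lesion is non-evaluable")
  }
  data.frame(
    mean_adc = mean(maps$adc[roi$voxels]),
    mean_fa = mean(maps$fa[roi$voxels]),
    mean_axial = mean(maps$axial[roi$voxels]),
    mean_radial = mean(maps$radial[roi$voxels]),
    mean_lambda_diff = mean(maps$lambda_diff[roi$voxels]),
    n_voxels = nrow(roi$voxels)
  )
}
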