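#' Construct a symmetric diffusion tensor from its eigensystem
#'
#' Builds D = R diag(lambda) R' where the first column of R is the unit
#' principal direction and the remaining columns complete an orthonormal
#' basis.
#'
#' @param eigenvalues Length-3 numeric vector, sorted descending, all > 0
#'   (mm^2/s).
#' @param direction Length-3 principal-eigenvector direction (any norm > 0).
#' @return A 3 x 3 symmetric matrix.
#' @export
tensor_from_eigen <- function(eigenvalues, direction = c(1, 0, 0)) {
  check_eigenvalues(eigenvalues)
  v1 <- direction / sqrt(sum(direction^2))
  # complete an orthonormal frame around v1
  helper <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v2 <- helper - sum(helper * v1) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  R <- cbind(v1, v2, v3)
  D <- R %*% diag(eigenvalues) %*% t(R)
  (D + t(D)) / 2
}

check_eigenvalues <- function(ev) {
  if (length(ev) != 3L || any(!is.finite(ev))) {
    stopf("invalid tensor: eigenvalues must be 3 finite numbers")
  }
  if (any(ev <= 0)) {
    stopf("invalid tensor: eigenvalues must be positive (got %s)",
          paste(signif(ev, 4), collapse = ", "))
  }
  if (is.unsorted(rev(ev))) {
    stopf("eigenvalues must be sorted descending (lambda1 >= lambda2 >= lambda3)")
  }
  invisible(ev)
}

#' Describe one homogeneous tensor region of a phantom
#'
#' @param eigenvalues Descending positive eigenvalue triple (mm^2/s).
#' @param direction Principal-eigenvector direction.
#' @param voxels Optional n x 3 integer matrix of 1-based voxel indices; `NULL`
#'   means the region fills whatever part of the grid no earlier region claims.
#' @return A list of class `tensor_region`.
#' @export
tensor_region <- function(eigenvalues, direction = c(1, 0, 0), voxels = NULL) {
  check_eigenvalues(eigenvalues)
  if (!is.null(voxels)) {
    voxels <- as.matrix(voxels)
    storage.mode(voxels) <- "integer"
    if (ncol(voxels) != 3L) stopf("voxels must be an n x 3 index matrix")
  }
  structure(list(eigenvalues = eigenvalues, direction = direction,
                 voxels = voxels),
            class = "tensor_region")
}

#' Configuration for a DWI phantom
#'
#' Defines the voxel grid, per-region diffusion tensors, baseline signal and
#' noise model of a synthetic diffusion-weighted acquisition following the
#' mono-exponential signal model S = S0 exp(-b g'Dg).
#'
#' @param grid_shape Integer triple of voxels per axis.
#' @param regions List of [tensor_region()] objects. Regions with explicit
#'   voxel lists are painted in order; at most one region may omit `voxels`
#'   and then fills the remainder of the grid.
#' @param s0 Baseline (b = 0) signal intensity, arbitrary units.
#' @param noise_sigma Noise scale (same units as `s0`); >= 0.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian perturbation, as in magnitude MRI).
#' @param voxel_size Voxel dimensions in mm.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(8L, 8L, 4L),
                           regions = list(tensor_region(c(2.0, 1.5, 1.0) * 1e-3)),
                           s0 = 1000,
                           noise_sigma = 0,
                           noise_model = c("gaussian", "rician"),
                           voxel_size = c(1.5, 1.5, 5),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stopf("grid_shape must be 3 positive integers")
  }
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (s0 <= 0) stopf("s0 must be > 0")
  if (!length(regions)) stopf("at least one tensor region is required")
  lapply(regions, function(r) {
    if (!inherits(r, "tensor_region")) stopf("regions must be tensor_region objects")
  })
  if (sum(vapply(regions, function(r) is.null(r$voxels), logical(1))) > 1L) {
    stopf("at most one region may omit an explicit voxel list")
  }
  structure(list(grid_shape = grid_shape, regions = regions, s0 = s0,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Construct a 4D diffusion-weighted volume
#'
#' @param data 4D array (x, y, z, acquisition) of non-negative intensities.
#' @param scheme A [make_gradient_scheme()] object; its length must equal the
#'   4th dimension of `data`.
#' @param voxel_size Voxel dimensions in mm.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, scheme, voxel_size = c(1.5, 1.5, 5)) {
  if (!inherits(scheme, "gradient_scheme")) stopf("scheme must be a gradient_scheme")
  d <- dim(data)
  if (length(d) != 4L) stopf("data must be a 4D array (x, y, z, acquisition)")
  if (d[4] != length(scheme$b)) {
    stopf("acquisition axis length (%d) does not match scheme length (%d)",
          d[4], length(scheme$b))
  }
  if (any(data < 0, na.rm = TRUE)) stopf("intensities must be >= 0")
  structure(list(data = data, scheme = scheme, voxel_size = voxel_size),
            class = "dwi_volume")
}

#' @method print dwi_volume
#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d acquisitions\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate a diffusion-weighted phantom with known tensors
#'
#' Evaluates the noiseless tensor signal S = S0 exp(-b g'Dg) per voxel and
#' acquisition, then adds Gaussian or Rician noise. The returned truth record
#' carries the generating tensor field for recovery tests.
#'
#' @param config A [phantom_config()].
#' @param scheme A [make_gradient_scheme()] object.
#' @return A list with elements `dwi` (a [dwi_volume()]) and `truth` (list
#'   with per-voxel `tensors` as an (x, y, z, 6) array in the order
#'   xx, yy, zz, xy, xz, yz, per-voxel `eigenvalues` (x, y, z, 3, descending),
#'   `region_id` map and the `config` used).
#' @examples
#' cfg <- phantom_config(grid_shape = c(4, 4, 2),
#'                       regions = list(tensor_region(c(1.5, 1.5, 1.5) * 1e-3)))
#' sim <- simulate_dwi_phantom(cfg, make_gradient_scheme())
#' @export
simulate_dwi_phantom <- function(config, scheme) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(scheme, "gradient_scheme"))
  dims <- config$grid_shape
  n_vox <- prod(dims)
  n_acq <- length(scheme$b)

  # paint region ids
  region_id <- array(NA_integer_, dims)
  fill_idx <- NULL
  for (i in seq_along(config$regions)) {
    r <- config$regions[[i]]
    if (is.null(r$voxels)) {
      fill_idx <- i
    } else {
      if (any(r$voxels < 1L) ||
          any(r$voxels > matrix(dims, nrow(r$voxels), 3, byrow = TRUE))) {
        stopf("region %d has voxels outside the grid", i)
      }
      region_id[r$voxels] <- i
    }
  }
  if (!is.null(fill_idx)) region_id[is.na(region_id)] <- fill_idx
  if (anyNA(region_id)) stopf("regions do not cover the grid and no fill region given")

  # per-region tensor as 6-vector (xx, yy, zz, xy, xz, yz)
  d6 <- vapply(config$regions, function(r) {
    D <- tensor_from_eigen(r$eigenvalues, r$direction)
    c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }, numeric(6))
  ev3 <- vapply(config$regions, function(r) r$eigenvalues, numeric(3))

  vox_d6 <- t(d6)[as.vector(region_id), , drop = FALSE]   # n_vox x 6

  # quadratic form per acquisition: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
  g <- scheme$g
  bq <- scheme$b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                         2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                         2 * g[, 2] * g[, 3])              # n_acq x 6
  signal <- config$s0 * exp(-vox_d6 %*% t(bq))             # n_vox x n_acq

  signal <- with_seed(config$seed, {
    if (config$noise_sigma > 0) {
      if (config$noise_model == "gaussian") {
        signal + matrix(stats::rnorm(n_vox * n_acq, 0, config$noise_sigma),
                        n_vox, n_acq)
      } else {
        re <- signal + matrix(stats::rnorm(n_vox * n_acq, 0, config$noise_sigma),
                              n_vox, n_acq)
        im <- matrix(stats::rnorm(n_vox * n_acq, 0, config$noise_sigma),
                     n_vox, n_acq)
        sqrt(re^2 + im^2)
      }
    } else {
      signal
    }
  })
  if (config$noise_model == "gaussian") signal <- pmax(signal, 0)

  truth <- list(
    tensors = array(vox_d6, c(dims, 6L)),
    eigenvalues = array(t(ev3)[as.vector(region_id), , drop = FALSE], c(dims, 3L)),
    region_id = region_id,
    config = config
  )
  list(dwi = dwi_volume(array(signal, c(dims, n_acq)), scheme,
                        config$voxel_size),
       truth = truth)
}

#' Prolate eigenvalue triple matching a target ADC and FA
#'
#' Inverts the mean-diffusivity and fractional-anisotropy definitions for an
#' axially symmetric (prolate, lambda2 = lambda3) tensor. With
#' delta = FA / sqrt(3 - 2 FA^2), the triple is
#' lambda1 = ADC (1 + 2 delta), lambda2 = lambda3 = ADC (1 - delta).
#'
#' @param adc Target mean diffusivity (any units); > 0.
#' @param fa Target fractional anisotropy in [0, 1).
#' @return For scalar input a length-3 descending vector; for vector input an
#'   n x 3 matrix.
#' @export
eigenvalues_from_adc_fa <- function(adc, fa) {
  if (any(adc <= 0)) stopf("adc must be > 0")
  if (any(fa < 0 | fa >= 1)) stopf("fa must lie in [0, 1) for a prolate tensor")
  delta <- fa / sqrt(3 - 2 * fa^2)
  out <- cbind(adc * (1 + 2 * delta), adc * (1 - delta), adc * (1 - delta))
  colnames(out) <- c("lambda1", "lambda2", "lambda3")
  if (length(adc) == 1L && length(fa) == 1L) drop(out) else out
}
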