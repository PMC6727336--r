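#' Estimate the diffusion tensor per voxel
#'
#' Fits the log-linearized mono-exponential model
#' log S = log S0 - b g'Dg by least squares in every masked voxel, then
#' diagonalizes the estimated tensor. This is the standard 7-parameter design
#' (six unique tensor elements plus log S0); all shells in the scheme enter
#' one joint fit unless `shells` restricts them.
#'
#' Voxels with any non-positive signal among the used acquisitions are
#' excluded from the fit (the log transform is undefined there and such voxels
#' are noise-dominated); they are reported in the validity mask. Negative
#' eigenvalues are clamped to zero and flagged, which keeps FA within [0, 1].
#'
#' @param dwi A [dwi_volume()].
#' @param mask Optional logical array over the voxel grid; `NULL` fits all
#'   voxels.
#' @param method `"ols"` (default) for ordinary least squares on log-signals,
#'   or `"wls"` for weighted least squares with weights proportional to the
#'   squared signal (the first-order variance correction for log-transformed
#'   Rician/Gaussian noise).
#' @param shells Optional numeric vector of b-values to use (must include 0
#'   and at least one non-zero shell); `NULL` uses every acquisition.
#' @return An object of class `tensor_map`: per-voxel `eigenvalues`
#'   (x, y, z, 3; descending), `eigenvectors` (x, y, z, 3, 3; columns are
#'   eigenvectors), `tensor` (x, y, z, 6; xx, yy, zz, xy, xz, yz), `s0`,
#'   logical `mask` of fitted voxels, and `clamped` flags.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("ols", "wls"),
                       shells = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  method <- match.arg(method)
  scheme <- dwi$scheme
  use <- if (is.null(shells)) rep(TRUE, length(scheme$b)) else scheme$b %in% shells
  if (!any(scheme$b[use] == 0)) stopf("selected shells must include b = 0")
  if (sum(use & scheme$b > 0) < 6L) {
    stopf("degenerate design: fewer than 6 diffusion-weighted acquisitions selected")
  }

  b <- scheme$b[use]
  g <- scheme$g[use, , drop = FALSE]
  X <- cbind(1, -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                           2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                           2 * g[, 2] * g[, 3]))
  if (qr(X)$rank < 7L) {
    stopf("degenerate design: gradient scheme does not span the 6 tensor elements")
  }

  dims <- dim(dwi$data)[1:3]
  n_vox <- prod(dims)
  S <- matrix(dwi$data, n_vox, dim(dwi$data)[4])[, use, drop = FALSE]

  in_mask <- if (is.null(mask)) rep(TRUE, n_vox) else as.vector(mask)
  if (length(in_mask) != n_vox) stopf("mask does not match the voxel grid")
  positive <- rowSums(S <= 0) == 0L
  fit_vox <- which(in_mask & positive)

  eigenvalues <- array(NA_real_, c(dims, 3L))
  eigenvectors <- array(NA_real_, c(dims, 3L, 3L))
  tensor6 <- array(NA_real_, c(dims, 6L))
  s0 <- array(NA_real_, dims)
  clamped <- array(FALSE, dims)

  if (length(fit_vox)) {
    logS <- log(S[fit_vox, , drop = FALSE])
    if (method == "ols") {
      P <- solve(crossprod(X), t(X))            # 7 x n_acq
      coefs <- logS %*% t(P)                    # n_fit x 7
    } else {
      coefs <- matrix(NA_real_, length(fit_vox), 7L)
      for (i in seq_along(fit_vox)) {
        w <- S[fit_vox[i], ]^2
        coefs[i, ] <- stats::lm.wfit(X, logS[i, ], w)$coefficients
      }
    }
    ev_mat <- matrix(NA_real_, length(fit_vox), 3L)
    for (i in seq_along(fit_vox)) {
      d <- coefs[i, 2:7]
      D <- matrix(c(d[1], d[4], d[5],
                    d[4], d[2], d[6],
                    d[5], d[6], d[3]), 3L, 3L)
      es <- eigen(D, symmetric = TRUE)          # values already descending
      ev <- es$values
      if (any(ev < 0)) {
        clamped[fit_vox[i]] <- TRUE
        ev <- pmax(ev, 0)
      }
      ev_mat[i, ] <- ev
      vox <- arrayInd(fit_vox[i], dims)
      eigenvectors[vox[1], vox[2], vox[3], , ] <- es$vectors
    }
    # fill per-voxel arrays via matrix assignment on the flattened grids
    for (k in 1:3) {
      tmp <- array(NA_real_, dims)
      tmp[fit_vox] <- ev_mat[, k]
      eigenvalues[, , , k] <- tmp
    }
    for (k in 1:6) {
      tmp <- array(NA_real_, dims)
      tmp[fit_vox] <- coefs[, k + 1L]
      tensor6[, , , k] <- tmp
    }
    s0[fit_vox] <- exp(coefs[, 1])
  }

  valid <- array(FALSE, dims)
  valid[fit_vox] <- TRUE
  structure(list(eigenvalues = eigenvalues, eigenvectors = eigenvectors,
                 tensor = tensor6, s0 = s0, mask = valid, clamped = clamped,
                 excluded_nonpositive = sum(in_mask & !positive),
                 method = method, dims = dims),
            class = "tensor_map")
}

#' @method print tensor_map
#' @export
print.tensor_map <- function(x, ...) {
  cat(sprintf("Tensor map: %s grid, %d fitted voxels (%d clamped, %d excluded)\n",
              paste(x$dims, collapse = " x "), sum(x$mask), sum(x$clamped),
              x$excluded_nonpositive))
  invisible(x)
}

#' Mean diffusivity from an eigenvalue triple
#'
#' ADC (mean diffusivity) is the average of the three diffusion-tensor
#' eigenvalues.
#'
#' @param ev Length-3 vector or n x 3 matrix of eigenvalues.
#' @return Scalar or vector of mean diffusivities.
#' @export
adc_from_eigenvalues <- function(ev) {
  ev <- rbind(ev)
  unname(rowMeans(ev))
}

#' Fractional anisotropy from an eigenvalue triple
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - ADC)^2)) / sqrt(sum(lambda_i^2)),
#' a unitless measure in [0, 1]; the FA of the zero tensor is defined as 0.
#'
#' @param ev Length-3 vector or n x 3 matrix of eigenvalues.
#' @return Scalar or vector of FA values.
#' @examples
#' fa_from_eigenvalues(c(2.20, 2.00, 1.80) * 1e-3)  # 0.0997...
#' @export
fa_from_eigenvalues <- function(ev) {
  ev <- rbind(ev)
  md <- rowMeans(ev)
  num <- sqrt(rowSums((ev - md)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  unname(fa)
}

#' Compute scalar parametric maps from a tensor map
#'
#' Produces the five rotationally invariant per-voxel parameters used to
#' characterize lesions: ADC (mean diffusivity, the eigenvalue average),
#' FA, axial diffusivity (lambda1), radial diffusivity ((lambda2+lambda3)/2),
#' and the empirical difference lambda1 - lambda3. All are computed from the
#' descending-sorted eigenvalues.
#'
#' @param tensors A `tensor_map` from [fit_tensor()].
#' @return An object of class `scalar_maps`: a list of 3D arrays `adc`, `fa`,
#'   `axial`, `radial`, `lambda_diff` (diffusivities in the input units,
#'   FA unitless).
#' @export
scalar_maps <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_map"))
  dims <- tensors$dims
  ev <- matrix(tensors$eigenvalues, prod(dims), 3L)
  adc <- rowMeans(ev)
  fa <- rep(NA_real_, nrow(ev))
  ok <- !is.na(ev[, 1])
  fa[ok] <- fa_from_eigenvalues(ev[ok, , drop = FALSE])
  structure(list(
    adc = array(adc, dims),
    fa = array(fa, dims),
    axial = array(ev[, 1], dims),
    radial = array((ev[, 2] + ev[, 3]) / 2, dims),
    lambda_diff = array(ev[, 1] - ev[, 3], dims)
  ), class = "scalar_maps")
}

#' @method print scalar_maps
#' @export
print.scalar_maps <- function(x, ...) {
  cat(sprintf("Scalar maps (%s grid): adc, fa, axial, radial, lambda_diff\n",
              paste(dim(x$adc), collapse = " x ")))
  invisible(x)
}

#' Combined diffusion-weighted image
#'
#' The geometric mean of the unidirectional diffusion-weighted images at one
#' b-value, used for qualitative reading and as the intensity reference for
#' ROI refinement. A voxel with any zero contributing signal maps to zero.
#' On a balanced direction set the combined image equals
#' S0 exp(-b ADC) for noiseless tensor data.
#'
#' @param dwi A [dwi_volume()].
#' @param b_target b-value of the shell to combine (s/mm^2).
#' @return A 3D array.
#' @export
combined_dwi <- function(dwi, b_target = 800) {
  stopifnot(inherits(dwi, "dwi_volume"))
  sel <- which(dwi$scheme$b == b_target)
  if (!length(sel)) {
    stopf("missing shell: no acquisitions at b = %g s/mm^2", b_target)
  }
  dims <- dim(dwi$data)[1:3]
  S <- matrix(dwi$data, prod(dims), dim(dwi$data)[4])[, sel, drop = FALSE]
  if (length(sel) == 1L) return(array(S[, 1], dims))
  # exp(mean(log S)); log(0) = -Inf propagates to a 0 geometric mean
  array(exp(rowMeans(log(pmax(S, 0)))), dims)
}
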