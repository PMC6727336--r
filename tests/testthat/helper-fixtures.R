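# Shared fixtures, all generated in code.

# Lesion-level table for a binary predictor from 2x2 contingency counts
# (positive/total in the malignant and benign groups); one patient per lesion.
binary_feature_cohort <- function(pos_mal, n_mal, pos_ben, n_ben) {
  y <- c(rep(1L, n_mal), rep(0L, n_ben))
  x <- c(rep(1L, pos_mal), rep(0L, n_mal - pos_mal),
         rep(1L, pos_ben), rep(0L, n_ben - pos_ben))
  data.frame(x = x, y = y, patient = seq_along(y))
}

# Pure-noise feature matrix: p standard-normal features unrelated to a 40%-
# prevalence outcome, 1-3 lesions per patient.
noise_feature_matrix <- function(seed, n_patients = 100L, p = 10L) {
  set.seed(seed)
  nles <- sample(1:3, n_patients, TRUE, c(0.8, 0.15, 0.05))
  pid <- rep(seq_len(n_patients), nles)
  n <- length(pid)
  dat <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(dat) <- paste0("x", seq_len(p))
  dat$patient_id <- pid
  dat$lesion_id <- seq_len(n)
  dat$malignant <- rbinom(n, 1L, 0.4)
  prepare_features(dat, log_features = character(0))
}

# DTI distribution overrides with no FA-class association and no ADC-FA
# coupling: a clean null for FA alongside the strong ADC class separation.
null_fa_dti <- function() {
  list(fa_mass_malignant = c(0.25, 0.13), fa_mass_benign = c(0.25, 0.13),
       fa_nonmass_malignant = c(0.25, 0.13), fa_nonmass_benign = c(0.25, 0.13),
       copula_rho = 0)
}

# Random descending positive eigenvalue triple in a diffusivity-like range
# (1e-3 mm^2/s units) and a random rotation, for tensor-recovery tests.
random_tensor <- function() {
  ev <- sort(runif(3, 0.5, 2.8), decreasing = TRUE) * 1e-3
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(eigenvalues = ev, D = Q %*% diag(ev) %*% t(Q), Q = Q)
}

# Noiseless DWI signals for an arbitrary 3x3 tensor under a scheme,
# wrapped as a single-voxel dwi_volume. Built independently of the
# package's phantom path (direct quadratic forms).
signals_for_tensor <- function(D, scheme, s0 = 1000) {
  s <- vapply(seq_along(scheme$b), function(i) {
    g <- scheme$g[i, ]
    s0 * exp(-scheme$b[i] * drop(t(g) %*% D %*% g))
  }, numeric(1))
  dwi_volume(array(s, c(1, 1, 1, length(s))), scheme)
}

# Independent tensor-fit oracle: per-voxel lm() on the log signals with a
# formula-built design (R's QR solver, not the package's normal equations).
lm_tensor_oracle <- function(dwi) {
  b <- dwi$scheme$b
  g <- dwi$scheme$g
  df <- data.frame(
    y = log(as.vector(dwi$data[1, 1, 1, ])),
    xx = -b * g[, 1]^2, yy = -b * g[, 2]^2, zz = -b * g[, 3]^2,
    xy = -2 * b * g[, 1] * g[, 2], xz = -2 * b * g[, 1] * g[, 3],
    yz = -2 * b * g[, 2] * g[, 3]
  )
  cf <- coef(lm(y ~ xx + yy + zz + xy + xz + yz, data = df))
  D <- matrix(c(cf["xx"], cf["xy"], cf["xz"],
                cf["xy"], cf["yy"], cf["yz"],
                cf["xz"], cf["yz"], cf["zz"]), 3, 3)
  eigen(D, symmetric = TRUE)$values
}
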