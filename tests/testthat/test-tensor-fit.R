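scheme <- make_gradient_scheme()

test_that("noiseless phantoms are recovered to near machine precision", {
  ev_true <- c(1.8, 1.5, 1.2) * 1e-3
  cfg <- phantom_config(grid_shape = c(3, 3, 2),
                        regions = list(tensor_region(ev_true, c(0, 0, 1))),
                        noise_sigma = 0)
  tm <- fit_tensor(simulate_dwi_phantom(cfg, scheme)$dwi)
  for (k in 1:3) {
    expect_equal(as.vector(tm$eigenvalues[, , , k]) / ev_true[k],
                 rep(1, 18), tolerance = 1e-9)
  }
  expect_true(all(tm$mask))
  expect_false(any(tm$clamped))
})

test_that("isotropic tensors fit with FA numerically zero", {
  cfg <- phantom_config(grid_shape = c(2, 2, 1),
                        regions = list(tensor_region(rep(1.4e-3, 3))),
                        noise_sigma = 0)
  maps <- scalar_maps(fit_tensor(simulate_dwi_phantom(cfg, scheme)$dwi))
  expect_true(all(abs(maps$fa) < 1e-9))
  expect_equal(as.vector(maps$lambda_diff), rep(0, 4), tolerance = 1e-12)
})

test_that("fitted eigenvalues are invariant to tensor orientation", {
  set.seed(11)
  for (i in 1:5) {
    tn <- random_tensor()
    M <- matrix(rnorm(9), 3, 3)
    R <- qr.Q(qr(M))
    fit1 <- fit_tensor(signals_for_tensor(tn$D, scheme))
    fit2 <- fit_tensor(signals_for_tensor(R %*% tn$D %*% t(R), scheme))
    expect_equal(fit1$eigenvalues[1, 1, 1, ], fit2$eigenvalues[1, 1, 1, ],
                 tolerance = 1e-9)
    expect_equal(fit1$eigenvalues[1, 1, 1, ], tn$eigenvalues,
                 tolerance = 1e-9)
  }
})

test_that("OLS fit agrees with an independent lm-based fitter", {
  set.seed(21)
  for (i in 1:25) {
    tn <- random_tensor()
    dwi <- signals_for_tensor(tn$D, scheme)
    mine <- fit_tensor(dwi)$eigenvalues[1, 1, 1, ]
    oracle <- lm_tensor_oracle(dwi)
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("weighted fit equals OLS on noiseless data", {
  tn <- list(eigenvalues = c(2.0, 1.4, 0.9) * 1e-3)
  cfg <- phantom_config(grid_shape = c(2, 2, 1),
                        regions = list(tensor_region(tn$eigenvalues, c(1, 1, 0))),
                        noise_sigma = 0)
  dwi <- simulate_dwi_phantom(cfg, scheme)$dwi
  expect_equal(fit_tensor(dwi, method = "wls")$eigenvalues,
               fit_tensor(dwi, method = "ols")$eigenvalues, tolerance = 1e-10)
})

test_that("FA stays in [0, 1] on noisy data and clamping flags fire", {
  cfg <- phantom_config(grid_shape = c(6, 6, 2),
                        regions = list(tensor_region(c(1.1, 1.0, 0.9) * 1e-3)),
                        s0 = 200, noise_sigma = 40, seed = 5)
  tm <- fit_tensor(simulate_dwi_phantom(cfg, scheme)$dwi)
  maps <- scalar_maps(tm)
  fa <- maps$fa[tm$mask]
  expect_true(all(fa >= 0 & fa <= 1))
  expect_true(all(tm$eigenvalues[, , , 3][tm$mask] >= 0))
})

test_that("voxels with non-positive signal are excluded and flagged", {
  cfg <- phantom_config(grid_shape = c(2, 2, 1), noise_sigma = 0)
  dwi <- simulate_dwi_phantom(cfg, scheme)$dwi
  dwi$data[1, 1, 1, 4] <- 0
  tm <- fit_tensor(dwi)
  expect_false(tm$mask[1, 1, 1])
  expect_equal(tm$excluded_nonpositive, 1L)
  expect_true(is.na(tm$eigenvalues[1, 1, 1, 1]))
  # empty mask gives an empty map
  tm0 <- fit_tensor(dwi, mask = array(FALSE, c(2, 2, 1)))
  expect_equal(sum(tm0$mask), 0L)
})

test_that("shell restriction works and b=0 is mandatory", {
  cfg <- phantom_config(grid_shape = c(2, 2, 1),
                        regions = list(tensor_region(c(2.2, 2.0, 1.8) * 1e-3)),
                        noise_sigma = 0)
  dwi <- simulate_dwi_phantom(cfg, scheme)$dwi
  tm <- fit_tensor(dwi, shells = c(0, 800))
  expect_equal(tm$eigenvalues[1, 1, 1, ], c(2.2, 2.0, 1.8) * 1e-3,
               tolerance = 1e-9)
  expect_error(fit_tensor(dwi, shells = c(100, 800)), "b = 0")
})

test_that("eigenvalue error grows monotonically with noise", {
  sigmas <- c(0, 10, 20, 40)
  ev_true <- c(1.8, 1.4, 1.0) * 1e-3
  med_err <- vapply(sigmas, function(sg) {
    errs <- vapply(1:200, function(seed) {
      cfg <- phantom_config(grid_shape = c(1, 1, 1),
                            regions = list(tensor_region(ev_true, c(1, 2, 3))),
                            s0 = 1000, noise_sigma = sg, seed = seed)
      tm <- fit_tensor(simulate_dwi_phantom(cfg, scheme)$dwi)
      if (!tm$mask[1, 1, 1]) return(NA_real_)
      mean(abs(tm$eigenvalues[1, 1, 1, ] - ev_true))
    }, numeric(1))
    median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
})

test_that("scalar maps satisfy their defining identities", {
  # worked example: lambda = (2, 1, 1) gives FA = sqrt(6)/6 * sqrt(1.5)...
  expect_lt(abs(fa_from_eigenvalues(c(2, 1, 1)) - 0.4082), 1e-4)
  expect_equal(adc_from_eigenvalues(c(2, 1, 1)), 4 / 3, tolerance = 1e-12)
  # isotropic triple: FA = 0, lambda1 - lambda3 = 0, axial = radial = ADC
  expect_equal(fa_from_eigenvalues(c(0.7, 0.7, 0.7)), 0)
  # FA of the zero tensor is defined as 0
  expect_equal(fa_from_eigenvalues(c(0, 0, 0)), 0)
  # map-level consistency: adc = (axial + 2 radial) / 3 exactly
  cfg <- phantom_config(grid_shape = c(4, 4, 2),
                        regions = list(tensor_region(c(2.0, 1.1, 0.7) * 1e-3,
                                                     c(2, -1, 1))),
                        s0 = 800, noise_sigma = 15, seed = 2)
  maps <- scalar_maps(fit_tensor(simulate_dwi_phantom(cfg, scheme)$dwi))
  expect_equal(maps$adc, (maps$axial + 2 * maps$radial) / 3)
  expect_true(all(maps$lambda_diff >= 0, na.rm = TRUE))
})

test_that("combined DWI is the geometric mean of the target shell", {
  # hand-built two-direction case: voxel signals 100 and 400 average to 200
  s2 <- make_gradient_scheme(6, c(0, 800))   # 7 volumes
  dat <- array(1, c(1, 1, 1, 7))
  dat[1, 1, 1, 2:3] <- c(100, 400)
  dat[1, 1, 1, 4:7] <- 200
  dwi <- dwi_volume(dat, s2)
  sub <- dwi
  sub$data <- dwi$data[, , , 1:3, drop = FALSE]
  sub$scheme$b <- s2$b[1:3]
  sub$scheme$g <- s2$g[1:3, ]
  expect_equal(combined_dwi(sub, 800)[1, 1, 1], 200)
  # single direction at the target returns that image unchanged
  one <- dwi
  one$data <- dwi$data[, , , 1:2, drop = FALSE]
  one$scheme$b <- s2$b[1:2]
  one$scheme$g <- s2$g[1:2, ]
  expect_equal(combined_dwi(one, 800)[1, 1, 1], 100)
  # a zero contributing signal zeroes the voxel
  z <- sub
  z$data[1, 1, 1, 2] <- 0
  expect_equal(combined_dwi(z, 800)[1, 1, 1], 0)
  expect_error(combined_dwi(sub, 600), "missing shell")
})

test_that("combined DWI on a balanced scheme equals S0 exp(-b ADC)", {
  ev <- c(2.3, 1.6, 0.9) * 1e-3
  cfg <- phantom_config(grid_shape = c(2, 2, 1),
                        regions = list(tensor_region(ev, c(1, -1, 2))),
                        s0 = 1000, noise_sigma = 0)
  comb <- combined_dwi(simulate_dwi_phantom(cfg, scheme)$dwi, 800)
  expected <- 1000 * exp(-800 * mean(ev))
  expect_equal(as.vector(comb) / expected, rep(1, 4), tolerance = 1e-9)
})
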