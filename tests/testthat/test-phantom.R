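test_that("phantom signal follows the tensor model", {
  spec <- tiny_spec()
  ph <- make_phantom(spec)
  ctr <- round(spec$regions[[1]]$center)
  sig <- Re(ph$data[ctr[1], ctr[2], ctr[3], ])

  # b = 0 volumes equal the S0 map
  expect_equal(sig[spec$bvals == 0], rep(100, sum(spec$bvals == 0)))
  b0map <- Re(ph$data[, , , which(spec$bvals == 0)[1]])
  expect_true(all(b0map[!phantom_mask(spec)] == 0))

  # isotropic region: S0 * exp(-b d) for any direction
  d_iso <- spec$regions[[1]]$tensor[1, 1]
  expect_equal(sig, 100 * exp(-spec$bvals * d_iso), tolerance = 1e-12)

  # anisotropic tensor, gradient along principal axis: independent scalar
  # computation of the attenuation
  D <- diag(c(1.7, 0.3, 0.2))
  spec2 <- phantom_spec(grid_shape = c(8, 8, 8), shells = c(0, 2), n_dirs = c(1, 1),
                        regions = list(list(center = c(4, 4, 4), semiaxes = 3,
                                            S0 = 50, tensor = D)))
  spec2$dirs <- rbind(c(0, 0, 1), c(1, 0, 0))
  ph2 <- make_phantom(spec2)
  expect_equal(Re(ph2$data[4, 4, 4, 2]), 50 * exp(-2 * 1.7), tolerance = 1e-12)

  # signal non-increasing in b for fixed direction family
  ord <- order(spec$bvals)
  expect_true(all(diff(sig[ord]) <= 1e-12))
})

test_that("non-SPD region tensors are rejected", {
  bad <- list(list(center = c(4, 4, 4), semiaxes = 2, S0 = 10,
                   tensor = diag(c(1, -0.1, 0.5))))
  expect_error(phantom_spec(grid_shape = c(8, 8, 8), regions = bad),
               "positive definite")
})

test_that("coil sets are reproducible with valid channel covariance", {
  c1 <- make_coils(c(12, 12, 8), L = 8, seed = 42)
  c2 <- make_coils(c(12, 12, 8), L = 8, seed = 42)
  expect_identical(c1, c2)
  ev <- eigen(c1$channel_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > 0)
  expect_equal(c1$channel_cov, Conj(t(c1$channel_cov)))
  cu <- make_coils(c(12, 12, 8), uniform = TRUE)
  expect_true(all(cu$sens == 1 + 0i))
  expect_equal(cu$channel_cov, matrix(1, 1, 1))
})

test_that("phase corruption is unit-modulus and exactly invertible", {
  spec <- tiny_spec()
  ph <- make_phantom(spec)
  pc <- random_phase_corruption(spec$grid_shape, spec$bvals, seed = 7,
                                integer_harmonics = FALSE)
  phc <- corrupt_phase(ph, pc)
  expect_equal(Mod(phc$data), Mod(ph$data), tolerance = 1e-12)
  back <- demodulate(phc, pc)
  expect_equal(back$data, ph$data, tolerance = 1e-10)
  z <- zero_phase_corruption(spec$grid_shape, length(spec$bvals))
  expect_identical(corrupt_phase(ph, z)$data, ph$data)
})

test_that("k-space sampling is a unitary round trip and counts PF lines", {
  spec <- tiny_spec()
  ph <- make_phantom(spec)
  coils <- make_coils(spec$grid_shape, uniform = TRUE)
  kd <- sample_kspace(ph, coils, sampling_scheme("FULL"), noise_sigma = 0)
  y <- sense_reconstruct(kd)
  expect_equal(y$data, ph$data, tolerance = 1e-9)

  expect_length(acquired_lines(64, 1, 0.75, 1), 48)
  expect_error(sampling_scheme("FULL", pf_fraction = 0.75), "pf_fraction")
})

test_that("sampled channel noise has the prescribed covariance", {
  gs <- c(8, 8, 2)
  coils <- make_coils(gs, L = 4, seed = 1, rho = 0.4)
  x0 <- volume_stack(array(0 + 0i, c(gs, 100)))
  kd <- sample_kspace(x0, coils, sampling_scheme("FULL"), noise_sigma = 2, seed = 3)
  z <- matrix(aperm(kd$z, c(1, 2, 3, 5, 4)), ncol = 4) # samples x coils
  emp <- (t(Conj(z)) %*% z) / nrow(z)
  expect_equal(Re(emp), 4 * coils$channel_cov, tolerance = 0.05)
  expect_lt(max(abs(Im(emp))), 0.05 * 4)
})
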