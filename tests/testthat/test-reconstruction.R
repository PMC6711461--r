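test_that("channel whitening standardizes receiver noise", {
  # identity covariance: no-op
  z <- cmat(50, 3)
  expect_equal(whiten_channels(z, diag(3)), z)
  # single channel, variance 4: division by 2
  z1 <- cmat(50, 1)
  expect_equal(whiten_channels(z1, matrix(4, 1, 1)), z1 / 2)
  # empirical covariance of whitened draws -> identity
  set.seed(1)
  L <- 5
  cc <- 0.5^abs(outer(1:L, 1:L, `-`))
  w <- cmat(20000, L) %*% t(gsvs:::herm_sqrt(cc))
  wb <- whiten_channels(w, cc)
  emp <- (t(Conj(wb)) %*% wb) / nrow(wb)
  expect_lt(max(Mod(emp - diag(L))), 0.05)
  # singular covariance rejected with a conditioning diagnostic
  expect_error(channel_whitener(matrix(c(1, 1, 1, 1), 2, 2)), "singular")
})

test_that("noiseless reconstruction is exact for FULL and UNDER", {
  spec <- tiny_spec()
  ph <- make_phantom(spec)
  coils <- make_coils(spec$grid_shape, L = 8, seed = 2)
  kdF <- sample_kspace(ph, coils, sampling_scheme("FULL"), noise_sigma = 0)
  expect_equal(sense_reconstruct(kdF)$data, ph$data, tolerance = 1e-8)
  kdU <- sample_kspace(ph, coils, sampling_scheme("UNDER", U = 2), noise_sigma = 0)
  expect_equal(sense_reconstruct(kdU)$data, ph$data, tolerance = 1e-8)
})

test_that("noiseless HALF zero-fill reconstruction blurs within a bound", {
  spec <- tiny_spec()
  ph <- make_phantom(spec)
  coils <- make_coils(spec$grid_shape, L = 8, seed = 2)
  scH <- sampling_scheme("HALF", pf_fraction = 0.75, spectral_filter = "zero_fill")
  yH <- sense_reconstruct(sample_kspace(ph, coils, scH, noise_sigma = 0))
  rel <- sqrt(sum(Mod(yH$data - ph$data)^2) / sum(Mod(ph$data)^2))
  expect_lt(rel, 0.15) # documented PE-blurring bound for this smooth phantom
})

test_that("reconstruction is linear", {
  gs <- c(8, 8, 4)
  coils <- make_coils(gs, L = 4, seed = 5)
  sc <- sampling_scheme("UNDER", U = 2)
  x1 <- volume_stack(array(crandn(prod(gs) * 2), c(gs, 2)))
  x2 <- volume_stack(array(crandn(prod(gs) * 2), c(gs, 2)))
  k1 <- sample_kspace(x1, coils, sc, noise_sigma = 0)
  k2 <- sample_kspace(x2, coils, sc, noise_sigma = 0)
  ksum <- k1
  ksum$z <- k1$z + k2$z
  expect_equal(sense_reconstruct(ksum)$data,
               sense_reconstruct(k1)$data + sense_reconstruct(k2)$data,
               tolerance = 1e-12)
})

test_that("propagated FULL variance matches the sensitivity formula and MC", {
  gs <- c(10, 10, 4)
  coils <- make_coils(gs, L = 6, seed = 3)
  sc <- sampling_scheme("FULL")
  nm <- propagate_noise(coils, sc, noise_sigma = 2)
  # unit coil: variance sigma^2 everywhere
  cu <- make_coils(gs, uniform = TRUE)
  nmu <- propagate_noise(cu, sc, noise_sigma = 1)
  expect_equal(as.vector(nmu$variance_map), rep(1, prod(gs)), tolerance = 1e-12)
  # Monte-Carlo agreement within 3 standard errors of the MC variance
  ndr <- 3000
  x0 <- volume_stack(array(0 + 0i, c(gs, ndr)))
  y <- sense_reconstruct(sample_kspace(x0, coils, sc, noise_sigma = 2, seed = 9))
  vemp <- rowMeans(Mod(matrix(y$data, ncol = ndr))^2)
  se <- as.vector(nm$variance_map) / sqrt(ndr) # var of |n|^2 ~ sigma^4
  expect_true(all(abs(vemp - as.vector(nm$variance_map)) < 3.5 * se * sqrt(2)))
})

test_that("UNDER covariance satisfies the g-factor identity and matches MC", {
  gs <- c(12, 12, 4)
  coils <- make_coils(gs, L = 6, seed = 3)
  scF <- sampling_scheme("FULL")
  scU <- sampling_scheme("UNDER", U = 2)
  nmF <- propagate_noise(coils, scF, noise_sigma = 1)
  nmU <- propagate_noise(coils, scU, noise_sigma = 1)
  g <- g_factor_map(coils, scU)
  ratio <- sqrt(nmU$variance_map / nmF$variance_map)
  expect_equal(ratio, g * sqrt(2), tolerance = 1e-8)
  expect_true(all(g >= 1 - 1e-8))

  # off-diagonal covariance of an aliased pair vs Monte-Carlo
  ndr <- 4000
  x0 <- volume_stack(array(0 + 0i, c(gs, ndr)))
  yU <- sense_reconstruct(sample_kspace(x0, coils, scU, noise_sigma = 1, seed = 4))
  ym <- matrix(yU$data, ncol = ndr)
  pair <- gsvs:::linear_index(rbind(c(3, 2, 2), c(3, 8, 2)), gs)
  S <- marginalize_patch_cov(nmU, pair)$matrix
  emp <- (ym[pair, ] %*% Conj(t(ym[pair, ]))) / ndr
  se <- max(Mod(S)) / sqrt(ndr) * sqrt(2)
  expect_lt(max(Mod(emp - S)), 4 * se * sqrt(2))
})

test_that("patch marginalization respects regimes and member order", {
  gs <- c(12, 12, 4)
  coils <- make_coils(gs, L = 6, seed = 3)
  nmF <- propagate_noise(coils, sampling_scheme("FULL"))
  nmU <- propagate_noise(coils, sampling_scheme("UNDER", U = 2))
  members <- gsvs:::linear_index(cbind(4:9, 3, 2), gs)
  SF <- marginalize_patch_cov(nmF, members)$matrix
  expect_true(all(SF[row(SF) != col(SF)] == 0))
  expect_equal(Re(diag(SF)), nmF$variance_map[members])

  # patch without any aliased pair is diagonal under UNDER
  SU <- marginalize_patch_cov(nmU, members)$matrix
  expect_true(all(SU[row(SU) != col(SU)] == 0))
  # ... and a patch containing a full aliased pair is not
  pair <- gsvs:::linear_index(rbind(c(3, 2, 2), c(3, 8, 2)), gs)
  SP <- marginalize_patch_cov(nmU, pair)$matrix
  expect_gt(Mod(SP[1, 2]), 0)

  # permuting members permutes rows/columns consistently
  perm <- c(3, 1, 6, 2, 5, 4)
  SUp <- marginalize_patch_cov(nmU, members[perm])$matrix
  expect_equal(SUp, SU[perm, perm])
})

test_that("HALF analytic covariance agrees with Monte-Carlo propagation", {
  gs <- c(12, 12, 4)
  coils <- make_coils(gs, L = 6, seed = 3)
  scH <- sampling_scheme("HALF", pf_fraction = 0.75, spectral_filter = "ramp")
  nmA <- propagate_noise(coils, scH, noise_sigma = 1.5, method = "analytic")
  nmM <- propagate_noise(coils, scH, noise_sigma = 1.5, method = "monte_carlo",
                         n_draws = 4000, seed = 7)
  members <- gsvs:::linear_index(cbind(5, 3:8, 2), gs)
  Sa <- marginalize_patch_cov(nmA, members)$matrix
  Sm <- marginalize_patch_cov(nmM, members)$matrix
  expect_lt(max(Mod(Sa - Sm)) / max(Mod(Sa)), 0.12)
})

test_that("patch whitener standardizes patch noise", {
  # identity and diagonal shortcuts
  expect_equal(patch_whitener(diag(4) + 0i), diag(4) + 0i, tolerance = 1e-12)
  W <- patch_whitener(diag(c(4, 9, 16)) + 0i)
  expect_equal(Mod(diag(W)), c(1 / 2, 1 / 3, 1 / 4), tolerance = 1e-12)
  # whitened correlated draws have identity covariance
  set.seed(2)
  S <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  S <- S + 0i
  W <- patch_whitener(S)
  expect_equal(Conj(t(W)) %*% W %*% S, diag(6) + 0i, tolerance = 1e-8)
  X <- gsvs:::herm_sqrt(S) %*% matrix(crandn(6 * 20000), 6)
  Xw <- W %*% X
  emp <- (Xw %*% Conj(t(Xw))) / ncol(Xw)
  expect_lt(max(Mod(emp - diag(6))), 0.06)
})
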