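test_that("simulated white-noise spectra reach the Marcenko-Pastur edge", {
  esd <- simulate_esd(diag(1, 64) + 0i, M = 64, N = 128, B = 4, seed = 1)
  expect_equal(esd$edge / sqrt(128), 1 + sqrt(0.5), tolerance = 0.03)
  # scaling the covariance by c^2 scales every spectrum value by c
  esd2 <- simulate_esd(diag(4, 64) + 0i, M = 64, N = 128, B = 4, seed = 1)
  expect_equal(esd2$spectrum, 2 * esd$spectrum, tolerance = 1e-12)
  # determinism
  esd3 <- simulate_esd(diag(1, 64) + 0i, M = 64, N = 128, B = 4, seed = 1)
  expect_identical(esd$spectrum, esd3$spectrum)
  expect_error(simulate_esd(diag(c(1, -1)) + 0i, 2, 4), "positive semi-definite")
})

test_that("closed-form MP spectrum matches simulation and its limits", {
  # gamma = 1: support reaches [0, 2*sigma]
  cf1 <- mp_closed_form_esd(1, sigma = 3)
  expect_equal(cf1$edge, 6)
  expect_lt(min(cf1$spectrum), 0.2)
  # gamma -> 0: collapses toward sigma
  cf0 <- mp_closed_form_esd(0.001, sigma = 2)
  expect_lt(diff(range(cf0$spectrum)), 0.3)
  expect_equal(mean(cf0$spectrum), 2, tolerance = 0.01)
  # quantile agreement with a large simulated spectrum
  esd <- simulate_esd(diag(1, 64) + 0i, M = 64, N = 128, B = 4, seed = 1)
  cf <- mp_closed_form_esd(0.5, sigma = sqrt(128))
  qs <- quantile(esd$spectrum, c(.1, .25, .5, .75, .9))
  qc <- quantile(cf$spectrum, c(.1, .25, .5, .75, .9))
  expect_lt(max(abs(qs - qc) / qc), 0.05)
})

test_that("the D-transform has the stated analytic structure", {
  esd0 <- zero_esd(32, 0.5)
  x <- c(0.5, 1, 2, 7)
  expect_equal(d_transform(x, esd0), 1 / x^2, tolerance = 1e-12)
  cf <- mp_closed_form_esd(0.5)
  # x^2 * Df(x) -> 1 as x -> infinity
  expect_equal(1e4^2 * d_transform(1e4, cf), 1, tolerance = 1e-4)
  # analytic derivative matches central finite differences
  xs <- seq(cf$edge * 1.05, cf$edge * 3, length.out = 9)
  h <- 1e-5
  fd <- (d_transform(xs + h, cf) - d_transform(xs - h, cf)) / (2 * h)
  expect_equal(d_transform_deriv(xs, cf), fd, tolerance = 1e-6)
  # strictly negative above the edge
  expect_true(all(d_transform_deriv(xs, cf) < 0))
  expect_error(d_transform(cf$edge, cf), "edge")
})

test_that("shrinkage applies the two-branch rule", {
  # zero-noise spectrum: identity shrinker
  res0 <- shrink(c(5, 3, 1), zero_esd(16, 0.5))
  expect_equal(res0$eta_hat, c(5, 3, 1), tolerance = 1e-9)
  expect_equal(res0$rank, 3)
  # everything at or below the edge is fully suppressed
  cf <- mp_closed_form_esd(0.5)
  below <- sort(runif(8, 0, cf$edge), decreasing = TRUE)
  resb <- shrink(below, cf)
  expect_equal(resb$eta_hat, rep(0, 8))
  expect_equal(resb$rank, 0)
})

test_that("GSVS equals the white-noise optimal Frobenius shrinker", {
  for (g in c(0.25, 0.5, 0.85)) {
    cf <- mp_closed_form_esd(g)
    edge <- 1 + sqrt(g)
    ys <- seq(1.05 * edge, 4, length.out = 60)
    got <- rev(shrink(sort(ys, decreasing = TRUE), cf)$eta_hat)
    oracle <- sqrt((ys^2 - g - 1)^2 - 4 * g) / ys
    expect_lt(max(abs(got - oracle) / oracle), 0.01)
  }
})

test_that("shrinkage is contractive, monotone and scale equivariant", {
  set.seed(4)
  for (rep in 1:5) {
    M <- 24; N <- 40
    S <- crossprod(matrix(rnorm(M * M, sd = 0.4), M)) + diag(M)
    esd <- simulate_esd(S + 0i, M, N, B = 3, seed = rep)
    y <- sort(esd$edge * runif(M, 0.5, 3), decreasing = TRUE)
    res <- shrink(y, esd)
    expect_true(all(res$eta_hat <= y + 1e-9))
    keep <- y > esd$edge
    expect_true(!is.unsorted(rev(res$eta_hat[keep])))
    # scale equivariance: scale data and covariance by c
    c0 <- 2.5
    esd_c <- esd
    esd_c$spectrum <- c0 * esd$spectrum
    esd_c$edge <- c0 * esd$edge
    res_c <- shrink(c0 * y, esd_c)
    expect_equal(res_c$eta_hat, c0 * res$eta_hat, tolerance = 1e-9)
  }
})

test_that("AMSE estimates track the realized Frobenius error", {
  expect_equal(estimate_amse(c(1, 0.5), structure(list(eta_hat = c(0, 0), rank = 0L,
                                                       kept_indices = integer(0)),
                                                  class = "shrinkage_result"),
               mp_closed_form_esd(0.5)), 0)
  M <- 96; N <- 120
  est <- 0; realz <- 0
  for (s in 1:12) {
    set.seed(s)
    X <- planted(M, N, sqrt(N) * (1 + sqrt(M / N)) * seq(3, 5, length.out = 4))
    Y <- X + cmat(M, N)
    esd <- simulate_esd(diag(1, M) + 0i, M, N, B = 2, seed = 100 + s)
    sv <- svd(Y)
    res <- shrink(sv$d, esd)
    est <- est + estimate_amse(sv$d, res, esd)
    k <- res$kept_indices
    Xh <- sv$u[, k, drop = FALSE] %*% (res$eta_hat[k] * Conj(t(sv$v[, k, drop = FALSE])))
    realz <- realz + sum(Mod(Xh - X)^2)
  }
  expect_lt(abs(est / realz - 1), 0.15)
  # doubling the noise scale with fixed signal increases the estimated AMSE
  set.seed(99)
  X <- planted(M, N, sqrt(N) * (1 + sqrt(M / N)) * c(6, 5, 4))
  W <- cmat(M, N)
  am <- vapply(c(1, 2), function(s0) {
    esd <- simulate_esd(diag(s0^2, M) + 0i, M, N, B = 2, seed = 7)
    sv <- svd(X + s0 * W, nu = 0, nv = 0)$d
    res <- shrink(sv, esd)
    estimate_amse(sv, res, esd)
  }, numeric(1))
  expect_gt(am[2], am[1])
})

test_that("spiked-eigenvalue limits behave as predicted", {
  expect_equal(spiked_limit(4, 0.5), 14 / 3, tolerance = 1e-12)
  # gamma -> 0: no inflation
  expect_equal(spiked_limit(4, 1e-9), 4, tolerance = 1e-6)
  # positive bias for all gamma > 0
  g <- seq(0.05, 0.9, by = 0.1)
  expect_true(all(spiked_limit(4, g) > 4))
  expect_warning(spiked_limit(1.2, 0.5), "threshold")
})

test_that("rank recovery from well-separated spikes is reliable", {
  M <- 64; N <- 80
  hits <- 0
  n_trials <- 40
  for (s in seq_len(n_trials)) {
    set.seed(s)
    Y <- planted(M, N, 2 * sqrt(N) * (1 + sqrt(M / N)) * seq(1, 1.5, length.out = 5)) +
      cmat(M, N)
    esd <- simulate_esd(diag(1, M) + 0i, M, N, B = 2, seed = 2000 + s)
    if (shrink(svd(Y, nu = 0, nv = 0)$d, esd)$rank == 5) hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.95)
})
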