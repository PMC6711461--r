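test_that("spherical layouts have the documented geometry", {
  mask <- array(TRUE, c(16, 16, 16))
  # M = 7 on an isotropic grid: center plus its six face neighbors
  layout <- build_layout(mask, N = 10, gamma = 0.7, T = 4)
  expect_equal(layout$M, 7)
  ctr <- which(layout$centers == gsvs:::linear_index(matrix(c(9, 9, 9), 1), c(16, 16, 16)))
  mem <- layout$members[, ctr]
  ijk <- gsvs:::index_to_ijk(mem, c(16, 16, 16))
  off <- sweep(ijk, 2, c(9, 9, 9))
  expect_true(all(rowSums(abs(off)) <= 1))
  expect_equal(nrow(unique(off)), 7)

  # stride-T center count ~ Q / T^3 when patches reach the lattice gaps
  layout2 <- build_layout(mask, N = 48, gamma = 0.7, T = 2)
  expect_lt(abs(length(layout2$centers) - 16^3 / 8) / (16^3 / 8), 0.3)

  # T = 1: every FOV voxel is a center
  small <- array(TRUE, c(6, 6, 6))
  layout3 <- build_layout(small, N = 10, gamma = 0.5, T = 1)
  expect_setequal(layout3$centers, seq_len(216))

  expect_error(build_layout(small, N = 300, gamma = 1, T = 1), "exceeds")
})

test_that("every FOV voxel is covered and member lists are distance-ordered", {
  spec <- tiny_spec()
  mask <- phantom_mask(spec)
  layout <- build_layout(mask, N = 12, gamma = 0.6, T = 2)
  covered <- logical(prod(dim(mask)))
  covered[layout$members] <- TRUE
  expect_true(all(covered[which(mask)]))
  # brute-force check of distance ordering for a few patches
  dims <- dim(mask)
  for (p in c(1, 5, length(layout$centers))) {
    cijk <- gsvs:::index_to_ijk(layout$centers[p], dims)
    mijk <- gsvs:::index_to_ijk(layout$members[, p], dims)
    d <- sqrt(rowSums(sweep(mijk, 2, as.vector(cijk))^2))
    expect_true(!is.unsorted(d))
    expect_equal(d, layout$dists[, p], tolerance = 1e-12)
    expect_equal(length(unique(layout$members[, p])), layout$M)
    # members are the M closest in-FOV voxels (set equality with brute force)
    allfov <- which(mask)
    aijk <- gsvs:::index_to_ijk(allfov, dims)
    ad <- sqrt(rowSums(sweep(aijk, 2, as.vector(cijk))^2))
    kth <- sort(ad)[layout$M]
    expect_true(all(d <= kth + 1e-12))
  }
})

test_that("extraction and identity scatter-back reproduce the input", {
  mask <- array(TRUE, c(8, 8, 4))
  N <- 6
  y <- array(crandn(prod(dim(mask)) * N), c(dim(mask), N))
  ym <- matrix(y, ncol = N)
  layout <- build_layout(mask, N, gamma = 1.2, T = 1)
  ests <- lapply(seq_along(layout$centers), function(p) extract_patch(ym, layout, p))
  for (scheme in c("uniform", "gaussian", "nearest")) {
    asm <- assemble_patches(ests, layout, N, scheme = scheme)
    expect_equal(asm$data, y, tolerance = 1e-12)
  }
  # constant volumes give a rank-1 patch matrix
  yc <- matrix(rep(complex(real = 1:N), each = prod(dim(mask))), ncol = N)
  d <- svd(extract_patch(yc, layout, 3), nu = 0, nv = 0)$d
  expect_lt(d[2] / d[1], 1e-12)
})

test_that("assembly weights form a partition of unity", {
  mask <- array(TRUE, c(10, 10, 6))
  N <- 8
  layout <- build_layout(mask, N, gamma = 1, T = 2)
  np <- length(layout$centers)
  ones <- lapply(seq_len(np), function(p) matrix(1 + 0i, layout$M, N))
  for (scheme in c("uniform", "gaussian", "inverse_variance")) {
    asm <- assemble_patches(ones, layout, N, scheme = scheme,
                            amse = seq_len(np) * 0.1)
    expect_equal(Re(asm$data), array(1, c(dim(mask), N)), tolerance = 1e-12)
  }
})

test_that("inverse-variance assembly downweights a corrupted patch", {
  mask <- array(TRUE, c(6, 6, 6))
  N <- 4
  layout <- build_layout(mask, N, gamma = 4, T = 3) # M = 16, few patches
  np <- length(layout$centers)
  truthv <- matrix(1 + 0i, layout$M, N)
  ests <- lapply(seq_len(np), function(p) truthv)
  amse <- rep(0.1, np)
  ests[[1]] <- truthv + 5 # deliberately corrupted estimate
  amse[1] <- 50
  a_u <- assemble_patches(ests, layout, N, scheme = "uniform")
  a_iv <- assemble_patches(ests, layout, N, scheme = "inverse_variance", amse = amse)
  err_u <- mean(Mod(a_u$data - 1)^2)
  err_iv <- mean(Mod(a_iv$data - 1)^2)
  expect_lt(err_iv, err_u)
})

test_that("assembled output is invariant to patch processing order", {
  mask <- array(TRUE, c(8, 8, 4))
  N <- 5
  y <- array(crandn(prod(dim(mask)) * N), c(dim(mask), N))
  ym <- matrix(y, ncol = N)
  layout <- build_layout(mask, N, gamma = 2, T = 2)
  ests <- lapply(seq_along(layout$centers), function(p) extract_patch(ym, layout, p))
  a1 <- assemble_patches(ests, layout, N, scheme = "gaussian")
  perm <- rev(seq_along(ests))
  layout_r <- layout
  layout_r$centers <- layout$centers[perm]
  layout_r$members <- layout$members[, perm, drop = FALSE]
  layout_r$dists <- layout$dists[, perm, drop = FALSE]
  a2 <- assemble_patches(ests[perm], layout_r, N, scheme = "gaussian")
  expect_equal(a1$data, a2$data, tolerance = 1e-10)
})
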