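# Image-domain noise models induced by linear SENSE reconstruction, their
# per-patch marginalization, and patch whitening.

#' Propagate channel noise through the reconstruction
#'
#' Builds the image-domain noise model of [sense_reconstruct()] for a given
#' coil set and sampling scheme, per unit `noise_sigma` of acquired-sample
#' noise. FULL gives a per-voxel variance map sigma^2/(sbar^H sbar); UNDER
#' gives the U x U covariance sigma^2 * U * (SbarU^H SbarU)^{-1} per aliased
#' set; HALF (U = 1) admits an analytic per-PE-column operator including the
#' spectral filter G; HALF with U > 1 and INTER default to the Monte-Carlo
#' path, where noise-only draws are pushed through the actual reconstruction
#' and patch covariances are sample covariances of the draws.
#'
#' @param coils a `coil_set`
#' @param scheme a [sampling_scheme()]
#' @param noise_sigma noise standard deviation per acquired complex sample
#' @param method "analytic" or "monte_carlo"; defaults to analytic for
#'   FULL/UNDER and for HALF with U = 1, Monte-Carlo otherwise
#' @param n_draws number of Monte-Carlo noise draws per encoding
#' @param seed seed for the Monte-Carlo draws
#' @return object of class `noise_model`
#' @export
propagate_noise <- function(coils, scheme, noise_sigma = 1,
                            method = NULL, n_draws = 2000, seed = 1L) {
  stopifnot(inherits(coils, "coil_set"), inherits(scheme, "sampling_scheme"))
  gs <- coils$grid_shape
  if (is.null(method)) {
    method <- if (scheme$mode %in% c("FULL", "UNDER") ||
                  (scheme$mode == "HALF" && scheme$U == 1L)) "analytic" else "monte_carlo"
  }
  method <- match.arg(method, c("analytic", "monte_carlo"))
  nm <- structure(list(regime = scheme$mode, sigma = noise_sigma, method = method,
                       scheme = scheme, grid_shape = gs),
                  class = "noise_model")
  if (method == "monte_carlo") {
    nm$mc <- lapply(seq_along(scheme$encodings), function(a)
      .noise_draws(coils, scheme, a, n_draws, noise_sigma, derive_seed(seed, a)))
    nm$variance_map <- array(Re(colMeans(abs(nm$mc[[1]])^2)), gs)
    return(nm)
  }
  sflat <- .whitened_sens_matrix(coils)
  if (scheme$mode == "FULL") {
    den <- rowSums(abs(sflat)^2)
    den[den <= 1e-12 * max(den)] <- NA_real_
    nm$variance_map <- array(noise_sigma^2 / den, gs)
  } else if (scheme$mode == "UNDER") {
    nm$under <- .under_cov(sflat, gs, scheme$U, scheme$encodings[[1]]$pe_axis, noise_sigma)
    nm$variance_map <- nm$under$variance_map
  } else if (scheme$mode %in% c("HALF", "INTER")) {
    if (scheme$U != 1L)
      stop("analytic covariance for partial-Fourier schemes requires U = 1; use method = 'monte_carlo'")
    nm$half <- lapply(scheme$encodings, function(enc)
      .half_analytic(sflat, gs, scheme, enc, noise_sigma))
    nm$variance_map <- nm$half[[1]]$variance_map
  }
  nm
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> regime %s (%s), sigma = %g\n", x$regime, x$method, x$sigma))
  invisible(x)
}

# Monte-Carlo: reconstruct n_draws independent noise-only "volumes" for one
# encoding; returns (n_draws x Q) complex matrix of reconstructed noise.
.noise_draws <- function(coils, scheme, enc_index, n_draws, noise_sigma, seed) {
  gs <- coils$grid_shape
  one <- sampling_scheme(mode = if (scheme$pf_fraction < 1) "HALF" else
                           if (scheme$U > 1) "UNDER" else "FULL",
                         U = scheme$U, pf_fraction = scheme$pf_fraction,
                         pe_axis = scheme$encodings[[enc_index]]$pe_axis,
                         pf_side = scheme$encodings[[enc_index]]$pf_side,
                         spectral_filter = scheme$spectral_filter)
  x0 <- volume_stack(array(0 + 0i, c(gs, n_draws)))
  kd <- sample_kspace(x0, coils, one, noise_sigma = noise_sigma, seed = seed)
  y <- sense_reconstruct(kd)
  t(matrix(y$data, nrow = prod(gs)))
}

# Analytic UNDER covariance: per aliased set along the PE axis,
# sigma^2 * U * (SbarU^H SbarU)^{-1}, stored in PE-first layout.
.under_cov <- function(sflat, gs, U, axis, noise_sigma) {
  L <- ncol(sflat)
  na <- gs[axis]
  if (na %% U != 0) stop("PE axis length must be divisible by U")
  K <- na %/% U
  others <- setdiff(1:3, axis)
  pord <- c(axis, others)
  sp <- aperm(array(sflat, c(gs, L)), c(pord, 4L))
  m1 <- gs[others[1]]; m2 <- gs[others[2]]
  Kp <- K * m1 * m2
  Bm <- lapply(seq_len(U) - 1L, function(uu)
    matrix(sp[uu * K + seq_len(K), , , , drop = FALSE], nrow = Kp))
  cov <- array(0 + 0i, c(U, U, Kp))
  for (s in seq_len(Kp)) {
    A <- matrix(vapply(seq_len(U), function(uu) Bm[[uu]][s, ], complex(L)), nrow = L)
    H <- Conj(t(A)) %*% A
    cov[, , s] <- noise_sigma^2 * U * solve(H)
  }
  # scatter diagonal entries back to voxel order
  vp <- array(0, c(na, m1, m2))
  for (uu in seq_len(U))
    vp[(uu - 1L) * K + seq_len(K), , ] <- array(Re(cov[uu, uu, ]), c(K, m1, m2))
  variance_map <- aperm(vp, match(1:3, pord))
  list(axis = axis, U = U, K = K, pord = pord, m1 = m1, m2 = m2,
       cov = cov, variance_map = variance_map)
}

# Analytic HALF (U = 1): noise is independent across readout and slice and
# correlated along the PE axis; per-column covariance
#   Lambda_col = G W C W^H G^H
# with C the acquired-line autocovariance kernel, W the diagonal coil-combine
# weights along the column and G the (dense) spectral filter operator.
.half_analytic <- function(sflat, gs, scheme, enc, noise_sigma) {
  axis <- enc$pe_axis
  na <- gs[axis]
  acq <- acquired_lines(na, scheme$U, scheme$pf_fraction, enc$pf_side)
  # autocovariance of zero-filled unitary IDFT noise along PE
  dk <- outer(seq_len(na), seq_len(na), `-`)
  Cker <- matrix(0 + 0i, na, na)
  for (k in acq) Cker <- Cker + exp(2i * pi * k * dk / na)
  Cker <- Cker / na * noise_sigma^2
  g <- pf_filter_taps(na, scheme$pf_fraction, enc$pf_side, scheme$spectral_filter)
  Gop <- if (scheme$spectral_filter == "none") NULL else {
    Fm <- cfft1_matrix(na)
    Conj(t(Fm)) %*% (g * Fm)
  }
  den <- rowSums(abs(sflat)^2)
  den[den <= 1e-12 * max(den)] <- NA_real_
  wts <- Conj(sflat) / den # Q x L combine weights
  L <- ncol(sflat)
  others <- setdiff(1:3, axis)
  col_cov <- function(i1, i2) {
    # covariance of the PE column at (other1 = i1, other2 = i2)
    idx <- integer(na)
    ijk <- matrix(1L, na, 3)
    ijk[, axis] <- seq_len(na)
    ijk[, others[1]] <- i1
    ijk[, others[2]] <- i2
    idx <- linear_index(ijk, gs)
    wcol <- wts[idx, , drop = FALSE]
    M0 <- (wcol %*% Conj(t(wcol))) * Cker
    if (!is.null(Gop)) M0 <- Gop %*% M0 %*% Conj(t(Gop))
    M0
  }
  # variance map from column diagonals
  vm <- array(NA_real_, gs)
  for (i2 in seq_len(gs[others[2]])) for (i1 in seq_len(gs[others[1]])) {
    dg <- Re(diag(col_cov(i1, i2)))
    ijk <- matrix(1L, na, 3)
    ijk[, axis] <- seq_len(na); ijk[, others[1]] <- i1; ijk[, others[2]] <- i2
    vm[linear_index(ijk, gs)] <- dg
  }
  list(axis = axis, others = others, col_cov = col_cov, variance_map = vm)
}

#' g-factor map of an undersampled acquisition
#'
#' Independent computation of the SENSE geometry factor from the whitened
#' sensitivities: g_q = sqrt([(SbarU^H SbarU)^{-1}]_uu [SbarU^H SbarU]_uu).
#'
#' @param coils a `coil_set`
#' @param scheme an UNDER [sampling_scheme()]
#' @return 3D array of g-factors
#' @export
g_factor_map <- function(coils, scheme) {
  stopifnot(scheme$mode == "UNDER")
  gs <- coils$grid_shape
  sflat <- .whitened_sens_matrix(coils)
  axis <- scheme$encodings[[1]]$pe_axis
  U <- scheme$U; na <- gs[axis]; K <- na %/% U
  others <- setdiff(1:3, axis)
  pord <- c(axis, others)
  L <- ncol(sflat)
  sp <- aperm(array(sflat, c(gs, L)), c(pord, 4L))
  m1 <- gs[others[1]]; m2 <- gs[others[2]]
  Kp <- K * m1 * m2
  Bm <- lapply(seq_len(U) - 1L, function(uu)
    matrix(sp[uu * K + seq_len(K), , , , drop = FALSE], nrow = Kp))
  gp <- array(NA_real_, c(na, m1, m2))
  gmat <- matrix(NA_real_, Kp, U)
  for (s in seq_len(Kp)) {
    A <- matrix(vapply(seq_len(U), function(uu) Bm[[uu]][s, ], complex(L)), nrow = L)
    H <- Conj(t(A)) %*% A
    Hi <- solve(H)
    gmat[s, ] <- sqrt(Re(diag(Hi)) * Re(diag(H)))
  }
  for (uu in seq_len(U))
    gp[(uu - 1L) * K + seq_len(K), , ] <- array(gmat[, uu], c(K, m1, m2))
  aperm(gp, match(1:3, pord))
}

#' Marginalize a noise model onto a patch
#'
#' Restricts the image-domain noise covariance to the patch's member voxels,
#' in member order. Stationary regimes give one M x M Hermitian matrix; INTER
#' gives one matrix per encoding plus the volume grouping.
#'
#' @param nm a `noise_model`
#' @param members integer vector of member voxel linear indices (patch order)
#' @return object of class `patch_covariance`: either `matrix` (stationary)
#'   or `matrices` + `groups_needed = TRUE` (per-encoding family)
#' @export
marginalize_patch_cov <- function(nm, members) {
  stopifnot(inherits(nm, "noise_model"))
  M <- length(members)
  gs <- nm$grid_shape
  mk <- function(mat) structure(list(matrix = mat, members = members, regime = nm$regime),
                                class = "patch_covariance")
  if (nm$method == "monte_carlo") {
    mats <- lapply(nm$mc, function(D) {
      Dm <- D[, members, drop = FALSE]
      S <- (t(Dm) %*% Conj(Dm)) / nrow(Dm)
      (S + Conj(t(S))) / 2
    })
    if (nm$regime == "INTER")
      return(structure(list(matrices = mats, members = members, regime = nm$regime),
                       class = "patch_covariance"))
    return(mk(mats[[1]]))
  }
  if (nm$regime == "FULL") {
    v <- nm$variance_map[members]
    if (anyNA(v)) stop("patch contains voxels outside the coil FOV")
    return(mk(diag(v, nrow = M) + 0i))
  }
  if (nm$regime == "UNDER") {
    un <- nm$under
    ijk <- index_to_ijk(members, gs)
    pe <- ijk[, un$axis]
    o1 <- ijk[, un$pord[2]]; o2 <- ijk[, un$pord[3]]
    j <- ((pe - 1L) %% un$K) + 1L       # set representative along PE
    uu <- ((pe - 1L) %/% un$K) + 1L     # replica index within set
    sid <- (o2 - 1L) * un$m1 * un$K + (o1 - 1L) * un$K + j # flat set id
    S <- matrix(0 + 0i, M, M)
    for (i in seq_len(M)) for (l in i:M) {
      if (sid[i] == sid[l]) {
        S[i, l] <- un$cov[uu[i], uu[l], sid[i]]
        S[l, i] <- Conj(S[i, l])
      }
    }
    return(mk(S))
  }
  # analytic HALF / INTER: correlation only within PE columns
  mats <- lapply(nm$half, function(h) {
    ijk <- index_to_ijk(members, gs)
    pe <- ijk[, h$axis]
    o1 <- ijk[, h$others[1]]; o2 <- ijk[, h$others[2]]
    colid <- paste(o1, o2)
    S <- matrix(0 + 0i, M, M)
    for (cid in unique(colid)) {
      w <- which(colid == cid)
      cc <- h$col_cov(o1[w[1]], o2[w[1]])
      S[w, w] <- cc[pe[w], pe[w], drop = FALSE]
    }
    (S + Conj(t(S))) / 2
  })
  if (nm$regime == "INTER")
    return(structure(list(matrices = mats, members = members, regime = nm$regime),
                     class = "patch_covariance"))
  mk(mats[[1]])
}

#' Patch whitening transform
#'
#' Returns Y_M with Y_M^H Y_M = Sigma_M^{-1} for a stationary patch
#' covariance, via eigendecomposition with a relative eigenvalue floor of
#' 1e-8 (floored eigenvalues are reported with a message).
#'
#' @param pc a stationary `patch_covariance` (or bare Hermitian matrix)
#' @return M x M whitening matrix
#' @export
patch_whitener <- function(pc) {
  S <- if (inherits(pc, "patch_covariance")) {
    if (is.null(pc$matrix)) stop("patch whitening requires a stationary (single-matrix) covariance")
    pc$matrix
  } else pc
  if (all(S[row(S) != col(S)] == 0)) {
    v <- Re(diag(S))
    fl <- 1e-8 * max(v)
    if (any(v < fl)) {
      message(sprintf("patch covariance: %d eigenvalue(s) floored at %.3g", sum(v < fl), fl))
      v <- pmax(v, fl)
    }
    return(diag(1 / sqrt(v), nrow = length(v)) + 0i)
  }
  e <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
  lam <- Re(e$values)
  fl <- 1e-8 * max(lam)
  if (any(lam < fl)) {
    message(sprintf("patch covariance: %d eigenvalue(s) floored at %.3g", sum(lam < fl), fl))
    lam <- pmax(lam, fl)
  }
  (1 / sqrt(lam)) * Conj(t(e$vectors))
}
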