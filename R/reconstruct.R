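# Linear SENSE reconstruction and exact propagation of the channel noise
# covariance into image-domain noise models.
#
# Convention (documented in the methods vignette): k-space is indexed on the
# full reconstruction grid with the centered unitary in-plane DFT, and noise
# lives on the *acquired* samples with covariance sigma^2 * Lambda_z. Under
# this sample-referenced convention the aliased-set covariance of a U-fold
# undersampled reconstruction is sigma^2 * U * (SbarU^H SbarU)^{-1}, and the
# ratio of undersampled to fully-sampled voxel noise equals the g-factor
# times sqrt(U), voxelwise.

#' Whitening transform of the channel noise covariance
#'
#' Returns the Hermitian matrix Y with Y^H Y = Lambda_z^{-1} (inverse
#' symmetric square root), used to decorrelate and standardize receiver
#' noise.
#'
#' @param channel_cov L x L Hermitian positive-definite covariance
#' @return L x L whitening matrix
#' @export
channel_whitener <- function(channel_cov) {
  e <- eigen((channel_cov + Conj(t(channel_cov))) / 2, symmetric = TRUE)
  lam <- Re(e$values)
  if (min(lam) <= 1e-12 * max(lam))
    stop(sprintf("channel covariance is numerically singular (condition number %.3g)",
                 max(lam) / max(min(lam), .Machine$double.xmin)))
  e$vectors %*% ((1 / sqrt(lam)) * Conj(t(e$vectors)))
}

#' Whiten multi-channel k-space data
#'
#' Applies the channel whitening transform along the coil dimension so the
#' whitened channel noise covariance is the identity.
#'
#' @param z complex array with the coil dimension fourth, dims (X,Y,Z,L) or
#'   (X,Y,Z,L,N), or a (samples x L) matrix
#' @param channel_cov L x L Hermitian positive-definite channel covariance
#' @return whitened data of the same shape
#' @export
whiten_channels <- function(z, channel_cov) {
  W <- channel_whitener(channel_cov)
  d <- dim(z)
  if (is.null(d) || length(d) == 2) {
    z <- as.matrix(z)
    return(z %*% t(W)) # rows are samples: w_new = W w
  }
  L <- ncol(W)
  stopifnot(d[4] == L)
  perm <- c(4L, setdiff(seq_along(d), 4L))
  zp <- aperm(z, perm)
  zp <- array(W %*% matrix(zp, nrow = L), dim(zp))
  aperm(zp, order(perm))
}

# whitened sensitivities, flattened to (Q x L)
.whitened_sens_matrix <- function(coils) {
  W <- channel_whitener(coils$channel_cov)
  matrix(coils$sens, ncol = coils$n_coils) %*% t(W)
}

#' Partial-Fourier spectral filter taps
#'
#' Taps of the filter G on the centered PE frequency grid. `zero_fill` is the
#' indicator of acquired lines; `ramp` is the homodyne-style weighting: 0 on
#' the omitted band, rising linearly from 0 to 2 across the symmetrically
#' sampled band (weight 1 at DC), and 2 on the asymmetric-only band.
#'
#' @param n PE axis length
#' @param pf_fraction acquired fraction of PE lines
#' @param pf_side +1 if the most-negative frequencies are omitted, -1 otherwise
#' @param type filter type
#' @return numeric tap vector of length n
#' @export
pf_filter_taps <- function(n, pf_fraction, pf_side, type = c("none", "zero_fill", "ramp")) {
  type <- match.arg(type)
  k <- centered_freqs(n)
  if (type == "none" || pf_fraction >= 1) return(rep(1, n))
  lim <- (pf_fraction - 0.5) * n
  acq <- if (pf_side >= 0) k >= -lim else k <= lim
  if (type == "zero_fill") return(as.numeric(acq))
  ks <- if (pf_side >= 0) k else -k
  w <- ifelse(ks > lim, 2, pmax(0, 1 + ks / lim))
  w * as.numeric(acq)
}

# multiply array by a vector broadcast along dimension `dim`
.mul_along <- function(x, dim, v) {
  idx <- slice.index(x, dim)
  x * v[idx]
}

# Unfold one encoding for a batch of volumes.
#   u: per-coil aliased images, dims (X, Y, Z, L, Ng) (zero-filled IDFT output)
#   sflat: whitened sensitivities (Q x L)
# Returns list(y = (X,Y,Z,Ng), bad = logical Q of rank-deficient voxels).
.unfold <- function(u, sflat, gs, L, U, axis) {
  Q <- prod(gs); Ng <- dim(u)[5]
  if (U == 1L) {
    den <- rowSums(abs(sflat)^2)
    bad <- den <= 1e-12 * max(den)
    den[bad] <- 1
    um <- matrix(u, nrow = Q) # columns: (l, n) with l fastest
    num <- matrix(0 + 0i, Q, Ng)
    for (l in seq_len(L))
      num <- num + Conj(sflat[, l]) * um[, (seq_len(Ng) - 1L) * L + l, drop = FALSE]
    y <- num / den
    y[bad, ] <- 0
    return(list(y = array(y, c(gs, Ng)), bad = bad))
  }
  na <- gs[axis]
  if (na %% U != 0) stop("PE axis length must be divisible by U")
  K <- na %/% U
  others <- setdiff(1:3, axis)
  pord <- c(axis, others)
  up <- aperm(u, c(pord, 4L, 5L))                  # (na, m1, m2, L, Ng)
  sp <- aperm(array(sflat, c(gs, L)), c(pord, 4L)) # (na, m1, m2, L)
  m1 <- gs[others[1]]; m2 <- gs[others[2]]
  Kp <- K * m1 * m2
  # set-representative flattening: rows j = 1..K along PE, then m1, m2
  Bm <- lapply(seq_len(U) - 1L, function(uu) {
    matrix(sp[uu * K + seq_len(K), , , , drop = FALSE], nrow = Kp) / U
  })
  ufm <- array(up[seq_len(K), , , , , drop = FALSE], c(Kp, L, Ng))
  xs <- vector("list", U) # per-replica estimates, each (Kp x Ng)
  if (U == 2L) {
    a <- rowSums(abs(Bm[[1]])^2)
    d2 <- rowSums(abs(Bm[[2]])^2)
    b <- rowSums(Conj(Bm[[1]]) * Bm[[2]])
    det <- a * d2 - abs(b)^2
    bads <- Mod(det) <= 1e-12 * pmax(a * d2, 1e-300)
    det[bads] <- 1
    x1 <- matrix(0 + 0i, Kp, Ng); x2 <- x1
    for (n in seq_len(Ng)) {
      r1 <- rowSums(Conj(Bm[[1]]) * ufm[, , n])
      r2 <- rowSums(Conj(Bm[[2]]) * ufm[, , n])
      x1[, n] <- (d2 * r1 - b * r2) / det
      x2[, n] <- (a * r2 - Conj(b) * r1) / det
    }
    x1[bads, ] <- 0; x2[bads, ] <- 0
    xs[[1]] <- x1; xs[[2]] <- x2
  } else {
    bads <- logical(Kp)
    for (uu in seq_len(U)) xs[[uu]] <- matrix(0 + 0i, Kp, Ng)
    for (s in seq_len(Kp)) {
      A <- vapply(seq_len(U), function(uu) Bm[[uu]][s, ], complex(L))
      A <- matrix(A, nrow = L)
      H <- Conj(t(A)) %*% A
      if (Mod(det(H)) <= 1e-12 * max(Mod(diag(H)), 1e-300)^U) {
        bads[s] <- TRUE
        next
      }
      xv <- solve(H, Conj(t(A)) %*% ufm[s, , ])
      for (uu in seq_len(U)) xs[[uu]][s, ] <- xv[uu, ]
    }
  }
  xp <- array(0 + 0i, c(na, m1, m2, Ng))
  badp <- array(FALSE, c(na, m1, m2))
  for (uu in seq_len(U)) {
    xp[(uu - 1L) * K + seq_len(K), , , ] <- array(xs[[uu]], c(K, m1, m2, Ng))
    badp[(uu - 1L) * K + seq_len(K), , ] <- array(bads, c(K, m1, m2))
  }
  iperm <- match(1:3, pord)
  list(y = aperm(xp, c(iperm, 4L)), bad = as.vector(aperm(badp, iperm)))
}

#' Linear SENSE reconstruction of sampled k-space
#'
#' Channel-whitens the data and sensitivities, zero-fills unacquired lines,
#' applies the centered unitary inverse in-plane DFT, unfolds the U aliased
#' voxels of each set by least squares, and (for partial-Fourier schemes)
#' applies the spectral filter G along the PE axis. Volumes of an interleaved
#' acquisition are reconstructed per encoding group.
#'
#' @param kdata a `kspace_data` object from [sample_kspace()]
#' @return a [volume_stack()] with attribute `fov_excluded` flagging voxels
#'   whose aliased set was rank deficient
#' @export
sense_reconstruct <- function(kdata) {
  stopifnot(inherits(kdata, "kspace_data"))
  coils <- kdata$coils; scheme <- kdata$scheme
  d <- dim(kdata$z); gs <- d[1:3]; L <- d[4]; N <- d[5]
  zb <- whiten_channels(kdata$z, coils$channel_cov)
  sflat <- .whitened_sens_matrix(coils)
  u <- cfft2(zb, inverse = TRUE)
  y <- array(0 + 0i, c(gs, N))
  bad <- rep(FALSE, prod(gs))
  for (a in seq_along(scheme$encodings)) {
    vols <- which(kdata$groups == a)
    if (!length(vols)) next
    enc <- scheme$encodings[[a]]
    ua <- u[, , , , vols, drop = FALSE]
    res <- .unfold(ua, sflat, gs, L, scheme$U, enc$pe_axis)
    ya <- res$y
    if (scheme$spectral_filter != "none" && scheme$pf_fraction < 1) {
      g <- pf_filter_taps(gs[enc$pe_axis], scheme$pf_fraction, enc$pf_side,
                          scheme$spectral_filter)
      ka <- cfft1(ya, dim = enc$pe_axis)
      ka <- .mul_along(ka, enc$pe_axis, g)
      ya <- cfft1(ka, dim = enc$pe_axis, inverse = TRUE)
    }
    y[, , , vols] <- ya
    bad <- bad | res$bad
  }
  out <- volume_stack(y, bvals = kdata$bvals, dirs = kdata$dirs,
                      voxel_size = kdata$voxel_size,
                      pe_group = if (scheme$mode == "INTER") kdata$groups else NULL)
  attr(out, "fov_excluded") <- array(bad, gs)
  out
}
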