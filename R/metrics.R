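# Image quality metrics: PSNR against a known ground truth, and a
# Gaussian-window structural similarity index on magnitude volumes.

#' Peak signal-to-noise ratio
#'
#' 10*log10(peak^2 / MSE) with peak the maximum ground-truth magnitude over
#' the mask and MSE the mean squared complex deviation. A zero-MSE input is
#' reported as the 300 dB cap.
#'
#' @param est,truth [volume_stack()]s or complex arrays of equal dimension
#' @param mask optional logical 3D array restricting the evaluation
#' @param per_shell if TRUE and b-values are available, also return PSNR per
#'   b-shell
#' @return overall PSNR in dB, or a list with `overall` and `per_shell`
#' @export
psnr <- function(est, truth, mask = NULL, per_shell = FALSE) {
  bvals <- if (inherits(truth, "volume_stack")) truth$bvals else NULL
  e <- if (inherits(est, "volume_stack")) est$data else est
  x <- if (inherits(truth, "volume_stack")) truth$data else truth
  stopifnot(all(dim(e) == dim(x)))
  d <- dim(x)
  sel <- if (is.null(mask)) rep(TRUE, prod(d[1:3])) else as.vector(mask)
  em <- matrix(e, ncol = d[4])[sel, , drop = FALSE]
  xm <- matrix(x, ncol = d[4])[sel, , drop = FALSE]
  peak <- max(Mod(xm))
  one <- function(cols) {
    mse <- mean(Mod(em[, cols, drop = FALSE] - xm[, cols, drop = FALSE])^2)
    if (mse == 0) 300 else min(10 * log10(peak^2 / mse), 300)
  }
  overall <- one(seq_len(d[4]))
  if (!per_shell || is.null(bvals)) return(overall)
  shells <- sort(unique(bvals))
  ps <- vapply(shells, function(b) one(which(bvals == b)), numeric(1))
  names(ps) <- paste0("b", shells)
  list(overall = overall, per_shell = ps)
}

# separable Gaussian smoothing along the 3 spatial dims with renormalized
# (mass-preserving) edge handling
.gauss_smooth3 <- function(x, sigma = 1.5, half = 3L) {
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  d <- dim(x)
  ones <- array(1, d)
  conv1 <- function(a, dim) {
    out <- array(0, dim(a))
    for (t in (-half):half) {
      src <- seq_len(d[dim]) + t
      ok <- src >= 1 & src <= d[dim]
      w <- k[t + half + 1]
      sl_dst <- which(ok)
      sl_src <- src[ok]
      args_dst <- rep(list(quote(expr = )), 3); args_dst[[dim]] <- sl_dst
      args_src <- rep(list(quote(expr = )), 3); args_src[[dim]] <- sl_src
      piece <- do.call(`[`, c(list(a), args_src, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(out), args_dst, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), args_dst, list(value = cur + w * piece)))
    }
    out
  }
  num <- x; den <- ones
  for (dim in 1:3) {
    num <- conv1(num, dim)
    den <- conv1(den, dim)
  }
  num / den
}

#' Structural similarity index on magnitude volumes
#'
#' Mean SSIM over the (masked) grid, computed per volume on magnitudes and
#' averaged. Local statistics use a separable Gaussian window (sd 1.5 voxels,
#' 7-voxel support); stabilizers C1 = (0.01 * data_range)^2 and
#' C2 = (0.03 * data_range)^2 with data_range the larger of the two
#' magnitude ranges, which makes the metric exactly symmetric in its
#' arguments.
#'
#' @param est,truth [volume_stack()]s or arrays of equal dimension
#' @param mask optional logical 3D array
#' @return mean SSIM in [-1, 1]
#' @export
ssim <- function(est, truth, mask = NULL) {
  e <- if (inherits(est, "volume_stack")) est$data else est
  x <- if (inherits(truth, "volume_stack")) truth$data else truth
  stopifnot(all(dim(e) == dim(x)))
  d <- dim(e)
  if (length(d) == 3) { dim(e) <- c(d, 1); dim(x) <- c(d, 1); d <- dim(e) }
  rng <- max(diff(range(Mod(x))), diff(range(Mod(e))))
  if (rng == 0) rng <- 1
  C1 <- (0.01 * rng)^2
  C2 <- (0.03 * rng)^2
  vals <- numeric(d[4])
  for (n in seq_len(d[4])) {
    a <- Mod(e[, , , n]); b <- Mod(x[, , , n])
    mu_a <- .gauss_smooth3(a); mu_b <- .gauss_smooth3(b)
    va <- .gauss_smooth3(a^2) - mu_a^2
    vb <- .gauss_smooth3(b^2) - mu_b^2
    cab <- .gauss_smooth3(a * b) - mu_a * mu_b
    s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
      ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
    vals[n] <- if (is.null(mask)) mean(s) else mean(s[mask])
  }
  mean(vals)
}
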