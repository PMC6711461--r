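# Centered unitary DFT helpers. All spectral operations in the package use the
# convention that both image and k-space indices are measured from the grid
# center c = floor(n/2) + 1 (1-based), so the DC coefficient sits at the center
# bin and F^H = F^{-1} holds exactly (unitary scaling by 1/sqrt(n)).

fftshift_idx <- function(n) {
  # index permutation that moves raw-FFT bin 0 to position floor(n/2)+1
  s <- floor(n / 2)
  c(seq.int(n - s + 1, n), seq.int(1, n - s))
}

ifftshift_idx <- function(n) {
  s <- ceiling(n / 2)
  c(seq.int(n - s + 1, n), seq.int(1, n - s))
}

#' Centered frequency values of an n-point grid
#' @param n grid length
#' @return integer frequencies from -floor(n/2) to ceiling(n/2)-1
#' @keywords internal
centered_freqs <- function(n) seq.int(-floor(n / 2), length.out = n)

# Apply a 1D transform along dimension `dim` of an array by permuting that
# dimension to the front and using mvfft on a matrix view.
.apply_mvfft <- function(x, dim, inverse = FALSE) {
  d <- base::dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  perm <- c(dim, setdiff(seq_len(nd), dim))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[dim])
  m <- stats::mvfft(m, inverse = inverse)
  if (inverse) m <- m / d[dim]
  xp <- array(m, base::dim(xp))
  aperm(xp, order(perm))
}

.shift_dim <- function(x, dim, idx) {
  d <- base::dim(x)
  args <- rep(list(quote(expr = )), length(d))
  args[[dim]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

#' Centered unitary 2D DFT over the first two dimensions of an array
#'
#' Computes, for every slice indexed by trailing dimensions, the transform
#' K(k) = (1/sqrt(XY)) * sum_r x(r) exp(-2*pi*i*k.(r-c)) with both r and k
#' measured from the grid center. `inverse = TRUE` applies the exact adjoint
#' (= inverse, by unitarity).
#'
#' @param x complex array with at least 2 dimensions
#' @param inverse logical; apply the inverse transform
#' @return array of the same shape
#' @keywords internal
cfft2 <- function(x, inverse = FALSE) {
  d <- base::dim(x)
  stopifnot(length(d) >= 2)
  sc <- sqrt(d[1] * d[2])
  x <- .shift_dim(x, 1, ifftshift_idx(d[1]))
  x <- .shift_dim(x, 2, ifftshift_idx(d[2]))
  x <- .apply_mvfft(x, 1, inverse = inverse)
  x <- .apply_mvfft(x, 2, inverse = inverse)
  x <- .shift_dim(x, 1, fftshift_idx(d[1]))
  x <- .shift_dim(x, 2, fftshift_idx(d[2]))
  if (inverse) x * sc else x / sc
}

#' Centered unitary 1D DFT along a chosen dimension
#' @keywords internal
cfft1 <- function(x, dim = 1, inverse = FALSE) {
  d <- base::dim(x)
  if (is.null(d)) {
    d <- length(x)
    x <- array(x, d)
    dim <- 1L
  }
  sc <- sqrt(d[dim])
  x <- .shift_dim(x, dim, ifftshift_idx(d[dim]))
  x <- .apply_mvfft(x, dim, inverse = inverse)
  x <- .shift_dim(x, dim, fftshift_idx(d[dim]))
  if (inverse) x * sc else x / sc
}

# Dense matrix of the centered unitary 1D DFT (used by the analytic partial
# Fourier covariance path, where spectral filters become dense PE operators).
cfft1_matrix <- function(n) {
  r <- centered_freqs(n)
  exp(-2i * pi * outer(r, r) / n) / sqrt(n)
}
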