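# Small shared helpers.

#' Complex standard Gaussian draws
#'
#' Circularly symmetric complex Gaussian CN(0, sigma^2) with the per-entry
#' convention E|w|^2 = sigma^2 (real and imaginary parts each N(0, sigma^2/2)).
#'
#' @param n number of draws
#' @param sigma noise standard deviation per complex entry
#' @return complex vector of length n
#' @export
crandn <- function(n, sigma = 1) {
  complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))
}

# Hermitian square root and inverse square root via eigendecomposition, with a
# relative eigenvalue floor so nearly singular covariances stay invertible.
herm_eig <- function(sigma, floor_rel = 1e-8) {
  e <- eigen((sigma + Conj(t(sigma))) / 2, symmetric = TRUE)
  lam <- pmax(Re(e$values), floor_rel * max(Re(e$values), 0) + .Machine$double.xmin)
  list(vectors = e$vectors, values = lam)
}

herm_sqrt <- function(sigma, floor_rel = 1e-8) {
  e <- herm_eig(sigma, floor_rel)
  e$vectors %*% (sqrt(e$values) * Conj(t(e$vectors)))
}

linear_index <- function(ijk, dims) {
  # 1-based (i,j,k) -> linear index, column-major like base R arrays
  (ijk[, 3] - 1L) * dims[1] * dims[2] + (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
}

index_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1]
  j <- (lin0 %/% dims[1]) %% dims[2]
  k <- lin0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# Deterministic per-item seed derivation, order-invariant and < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
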