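# Shared small fixtures, built in code.

tiny_spec <- function(grid = c(16, 16, 16), shells = c(0, 1, 2.5),
                      n_dirs = c(3, 4, 5)) {
  phantom_spec(grid_shape = grid, shells = shells, n_dirs = n_dirs)
}

# complex iid Gaussian matrix with per-entry sd sigma
cmat <- function(M, N, sigma = 1) matrix(crandn(M * N, sigma), M, N)

# rank-R planted low-rank matrix with prescribed singular values
planted <- function(M, N, sv) {
  R <- length(sv)
  u <- qr.Q(qr(cmat(M, R)))
  v <- qr.Q(qr(cmat(N, R)))
  u %*% (sv * Conj(t(v)))
}

# identity-covariance esd_model with a zero-noise spectrum (for the identity
# shrinkage path)
zero_esd <- function(M, gamma) {
  structure(list(spectrum = rep(0, M), edge = 0, gamma = gamma, B = 1L,
                 provenance = "mp_closed_form", seed = NA_integer_),
            class = "esd_model")
}
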