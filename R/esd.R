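# Empirical spectral distribution (ESD) of patch noise: Monte-Carlo
# simulation under an arbitrary patch covariance, and the Marcenko-Pastur
# closed form for white noise.

#' Monte-Carlo noise singular-value spectrum for a patch
#'
#' Draws one (B*M) x (B*N) complex Gaussian matrix whose entries follow the
#' patch noise law: the spatial covariance is block-replicated B times across
#' rows; for interleaved (per-encoding) covariances the column groups are
#' replicated B times with their own spatial covariance. Singular values are
#' divided by sqrt(B) so the spectrum lives on the M x N singular-value
#' scale, and zero atoms are padded in so the spectrum has B*M atoms.
#'
#' @param pc a `patch_covariance` (stationary matrix or per-encoding family),
#'   or a bare M x M Hermitian matrix
#' @param M,N patch matrix dimensions
#' @param B integer oversampling factor (asymptotics accuracy vs speed)
#' @param seed integer seed; same seed gives an identical model
#' @param volume_groups integer vector (length N) of per-column encoding
#'   groups, required when `pc` is a per-encoding family
#' @return object of class `esd_model` with fields `spectrum` (decreasing),
#'   `edge`, `gamma`, `B`, `provenance`, `seed`
#' @export
simulate_esd <- function(pc, M, N, B = 2L, seed = 1L, volume_groups = NULL) {
  stopifnot(B >= 1)
  B <- as.integer(B)
  mats <- if (inherits(pc, "patch_covariance")) {
    if (!is.null(pc$matrix)) list(pc$matrix) else pc$matrices
  } else list(pc)
  if (length(mats) > 1 && is.null(volume_groups))
    stop("volume_groups is required for a per-encoding covariance family")
  if (is.null(volume_groups)) volume_groups <- rep(1L, N)
  stopifnot(length(volume_groups) == N, nrow(mats[[1]]) == M)
  roots <- lapply(mats, function(S) {
    e <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
    lam <- Re(e$values)
    if (min(lam) < -1e-8 * max(abs(lam), .Machine$double.xmin))
      stop("patch covariance is not positive semi-definite")
    e$vectors %*% (sqrt(pmax(lam, 0)) * Conj(t(e$vectors)))
  })
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  BM <- B * M; BN <- B * N
  G <- matrix(crandn(BM * BN), BM, BN)
  groups_rep <- rep(volume_groups, each = B)
  W <- matrix(0 + 0i, BM, BN)
  for (a in seq_along(mats)) {
    cols <- which(groups_rep == a)
    if (!length(cols)) next
    Ga <- G[, cols, drop = FALSE]
    # apply kron(I_B, sqrt(Sigma_a)) to the rows
    Ga <- array(Ga, c(M, B, length(cols)))
    Ga <- array(roots[[a]] %*% matrix(Ga, nrow = M), c(M, B, length(cols)))
    W[, cols] <- matrix(Ga, nrow = BM)
  }
  sv <- svd(W, nu = 0, nv = 0)$d / sqrt(B)
  if (length(sv) < BM) sv <- c(sv, rep(0, BM - length(sv)))
  structure(list(spectrum = sort(sv, decreasing = TRUE), edge = max(sv),
                 gamma = M / N, B = B, provenance = "monte_carlo",
                 seed = as.integer(seed)),
            class = "esd_model")
}

#' @export
print.esd_model <- function(x, ...) {
  cat(sprintf("<esd_model> %s, %d atoms, gamma = %.3g, edge = %.4g\n",
              x$provenance, length(x$spectrum), x$gamma, x$edge))
  invisible(x)
}

# Marcenko-Pastur eigenvalue density/CDF on a grid, unit scale, gamma in (0, 1]
.mp_grid <- function(gamma, n_grid = 4096) {
  lm <- (1 - sqrt(gamma))^2
  lp <- (1 + sqrt(gamma))^2
  lam <- seq(lm, lp, length.out = n_grid)
  dens <- sqrt(pmax((lp - lam) * (lam - lm), 0)) / (2 * pi * gamma * pmax(lam, 1e-300))
  dl <- lam[2] - lam[1]
  cdf <- cumsum((dens + c(0, dens[-n_grid])) / 2) * dl
  cdf <- cdf / cdf[n_grid]
  list(lam = lam, cdf = cdf)
}

#' Closed-form Marcenko-Pastur noise spectrum (white noise)
#'
#' Deterministic quantile discretization of the Marcenko-Pastur singular
#' value law with aspect ratio gamma (<= 1) and per-entry noise scale sigma;
#' the upper edge is the exact supremum sigma*(1 + sqrt(gamma)).
#'
#' @param gamma aspect ratio M/N in (0, 1]
#' @param sigma noise scale (per-entry sd times sqrt(N) when used against raw
#'   singular values)
#' @param n_points number of atoms
#' @return an `esd_model`
#' @export
mp_closed_form_esd <- function(gamma, sigma = 1, n_points = 2048) {
  stopifnot(gamma > 0, gamma <= 1, sigma > 0)
  g <- .mp_grid(gamma)
  q <- (seq_len(n_points) - 0.5) / n_points
  lam_q <- stats::approx(g$cdf, g$lam, xout = q, rule = 2)$y
  sv <- sigma * sqrt(lam_q)
  sv <- sort(sv, decreasing = TRUE)
  edge <- sigma * (1 + sqrt(gamma))
  sv[1] <- edge
  structure(list(spectrum = sv, edge = edge, gamma = gamma, B = NA_integer_,
                 provenance = "mp_closed_form", seed = NA_integer_),
            class = "esd_model")
}

#' Median of the unit-scale Marcenko-Pastur eigenvalue law
#'
#' Numerical inversion of the Marcenko-Pastur CDF at 1/2; the normalizer
#' theta^2 of the spectral-median noise estimator.
#'
#' @param gamma aspect ratio in (0, 1]
#' @return the median eigenvalue
#' @export
mp_median <- function(gamma) {
  stopifnot(gamma > 0, gamma <= 1)
  if (gamma < 1e-8) return(1)
  g <- .mp_grid(gamma)
  stats::approx(g$cdf, g$lam, xout = 0.5, rule = 2)$y
}

#' D-transform of an ESD
#'
#' Df(x) = phi(x) * (gamma * phi(x) + (1 - gamma)/x) with
#' phi(x) = mean over the spectrum atoms of x / (x^2 - eta^2); defined for
#' x strictly above the bulk edge.
#'
#' @param x evaluation points (all > edge)
#' @param esd an `esd_model`
#' @return Df values
#' @export
d_transform <- function(x, esd) {
  .check_above_edge(x, esd)
  eta2 <- esd$spectrum^2
  phi <- vapply(x, function(xx) mean(xx / (xx^2 - eta2)), numeric(1))
  phi * (esd$gamma * phi + (1 - esd$gamma) / x)
}

#' Derivative of the D-transform
#'
#' Exact differentiation of the discrete-atom D-transform; strictly negative
#' above the edge for valid spectra.
#'
#' @inheritParams d_transform
#' @return D'f values
#' @export
d_transform_deriv <- function(x, esd) {
  .check_above_edge(x, esd)
  eta2 <- esd$spectrum^2
  g <- esd$gamma
  vapply(x, function(xx) {
    phi <- mean(xx / (xx^2 - eta2))
    dphi <- mean(-(xx^2 + eta2) / (xx^2 - eta2)^2)
    dphi * (g * phi + (1 - g) / xx) + phi * (g * dphi - (1 - g) / xx^2)
  }, numeric(1))
}

.check_above_edge <- function(x, esd) {
  if (any(x <= esd$edge))
    stop("D-transform evaluated at or below the bulk edge; such components must be routed to the zero branch of the shrinker")
}

#' Optimal Frobenius singular-value shrinkage
#'
#' Applies the two-branch rule: observed singular values above the noise bulk
#' edge are shrunk to -2 Df(y) / D'f(y); values at or below the edge are set
#' to zero. The number of surviving components is the rank estimate.
#'
#' @param etaY observed singular values, sorted decreasingly
#' @param esd an `esd_model` on the same singular-value scale
#' @return object of class `shrinkage_result`: `eta_hat`, `rank`,
#'   `kept_indices`
#' @export
shrink <- function(etaY, esd) {
  stopifnot(!is.unsorted(rev(etaY)))
  keep <- etaY > esd$edge
  eta_hat <- numeric(length(etaY))
  if (any(keep)) {
    y <- etaY[keep]
    val <- -2 * d_transform(y, esd) / d_transform_deriv(y, esd)
    neg <- val < 0
    if (any(neg)) {
      message(sprintf("shrinker produced %d negative value(s); clamped to 0", sum(neg)))
      val[neg] <- 0
    }
    eta_hat[keep] <- val
  }
  structure(list(eta_hat = eta_hat, rank = sum(keep), kept_indices = which(keep)),
            class = "shrinkage_result")
}

#' Estimated asymptotic mean squared error of a shrunk patch
#'
#' Sums 1/Df(etaY_r) - etaX_hat_r^2 over the components kept by the shrinker;
#' negative terms (numerical) are floored at zero.
#'
#' @param etaY observed singular values (decreasing)
#' @param result the matching `shrinkage_result`
#' @param esd the `esd_model` used for shrinkage
#' @return non-negative AMSE estimate (squared data units)
#' @export
estimate_amse <- function(etaY, result, esd) {
  k <- result$kept_indices
  if (!length(k)) return(0)
  terms <- 1 / d_transform(etaY[k], esd) - result$eta_hat[k]^2
  sum(pmax(terms, 0))
}

#' Asymptotic location of a spiked sample eigenvalue
#'
#' For a population covariance with one eigenvalue etaX^2 > 1 above a unit
#' bulk, the top sample-covariance eigenvalue converges to
#' etaX^2 * (1 + gamma / (etaX^2 - 1)); a positive bias for all gamma > 0.
#'
#' @param eta_x2 population spike eigenvalue (> 1 + sqrt(gamma))
#' @param gamma aspect ratio
#' @return the deterministic limit of the sample eigenvalue
#' @export
spiked_limit <- function(eta_x2, gamma) {
  stopifnot(gamma >= 0)
  if (any(eta_x2 <= 1 + sqrt(gamma)))
    warning("population spike at or below the detection threshold; the limit formula does not apply")
  eta_x2 * (1 + gamma / (eta_x2 - 1))
}
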