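# Data-driven noise level / rank estimators operating on the singular-value
# spectrum of a patch matrix, and the hard-truncation baseline.
#
# All estimators work in sample-covariance eigenvalue units lambda_r =
# etaY_r^2 / N and return the noise standard deviation per complex matrix
# entry (real and imaginary parts combined). They are symmetric in (M, N):
# if M > N the roles are swapped internally.

#' Spectral-expectation noise and rank estimator (EXP1 / EXP2)
#'
#' Iterates candidate signal ranks R; at each R the Marcenko-Pastur
#' bulk-width statistic
#'   sigma~^2(R) = (lambda_{R+1} - lambda_p) / (4 * sqrt(beta)),
#' with beta = (M - R)/N for EXP1 and (M - R)/(N - R) for EXP2 (the
#' shape-corrected variant for close-to-square matrices), is compared with
#' the expectation of the putative noise tail. The rank estimate is the
#' smallest R satisfying
#'   sum_{r > R} lambda_r >= (M - R) * sigma~^2(R),
#' i.e. the first R at which the tail expectation reaches the level implied
#' by the bulk width, and the reported noise variance is the tail
#' expectation sigma^2 = sum_{r > R} lambda_r / (M - R) at that R (the
#' statistic whose mean is exactly sigma^2 on pure noise).
#'
#' @param etaY observed singular values, sorted decreasingly
#' @param M,N matrix dimensions (rows, columns)
#' @param variant "EXP1" or "EXP2"
#' @return object of class `noise_estimate`: `sigma` (per complex entry),
#'   `rank`, `variant`, `converged`
#' @export
exp_estimator <- function(etaY, M, N, variant = c("EXP2", "EXP1")) {
  variant <- match.arg(variant)
  if (M > N) { tmp <- M; M <- N; N <- tmp }
  p <- min(M, length(etaY))
  if (p < 2) stop("spectral-expectation estimation needs at least two singular values")
  lam <- sort(etaY^2 / N, decreasing = TRUE)[seq_len(p)]
  rank <- p - 1L
  sigma2 <- NA_real_
  converged <- FALSE
  for (R in 0:(p - 2L)) {
    beta <- if (variant == "EXP1") (M - R) / N else (M - R) / (N - R)
    s2 <- (lam[R + 1L] - lam[p]) / (4 * sqrt(beta))
    tail <- sum(lam[(R + 1L):p])
    if (tail >= (M - R) * s2) {
      rank <- R
      sigma2 <- tail / (M - R)
      converged <- TRUE
      break
    }
    sigma2 <- tail / (M - R)
  }
  if (!converged)
    warning("rank criterion never satisfied; returning rank min(M,N) - 1")
  structure(list(sigma = sqrt(max(sigma2, 0)), rank = as.integer(rank),
                 variant = variant, converged = converged),
            class = "noise_estimate")
}

#' Spectral-median noise estimator (MED)
#'
#' sigma^2 = lambda_median / theta^2_median(gamma), the ratio of the median
#' observed sample-covariance eigenvalue to the median of the unit-scale
#' Marcenko-Pastur law at gamma = M/N. For an even number of eigenvalues the
#' index p/2 of the decreasingly sorted spectrum is used.
#'
#' @param etaY observed singular values, sorted decreasingly
#' @param M,N matrix dimensions
#' @return a `noise_estimate` (rank is NA for this estimator)
#' @export
med_estimator <- function(etaY, M, N) {
  if (M > N) { tmp <- M; M <- N; N <- tmp }
  p <- min(M, length(etaY))
  lam <- sort(etaY^2 / N, decreasing = TRUE)[seq_len(p)]
  idx <- if (p %% 2 == 0) p %/% 2L else (p + 1L) %/% 2L
  th2 <- mp_median(M / N)
  structure(list(sigma = sqrt(lam[idx] / th2), rank = NA_integer_,
                 variant = "MED", converged = TRUE),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> %s: sigma = %.4g, rank = %s\n",
              x$variant, x$sigma, ifelse(is.na(x$rank), "-", x$rank)))
  invisible(x)
}

#' Hard singular-value truncation (MPPCA-style baseline)
#'
#' Keeps the top `rank` SVD components of a patch matrix unchanged and zeros
#' the rest — the keep-or-kill baseline that optimal shrinkage is compared
#' against.
#'
#' @param Y complex M x N patch matrix
#' @param rank number of components to keep (e.g. from [exp_estimator()])
#' @return the truncated matrix
#' @export
mppca_truncate <- function(Y, rank) {
  rank <- min(as.integer(rank), min(dim(Y)))
  if (rank <= 0) return(array(0 + 0i, dim(Y)))
  if (rank == min(dim(Y))) return(Y)
  sv <- svd(Y, nu = rank, nv = rank)
  sv$u %*% (sv$d[seq_len(rank)] * Conj(t(sv$v)))
}
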