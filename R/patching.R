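# Spherical sliding patches: layout construction, Casorati matrix
# extraction, and weighted assembly of overlapping patch estimates.

#' Build a spherical patch layout
#'
#' Patch centers sit on a stride-T lattice intersected with the FOV mask,
#' augmented with extra centers so that every FOV voxel belongs to at least
#' one patch. Each patch consists of the M nearest in-FOV voxels to its
#' center (Euclidean distance in voxel-size units, ties broken by
#' lexicographic offset), so spheres deform at FOV boundaries instead of
#' zero-padding. M = round(gamma * N).
#'
#' @param fov_mask logical 3D array of in-FOV voxels
#' @param N number of volumes (columns of the patch matrices)
#' @param gamma target aspect ratio M/N (> 0)
#' @param T stride of the center lattice (>= 1)
#' @param voxel_size length-3 physical voxel size used for distances
#' @param cover if TRUE (the default), add extra centers until every FOV
#'   voxel belongs to a patch (required for assembly); sparse evaluation
#'   layouts (patch-size estimation) can skip this
#' @return object of class `patch_layout`: `centers` (linear indices),
#'   `members` (M x n_centers matrix of linear indices, distance-ordered),
#'   `dists` (matching distances), `M`, `gamma`, `stride`
#' @export
build_layout <- function(fov_mask, N, gamma, T = 2L, voxel_size = c(1, 1, 1),
                         cover = TRUE) {
  stopifnot(gamma > 0, N >= 1, T >= 1)
  dims <- dim(fov_mask)
  M <- max(1L, as.integer(round(gamma * N)))
  nfov <- sum(fov_mask)
  if (M > nfov) stop(sprintf("patch size M = %d exceeds the %d FOV voxels", M, nfov))
  # precomputed offsets sorted by distance (then lexicographic), generous
  # radius so boundary-deformed patches still find M members
  r3 <- max(2, ceiling((3 * 8 * M / (4 * pi))^(1 / 3)) + 1)
  off <- as.matrix(expand.grid(dx = -r3:r3, dy = -r3:r3, dz = -r3:r3))
  d2 <- (off[, 1] * voxel_size[1])^2 + (off[, 2] * voxel_size[2])^2 + (off[, 3] * voxel_size[3])^2
  ord <- order(d2, off[, 1], off[, 2], off[, 3])
  off <- off[ord, , drop = FALSE]
  d2 <- d2[ord]
  lat <- function(n) seq.int(1L, n, by = T)
  cand <- as.matrix(expand.grid(i = lat(dims[1]), j = lat(dims[2]), k = lat(dims[3])))
  centers <- linear_index(cand, dims)
  centers <- centers[fov_mask[centers]]
  fill_members <- function(ctrs) {
    mem <- matrix(0L, M, length(ctrs))
    dst <- matrix(0, M, length(ctrs))
    ijk <- index_to_ijk(ctrs, dims)
    for (c in seq_along(ctrs)) {
      pos <- sweep(off, 2, ijk[c, ], `+`)
      ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] & pos[, 2] >= 1 & pos[, 2] <= dims[2] &
        pos[, 3] >= 1 & pos[, 3] <= dims[3]
      li <- linear_index(pos[ok, , drop = FALSE], dims)
      dd <- d2[ok]
      inf <- fov_mask[li]
      li <- li[inf]; dd <- dd[inf]
      if (length(li) < M) {
        # rare tight-mask fallback: search the whole FOV
        allfov <- which(fov_mask)
        aijk <- index_to_ijk(allfov, dims)
        ad2 <- ((aijk[, 1] - ijk[c, 1]) * voxel_size[1])^2 +
          ((aijk[, 2] - ijk[c, 2]) * voxel_size[2])^2 +
          ((aijk[, 3] - ijk[c, 3]) * voxel_size[3])^2
        aord <- order(ad2, aijk[, 1], aijk[, 2], aijk[, 3])
        li <- allfov[aord]; dd <- ad2[aord]
      }
      mem[, c] <- li[seq_len(M)]
      dst[, c] <- sqrt(dd[seq_len(M)])
    }
    list(members = mem, dists = dst)
  }
  fm <- fill_members(centers)
  covered <- logical(prod(dims))
  covered[fm$members] <- TRUE
  missing <- if (cover) which(fov_mask & !array(covered, dims)) else integer(0)
  if (length(missing)) {
    extra <- fill_members(missing)
    centers <- c(centers, missing)
    fm$members <- cbind(fm$members, extra$members)
    fm$dists <- cbind(fm$dists, extra$dists)
  }
  structure(list(centers = centers, members = fm$members, dists = fm$dists,
                 M = M, gamma = M / N, stride = as.integer(T), dims = dims,
                 voxel_size = voxel_size),
            class = "patch_layout")
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("<patch_layout> %d centers, M = %d (gamma = %.3g), stride %d on %s grid\n",
              length(x$centers), x$M, x$gamma, x$stride, paste(x$dims, collapse = "x")))
  invisible(x)
}

#' Extract the Casorati matrix of one patch
#'
#' Row m holds the N complex values of the m-closest member voxel.
#'
#' @param ymat flattened data matrix (Q x N), e.g. `matrix(y$data, ncol = N)`
#' @param layout a `patch_layout`
#' @param index patch index
#' @return complex M x N matrix
#' @export
extract_patch <- function(ymat, layout, index) {
  ymat[layout$members[, index], , drop = FALSE]
}

#' Assemble overlapping patch estimates into volumes
#'
#' Each voxel's output is a convex combination of the estimates from all
#' patches containing it. Weight schemes: `uniform`; `inverse_variance`
#' (per-patch weight 1/AMSE); `gaussian` (distance from patch center, window
#' width = half the nominal patch radius by default); `nearest` keeps, for
#' each voxel, only the estimate from the patch whose center is closest — the
#' no-overlap diagnostic. Weights are normalized per voxel so they sum to 1.
#'
#' @param estimates list of M x N complex matrices (one per patch)
#' @param layout the `patch_layout` used for extraction
#' @param scheme weighting scheme
#' @param amse per-patch AMSE values (required for `inverse_variance`)
#' @param gaussian_width window sd in distance units (default: half the
#'   nominal patch radius (3M/4pi)^(1/3))
#' @param N number of volumes
#' @return list with `data` (X,Y,Z,N complex array) and `weight_sum`
#' @export
assemble_patches <- function(estimates, layout, N,
                             scheme = c("inverse_variance", "uniform", "gaussian", "nearest"),
                             amse = NULL, gaussian_width = NULL) {
  scheme <- match.arg(scheme)
  Q <- prod(layout$dims)
  npatch <- length(estimates)
  stopifnot(ncol(layout$members) == npatch)
  if (scheme == "inverse_variance") {
    stopifnot(!is.null(amse), length(amse) == npatch)
    eps <- 1e-12 * max(amse, 1e-300)
    pw <- 1 / pmax(amse, eps)
  } else pw <- rep(1, npatch)
  if (scheme == "gaussian" && is.null(gaussian_width))
    gaussian_width <- 0.5 * (3 * layout$M / (4 * pi))^(1 / 3) * mean(layout$voxel_size)
  num <- matrix(0 + 0i, Q, N)
  den <- numeric(Q)
  if (scheme == "nearest") {
    best <- rep(Inf, Q)
    bestc <- rep(.Machine$integer.max, Q)
    pick <- matrix(0 + 0i, Q, N)
    for (p in seq_len(npatch)) {
      mem <- layout$members[, p]
      d <- layout$dists[, p]
      ctr <- layout$centers[p]
      upd <- d < best[mem] | (d == best[mem] & ctr < bestc[mem])
      if (any(upd)) {
        best[mem[upd]] <- d[upd]
        bestc[mem[upd]] <- ctr
        pick[mem[upd], ] <- estimates[[p]][upd, , drop = FALSE]
      }
    }
    den[best < Inf] <- 1
    num <- pick
  } else {
    for (p in seq_len(npatch)) {
      mem <- layout$members[, p]
      w <- if (scheme == "gaussian")
        pw[p] * exp(-layout$dists[, p]^2 / (2 * gaussian_width^2)) else
          rep(pw[p], layout$M)
      num[mem, ] <- num[mem, ] + w * estimates[[p]]
      den[mem] <- den[mem] + w
    }
  }
  covered <- den > 0
  if (!all(covered[unique(as.vector(layout$members))]))
    stop("assembly produced an uncovered member voxel; layout guarantee violated")
  num[covered, ] <- num[covered, ] / den[covered]
  list(data = array(num, c(layout$dims, N)), weight_sum = array(den, layout$dims))
}
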