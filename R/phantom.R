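#' Complex DWI volume stack
#'
#' Lightweight container for a stack of complex diffusion-weighted volumes on
#' a common voxel grid: a 4D complex array (x, y, z, volume) plus the
#' per-volume diffusion metadata (b-value, gradient direction).
#'
#' @param data complex (or numeric) 4D array, dims (X, Y, Z, N)
#' @param bvals numeric length-N b-values (ms/um^2)
#' @param dirs N x 3 matrix of unit gradient directions
#' @param voxel_size length-3 voxel size in mm
#' @param pe_group optional integer vector (length N): encoding group of each
#'   volume for interleaved acquisitions
#' @return object of class `volume_stack`
#' @export
volume_stack <- function(data, bvals = NULL, dirs = NULL,
                         voxel_size = c(1, 1, 1), pe_group = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 4)
  storage.mode(data) <- "complex"
  structure(list(data = data, bvals = bvals, dirs = dirs,
                 voxel_size = voxel_size, pe_group = pe_group),
            class = "volume_stack")
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %d x %d x %d grid, %d volumes\n", d[1], d[2], d[3], d[4]))
  if (!is.null(x$bvals))
    cat("  b-values:", paste(unique(x$bvals), collapse = ", "), "ms/um^2\n")
  invisible(x)
}

#' Quasi-uniform unit directions on the sphere
#'
#' Deterministic Fibonacci-spiral point set, optionally rotated so successive
#' shells do not share directions.
#'
#' @param n number of directions
#' @param rot rotation offset (radians) applied around z
#' @return n x 3 matrix of unit vectors
#' @export
sphere_directions <- function(n, rot = 0) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i + rot
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Phantom specification
#'
#' Geometry and diffusion protocol of the synthetic multi-shell tensor
#' phantom. Regions are ellipsoids, each carrying a baseline intensity S0 and
#' a symmetric positive-definite diffusion tensor (um^2/ms); later regions
#' overwrite earlier ones where they overlap.
#'
#' @param grid_shape length-3 integer grid size
#' @param voxel_size length-3 voxel size (mm)
#' @param shells b-values of the shells (ms/um^2)
#' @param n_dirs number of directions per shell (recycled)
#' @param regions list of regions; each a list with `center` (voxel units),
#'   `semiaxes` (voxel units), `S0`, and `tensor` (3x3 SPD, um^2/ms)
#' @param seed integer seed recorded for provenance
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), voxel_size = c(2.5, 2.5, 2.5),
                         shells = c(0, 1, 2.5, 5), n_dirs = c(6, 10, 14, 18),
                         regions = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  n_dirs <- rep_len(as.integer(n_dirs), length(shells))
  if (is.null(regions)) regions <- default_phantom_regions(grid_shape)
  for (rg in regions) {
    ev <- eigen(rg$tensor, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("region diffusion tensor must be symmetric positive definite")
    if (any(rg$center < 1 | rg$center > grid_shape))
      stop("region center lies outside the grid")
  }
  bvals <- rep(shells, n_dirs)
  dirs <- do.call(rbind, lapply(seq_along(shells), function(s)
    sphere_directions(n_dirs[s], rot = (s - 1) * 0.7)))
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 shells = shells, n_dirs = n_dirs, bvals = bvals, dirs = dirs,
                 regions = regions, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default nested-ellipsoid phantom geometry
#'
#' An outer isotropic "brain" ellipsoid, two anisotropic "tract" bundles with
#' orthogonal principal orientations, and a small free-diffusion (CSF-like)
#' sphere, scaled to the grid.
#'
#' @param grid_shape length-3 grid size
#' @return list of region descriptions
#' @export
default_phantom_regions <- function(grid_shape) {
  c0 <- (grid_shape + 1) / 2
  sc <- grid_shape / 32
  iso <- function(d) diag(rep(d, 3))
  aniso <- function(axis, lam_par = 1.7, lam_perp = 0.3) {
    d <- rep(lam_perp, 3); d[axis] <- lam_par; diag(d)
  }
  list(
    list(center = c0, semiaxes = 13 * sc, S0 = 100, tensor = iso(0.8)),
    list(center = c0 + c(0, -4, 0) * sc, semiaxes = c(9, 3, 3) * sc, S0 = 110,
         tensor = aniso(1)),
    list(center = c0 + c(0, 4, 2) * sc, semiaxes = c(3, 9, 3) * sc, S0 = 110,
         tensor = aniso(2)),
    list(center = c0 + c(6, 0, -4) * sc, semiaxes = 3.5 * sc, S0 = 150,
         tensor = iso(3.0))
  )
}

#' Synthesize the noise-free phantom signal
#'
#' Evaluates the single-tensor model S0 * exp(-b g' D g) per region and
#' volume. Background voxels are zero; the result is real-valued (zero phase)
#' until phase corruption is applied.
#'
#' @param spec a [phantom_spec()]
#' @return a [volume_stack()] with the ground-truth signal
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  N <- length(spec$bvals)
  x <- array(0 + 0i, c(gs, N))
  ax <- seq_len(gs[1]); ay <- seq_len(gs[2]); az <- seq_len(gs[3])
  coords <- cbind(rep(ax, times = gs[2] * gs[3]),
                  rep(rep(ay, each = gs[1]), times = gs[3]),
                  rep(az, each = gs[1] * gs[2]))
  Q <- prod(gs)
  xm <- matrix(0, Q, N)
  for (rg in spec$regions) {
    sa <- rep_len(rg$semiaxes, 3)
    u <- sweep(coords, 2, rg$center) / matrix(sa, Q, 3, byrow = TRUE)
    inside <- rowSums(u^2) <= 1
    if (!any(inside)) next
    # attenuation per volume: exp(-b * g' D g)
    gDg <- rowSums((spec$dirs %*% rg$tensor) * spec$dirs)
    att <- rg$S0 * exp(-spec$bvals * gDg)
    xm[inside, ] <- matrix(att, sum(inside), N, byrow = TRUE)
  }
  x[] <- complex(real = xm)
  volume_stack(x, bvals = spec$bvals, dirs = spec$dirs, voxel_size = spec$voxel_size)
}

#' Phantom support mask
#'
#' Logical 3D array marking voxels inside any region of the spec.
#' @param spec a [phantom_spec()]
#' @return logical array of dim `grid_shape`
#' @export
phantom_mask <- function(spec) {
  gs <- spec$grid_shape
  ax <- seq_len(gs[1]); ay <- seq_len(gs[2]); az <- seq_len(gs[3])
  coords <- cbind(rep(ax, times = gs[2] * gs[3]),
                  rep(rep(ay, each = gs[1]), times = gs[3]),
                  rep(az, each = gs[1] * gs[2]))
  m <- rep(FALSE, prod(gs))
  for (rg in spec$regions) {
    sa <- rep_len(rg$semiaxes, 3)
    u <- sweep(coords, 2, rg$center) / matrix(sa, prod(gs), 3, byrow = TRUE)
    m <- m | rowSums(u^2) <= 1
  }
  array(m, gs)
}

#' Smooth multi-coil sensitivity set
#'
#' Generates L smooth complex coil sensitivity maps (Gaussian magnitude lobes
#' centered on the FOV boundary with smooth linear phase) and an L x L
#' Hermitian positive-definite channel noise covariance with exponentially
#' decaying off-diagonal correlation rho^|i-j|.
#'
#' @param grid_shape length-3 grid size
#' @param L number of coils
#' @param seed integer seed; same seed gives a bit-identical coil set
#' @param rho channel correlation parameter in [0, 1)
#' @param uniform if TRUE return a single uniform unit-sensitivity "coil"
#'   regardless of L (identity configuration for tests)
#' @return object of class `coil_set` with fields `sens` (X,Y,Z,L complex),
#'   `channel_cov` (L x L), `n_coils`
#' @export
make_coils <- function(grid_shape, L = 8, seed = 1L, rho = 0.3, uniform = FALSE) {
  grid_shape <- as.integer(grid_shape)
  if (uniform) {
    sens <- array(1 + 0i, c(grid_shape, 1L))
    return(structure(list(sens = sens, channel_cov = matrix(1, 1, 1), n_coils = 1L,
                          grid_shape = grid_shape),
                     class = "coil_set"))
  }
  stopifnot(L >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  gs <- grid_shape
  c0 <- (gs + 1) / 2
  ax <- seq_len(gs[1]); ay <- seq_len(gs[2]); az <- seq_len(gs[3])
  sens <- array(0 + 0i, c(gs, L))
  width <- 0.9 * max(gs)
  ang <- 2 * pi * (seq_len(L) - 1) / L + stats::runif(1, 0, 2 * pi)
  rad <- 0.55 * gs[1:2]
  for (l in seq_len(L)) {
    cx <- c0[1] + rad[1] * cos(ang[l])
    cy <- c0[2] + rad[2] * sin(ang[l])
    cz <- c0[3] + stats::runif(1, -0.2, 0.2) * gs[3]
    d2 <- outer(outer((ax - cx)^2, (ay - cy)^2, `+`), 0.5 * (az - cz)^2, `+`)
    mag <- exp(-d2 / (2 * width^2))
    # smooth linear phase per coil
    ph <- outer(outer(stats::runif(1, -1, 1) * pi * (ax - c0[1]) / gs[1],
                      stats::runif(1, -1, 1) * pi * (ay - c0[2]) / gs[2], `+`),
                stats::runif(1, -1, 1) * pi * (az - c0[3]) / gs[3], `+`) +
      stats::runif(1, -pi, pi)
    sens[, , , l] <- mag * exp(1i * ph)
  }
  # normalize so sum-of-squares sensitivity is O(1) in the FOV center
  ss <- sqrt(apply(abs(sens)^2, 1:3, sum))
  sens <- sens / max(ss)
  cc <- rho^abs(outer(seq_len(L), seq_len(L), `-`))
  structure(list(sens = sens, channel_cov = cc, n_coils = L, grid_shape = gs),
            class = "coil_set")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Per-slice linear phase corruption model
#'
#' Draws a random linear phase ramp (cycles across the FOV, per in-plane
#' axis) and constant offset for each (slice, volume), with ramp amplitude
#' scaling as sqrt(b / b_max) so stronger diffusion weighting carries larger
#' phase fluctuations. b = 0 volumes are left uncorrupted.
#'
#' @param grid_shape length-3 grid size
#' @param bvals per-volume b-values
#' @param max_harmonic maximal ramp magnitude in cycles/FOV at b = b_max
#' @param integer_harmonics draw ramps on the integer-harmonic lattice (exact
#'   demodulation possible) or continuously
#' @param offset_scale maximal |offset| in radians
#' @param seed integer seed
#' @return object of class `phase_corruption`: arrays `hx`, `hy`, `offset` of
#'   dim (n_slices, N)
#' @export
random_phase_corruption <- function(grid_shape, bvals, max_harmonic = 3,
                                    integer_harmonics = TRUE, offset_scale = pi,
                                    seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  nz <- grid_shape[3]; N <- length(bvals)
  bmax <- max(bvals)
  amp <- if (bmax > 0) sqrt(bvals / bmax) else rep(0, N)
  draw <- function() {
    h <- matrix(stats::runif(nz * N, -max_harmonic, max_harmonic), nz, N)
    h <- sweep(h, 2, amp, `*`)
    if (integer_harmonics) h <- round(h)
    h
  }
  hx <- draw(); hy <- draw()
  off <- matrix(stats::runif(nz * N, -offset_scale, offset_scale), nz, N)
  off <- sweep(off, 2, as.numeric(amp > 0), `*`)
  structure(list(hx = hx, hy = hy, offset = off, grid_shape = grid_shape),
            class = "phase_corruption")
}

#' Zero phase corruption (identity)
#' @param grid_shape length-3 grid size
#' @param N number of volumes
#' @return a `phase_corruption` with all-zero ramps and offsets
#' @export
zero_phase_corruption <- function(grid_shape, N) {
  nz <- grid_shape[3]
  structure(list(hx = matrix(0, nz, N), hy = matrix(0, nz, N),
                 offset = matrix(0, nz, N), grid_shape = grid_shape),
            class = "phase_corruption")
}

# unit-modulus phase plane for one slice: exp(i*(2*pi*(hx*(x-cx)/X + hy*(y-cy)/Y) + off))
.phase_plane <- function(dims, hx, hy, off) {
  fx <- centered_freqs(dims[1]) / dims[1]
  fy <- centered_freqs(dims[2]) / dims[2]
  exp(1i * (2 * pi * outer(hx * fx, hy * fy, `+`) + off))
}

#' Apply linear phase corruption to a volume stack
#'
#' Multiplies each slice of each volume by the unit-modulus linear phase
#' plane of `pc`; magnitudes are unchanged everywhere.
#'
#' @param x a [volume_stack()]
#' @param pc a phase corruption from [random_phase_corruption()]
#' @return corrupted [volume_stack()]
#' @export
corrupt_phase <- function(x, pc) {
  stopifnot(inherits(x, "volume_stack"), inherits(pc, "phase_corruption"))
  d <- dim(x$data)
  stopifnot(all(d[3] == nrow(pc$hx)), d[4] == ncol(pc$hx))
  out <- x$data
  for (n in seq_len(d[4])) for (z in seq_len(d[3])) {
    if (pc$hx[z, n] == 0 && pc$hy[z, n] == 0 && pc$offset[z, n] == 0) next
    out[, , z, n] <- out[, , z, n] * .phase_plane(d[1:2], pc$hx[z, n], pc$hy[z, n], pc$offset[z, n])
  }
  x$data <- out
  x
}

#' Cartesian sampling scheme
#'
#' Describes how each volume's k-space is sampled on the (centered) full
#' reconstruction grid: regular undersampling by `U` along the phase-encoding
#' axis, partial-Fourier coverage `pf_fraction`, and for interleaved
#' acquisitions a per-volume encoding out of `A` alternatives (PE axis in
#' {x, y} x omitted side in {-, +}).
#'
#' @param mode one of "FULL", "UNDER", "HALF", "INTER"
#' @param U integer undersampling factor along the PE axis
#' @param pf_fraction fraction of PE lines acquired (0.5-1]; 1 unless mode is
#'   HALF or INTER
#' @param pe_axis in-plane PE axis (1 or 2) for non-interleaved modes
#' @param pf_side which end of the PE axis is omitted (+1: most-negative
#'   frequencies omitted)
#' @param spectral_filter one of "none", "zero_fill", "ramp" (the filter G
#'   applied after unfolding for partial-Fourier data)
#' @param A number of interleaved encodings (INTER only; up to 4)
#' @param pe_group optional explicit per-volume encoding index (INTER)
#' @return object of class `sampling_scheme`
#' @export
sampling_scheme <- function(mode = c("FULL", "UNDER", "HALF", "INTER"),
                            U = 1L, pf_fraction = 1, pe_axis = 2L, pf_side = 1L,
                            spectral_filter = c("none", "zero_fill", "ramp"),
                            A = 4L, pe_group = NULL) {
  mode <- match.arg(mode)
  spectral_filter <- match.arg(spectral_filter)
  if (!mode %in% c("HALF", "INTER") && pf_fraction != 1)
    stop("pf_fraction must be 1 unless mode is HALF or INTER")
  if (mode == "FULL" && U != 1) stop("mode FULL requires U = 1")
  stopifnot(pf_fraction > 0.5 || pf_fraction == 0.5, pf_fraction <= 1, U >= 1)
  encodings <- if (mode == "INTER") {
    all4 <- list(list(pe_axis = 2L, pf_side = 1L), list(pe_axis = 2L, pf_side = -1L),
                 list(pe_axis = 1L, pf_side = 1L), list(pe_axis = 1L, pf_side = -1L))
    all4[seq_len(A)]
  } else {
    list(list(pe_axis = as.integer(pe_axis), pf_side = as.integer(pf_side)))
  }
  structure(list(mode = mode, U = as.integer(U), pf_fraction = pf_fraction,
                 spectral_filter = spectral_filter, encodings = encodings,
                 A = if (mode == "INTER") as.integer(A) else 1L,
                 pe_group = pe_group),
            class = "sampling_scheme")
}

#' Acquired PE lines of a scheme
#'
#' Centered frequency indices acquired along a PE axis of length `n`:
#' multiples of `U` with the `pf_side`-most extreme fraction (1 - pf) of the
#' axis omitted.
#'
#' @param n PE axis length
#' @param U undersampling factor
#' @param pf_fraction acquired fraction
#' @param pf_side +1 omits the most-negative frequencies, -1 the most-positive
#' @return integer vector of centered acquired frequencies
#' @export
acquired_lines <- function(n, U = 1L, pf_fraction = 1, pf_side = 1L) {
  k <- centered_freqs(n)
  keep <- (k %% U) == 0
  if (pf_fraction < 1) {
    lim <- (pf_fraction - 0.5) * n
    keep <- keep & (if (pf_side >= 0) k >= -lim else k <= lim)
  }
  acq <- k[keep]
  if (length(acq) < 1) stop("sampling scheme leaves no acquired PE lines")
  acq
}

# per-volume encoding index
.volume_groups <- function(scheme, N) {
  if (scheme$mode != "INTER") return(rep(1L, N))
  if (!is.null(scheme$pe_group)) {
    stopifnot(length(scheme$pe_group) == N)
    return(as.integer(scheme$pe_group))
  }
  ((seq_len(N) - 1L) %% scheme$A) + 1L
}

#' Sample multi-channel k-space from a volume stack
#'
#' Applies the forward encoding z = M . F2D(S_c x) + w per volume, slice and
#' coil, where F2D is the centered unitary in-plane DFT, M keeps the acquired
#' PE lines of the scheme and w is circularly symmetric complex Gaussian with
#' channel covariance `noise_sigma^2 * Lambda_z`, independent across acquired
#' samples and volumes. Unacquired samples are stored as zeros alongside the
#' acquisition mask.
#'
#' @param x a [volume_stack()] (ground truth)
#' @param coils a `coil_set` from [make_coils()]
#' @param scheme a [sampling_scheme()]
#' @param noise_sigma noise standard deviation per acquired complex sample
#' @param seed integer seed for the noise draws
#' @return object of class `kspace_data`: `z` complex array (X,Y,Z,L,N),
#'   `masks` per-encoding logical PE masks, `groups` per-volume encoding
#'   index, plus the coil set and scheme
#' @export
sample_kspace <- function(x, coils, scheme, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(x, "volume_stack"), inherits(coils, "coil_set"),
            inherits(scheme, "sampling_scheme"))
  d <- dim(x$data); gs <- d[1:3]; N <- d[4]; L <- coils$n_coils
  stopifnot(all(coils$grid_shape == gs))
  groups <- .volume_groups(scheme, N)
  masks <- lapply(scheme$encodings, function(enc) {
    axis <- enc$pe_axis
    acq <- acquired_lines(gs[axis], scheme$U, scheme$pf_fraction, enc$pf_side)
    centered_freqs(gs[axis]) %in% acq
  })
  # coil-modulated images, then in-plane DFT for all (slice, coil, volume)
  z <- array(0 + 0i, c(gs, L, N))
  for (n in seq_len(N)) {
    z[, , , , n] <- array(rep(x$data[, , , n], L), c(gs, L)) * coils$sens
  }
  z <- cfft2(z)
  # apply per-volume PE mask
  for (n in seq_len(N)) {
    enc <- scheme$encodings[[groups[n]]]
    m <- masks[[groups[n]]]
    if (enc$pe_axis == 1L) z[!m, , , , n] <- 0 else z[, !m, , , n] <- 0
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    ch <- herm_sqrt(coils$channel_cov * noise_sigma^2)
    nk <- prod(gs)
    for (n in seq_len(N)) {
      w <- matrix(crandn(nk * L), nk, L) %*% t(ch)  # rows: samples, channel cov per row
      w <- array(w, c(gs, L))
      enc <- scheme$encodings[[groups[n]]]
      m <- masks[[groups[n]]]
      if (enc$pe_axis == 1L) w[!m, , , ] <- 0 else w[, !m, , ] <- 0
      z[, , , , n] <- as.vector(z[, , , , n]) + as.vector(w)
    }
  }
  structure(list(z = z, masks = masks, groups = groups, coils = coils,
                 scheme = scheme, noise_sigma = noise_sigma,
                 bvals = x$bvals, dirs = x$dirs, voxel_size = x$voxel_size),
            class = "kspace_data")
}
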