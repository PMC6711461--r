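# Per-slice, per-volume linear phase estimation and removal via the Fourier
# shift theorem. The phase origin is the grid center (the DC bin of the
# centered DFT), so a ramp of h cycles/FOV moves the spectral peak by exactly
# h integer bins.

#' Estimate the linear phase of one complex slice
#'
#' The ramp is the integer harmonic at the argmax of the magnitude of the
#' centered 2D DFT of the slice (relative to DC) and the offset is the phase
#' of the DFT coefficient at that location — a robust gross approximation of
#' the underlying phase, suitable for low-SNR data.
#'
#' @param slice_image complex 2D array
#' @return list with `hx`, `hy` (integer harmonics, cycles/FOV) and `offset`
#'   (radians)
#' @export
estimate_linear_phase <- function(slice_image) {
  d <- dim(slice_image)
  stopifnot(length(d) == 2)
  if (all(slice_image == 0)) {
    message("all-zero slice: returning zero ramp and offset")
    return(list(hx = 0L, hy = 0L, offset = 0))
  }
  K <- cfft2(array(slice_image, c(d, 1)))[, , 1]
  pk <- arrayInd(which.max(Mod(K)), d)
  ctr <- floor(d / 2) + 1L
  list(hx = as.integer(pk[1] - ctr[1]), hy = as.integer(pk[2] - ctr[2]),
       offset = Arg(K[pk[1], pk[2]]))
}

#' Estimate a linear phase field for every slice and volume
#'
#' @param y a [volume_stack()]
#' @return a `phase_corruption` object holding the estimated field (usable
#'   with [demodulate()] / [remodulate()])
#' @export
estimate_phase_field <- function(y) {
  d <- dim(y$data)
  hx <- matrix(0, d[3], d[4]); hy <- hx; off <- hx
  for (n in seq_len(d[4])) for (z in seq_len(d[3])) {
    e <- estimate_linear_phase(y$data[, , z, n])
    hx[z, n] <- e$hx; hy[z, n] <- e$hy; off[z, n] <- e$offset
  }
  structure(list(hx = hx, hy = hy, offset = off, grid_shape = d[1:3]),
            class = "phase_corruption")
}

#' Remove a linear phase field from a volume stack
#'
#' Elementwise multiplication by the conjugate phase planes; magnitudes are
#' preserved and [remodulate()] is the exact inverse.
#'
#' @param y a [volume_stack()]
#' @param phi a `phase_corruption` (true or estimated field)
#' @return the demodulated stack
#' @export
demodulate <- function(y, phi) {
  stopifnot(inherits(y, "volume_stack"), inherits(phi, "phase_corruption"))
  d <- dim(y$data)
  out <- y$data
  for (n in seq_len(d[4])) for (z in seq_len(d[3])) {
    if (phi$hx[z, n] == 0 && phi$hy[z, n] == 0 && phi$offset[z, n] == 0) next
    out[, , z, n] <- out[, , z, n] *
      Conj(.phase_plane(d[1:2], phi$hx[z, n], phi$hy[z, n], phi$offset[z, n]))
  }
  y$data <- out
  y
}

#' Reapply a linear phase field (inverse of demodulation)
#'
#' @inheritParams demodulate
#' @return the remodulated stack
#' @export
remodulate <- function(y, phi) {
  stopifnot(inherits(phi, "phase_corruption"))
  corrupt_phase(y, phi)
}

#' Export a phase field as a plain-text table
#'
#' Writes one row per (slice, volume) with the harmonics and offset, for
#' audit.
#'
#' @param phi a `phase_corruption`
#' @param path output file path (tab-separated)
#' @return the data frame, invisibly
#' @export
write_phase_table <- function(phi, path) {
  d <- dim(phi$hx)
  df <- data.frame(slice = rep(seq_len(d[1]), d[2]),
                   volume = rep(seq_len(d[2]), each = d[1]),
                   kx = as.vector(phi$hx), ky = as.vector(phi$hy),
                   offset = as.vector(phi$offset))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
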