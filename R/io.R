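# Export helpers: R-native run containers, NIfTI views, and delimited
# tables.

#' Save a simulation/reconstruction container
#'
#' Bundles ground truth, coils, k-space, masks and noise-model metadata into
#' one R-native container file (RDS). The complementary reader restores the
#' named components.
#'
#' @param path output file path
#' @param ... named components (e.g. truth, coils, kspace, noise_model)
#' @return the path, invisibly
#' @export
save_container <- function(path, ...) {
  obj <- list(...)
  stopifnot(length(obj) == 0 || !is.null(names(obj)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)

#' Export a volume stack (or 3D map) as NIfTI
#'
#' Complex stacks are written as a `_real` / `_imag` file pair plus a `_mag`
#' magnitude view; real maps as a single file. Requires the RNifti package.
#'
#' @param x a [volume_stack()] or numeric 3D/4D array
#' @param prefix output path prefix (without extension)
#' @return character vector of files written, invisibly
#' @export
write_nifti <- function(x, prefix) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
  vs <- c(1, 1, 1)
  if (inherits(x, "volume_stack")) {
    vs <- x$voxel_size
    x <- x$data
  }
  files <- character(0)
  wr <- function(arr, suffix) {
    f <- paste0(prefix, suffix, ".nii.gz")
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vs, rep(1, max(0, length(dim(arr)) - 3)))
    RNifti::writeNifti(img, f)
    f
  }
  if (is.complex(x)) {
    files <- c(wr(Re(x), "_real"), wr(Im(x), "_imag"), wr(Mod(x), "_mag"))
  } else {
    files <- wr(x, "")
  }
  invisible(files)
}

#' Scatter per-patch values onto a voxel map
#'
#' Places per-patch scalars (rank, AMSE, sigma estimates) at the patch
#' centers of a layout; other voxels are NA. Useful for map-style exports.
#'
#' @param values numeric per-patch vector
#' @param layout a `patch_layout`
#' @return 3D array
#' @export
patch_value_map <- function(values, layout) {
  stopifnot(length(values) == length(layout$centers))
  out <- array(NA_real_, layout$dims)
  out[layout$centers] <- values
  out
}
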