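#' Diffusion-weighted dataset
#'
#' Container for a 4-D diffusion-weighted image: the signal grid (last axis
#' enumerates frames), its voxel-to-world affine, the gradient table, and an
#' optional binary brain mask on the same spatial grid.
#'
#' @param signal 4-D numeric array; last dimension = acquisition frames.
#' @param affine 4x4 voxel-to-world (RAS+ mm) matrix; must be invertible.
#' @param gtab a [gradient_table()] with as many frames as `signal`.
#' @param mask optional 3-D logical/0-1 array matching the spatial grid.
#' @return an object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, affine, gtab, mask = NULL) {
  stopifnot(is.array(signal), length(dim(signal)) == 4L,
            inherits(gtab, "gradient_table"))
  if (dim(signal)[4L] != length(gtab))
    stop("frame_count_mismatch: image has ", dim(signal)[4L],
         " frames but the gradient table has ", length(gtab), call. = FALSE)
  invert_affine(affine)  # errors if singular
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!all(dim(mask) == dim(signal)[1:3]))
      stop("mask_shape_mismatch: mask does not match the spatial grid",
           call. = FALSE)
  }
  structure(list(signal = signal, affine = affine, gtab = gtab, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_dataset: %d x %d x %d grid, %d frames%s\n",
              d[1L], d[2L], d[3L], d[4L],
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Load a diffusion-weighted dataset from NIfTI + FSL gradient files
#'
#' @param image_path path to a 4-D NIfTI (.nii / .nii.gz).
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @param mask_path optional NIfTI binary mask on the same grid.
#' @param b0_threshold passed to [gradient_table()].
#' @return a [dwi_dataset()].
#' @export
load_dwi <- function(image_path, bval_path, bvec_path, mask_path = NULL,
                     b0_threshold = 50) {
  img <- RNifti::readNifti(image_path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop("image_error: expected a 4-D diffusion image, got ",
         length(dim(a)), "-D", call. = FALSE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  gtab <- load_gradients(bval_path, bvec_path, b0_threshold = b0_threshold)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    mask <- array(m != 0, dim = dim(m)[1:3])
  }
  dwi_dataset(a, affine, gtab, mask)
}

#' Save a diffusion-weighted dataset as NIfTI + FSL gradient files
#'
#' @param dwi a [dwi_dataset()].
#' @param image_path,bval_path,bvec_path output paths.
#' @export
save_dwi <- function(dwi, image_path, bval_path, bvec_path) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  write_nifti_volume(dwi$signal, dwi$affine, image_path)
  save_gradients(dwi$gtab, bval_path, bvec_path)
  invisible(image_path)
}

#' Write a 3-D or 4-D array as NIfTI with a given affine
#'
#' @param vol numeric array (3-D or 4-D).
#' @param affine 4x4 voxel-to-world matrix, stored as the sform.
#' @param path output path (.nii or .nii.gz).
#' @export
write_nifti_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI volume and its affine
#'
#' @param path NIfTI file.
#' @return list with `data` (array) and `affine` (4x4 matrix).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(data = as.array(img), affine = affine)
}
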