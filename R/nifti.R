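#' Read or write PET volumes as NIfTI
#'
#' Thin wrappers around RNifti preserving voxel size; 4D volumes carry
#' frames in the fourth dimension.
#'
#' @param img 3D or 4D numeric array.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param voxdim voxel size in mm per spatial axis.
#' @return `read_pet_volume` returns a plain array with attribute `voxdim`.
#' @export
write_pet_volume <- function(img, path, voxdim = c(2, 2, 2)) {
  nd <- length(dim(img))
  x <- RNifti::asNifti(unclass(img))
  RNifti::pixdim(x) <- if (nd == 4L) c(voxdim, 1) else voxdim
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' @rdname write_pet_volume
#' @export
read_pet_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxdim") <- RNifti::pixdim(img)[1:3]
  out
}
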