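#' Read a 3D volume from a NIfTI file
#'
#' Volumes are expected in LPS orientation (the assumed input standard for
#' skull-stripped, co-registered data). If the file carries no orientation
#' information a warning is emitted and LPS is assumed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach; default taken from the filename.
#' @return a [volume()].
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D volume, got %d dimensions in %s",
                 length(d), path))
  }
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L) {
    warning("no orientation information in ", basename(path),
            "; assuming LPS")
  }
  if (is.null(modality)) {
    modality <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume(array(as.numeric(img), dim = d),
         spacing = RNifti::pixdim(img), modality = modality)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol a [volume()] or a 3D array (masks are written as-is).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing, used when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "bs_volume")) {
    arr <- vol$data
    spacing <- vol$spacing
  } else {
    arr <- as_vol_array(vol)
    storage.mode(arr) <- "double"
  }
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, spacing, 0, 0, 0, 0)))
  # LPS axes: x and y scales negated relative to the NIfTI RAS world frame.
  RNifti::`qform<-`(img, structure(diag(c(-spacing[1], -spacing[2], spacing[3], 1)),
                                   code = 2L)) -> img
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write NIfTI file: ", path)
  invisible(path)
}
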