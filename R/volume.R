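#' Single-modality intensity volume
#'
#' A lightweight container for one modality's 3D intensity grid. The third
#' array axis is the axial (inferior-superior) axis; volumes are assumed
#' skull-stripped and co-registered, in LPS orientation.
#'
#' @param data numeric 3D array of voxel intensities (finite values).
#' @param spacing numeric length-3, mm per voxel along each axis.
#' @param modality modality tag, e.g. `"FLAIR"` or `"T2w"`.
#' @param brain_mask optional binary 3D array matching `data`'s shape.
#' @return an object of class `bs_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), modality = "FLAIR",
                   brain_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array")
  }
  if (!all(is.finite(data))) stop("`data` must contain only finite values")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers")
  }
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(data))) {
      stop("`brain_mask` shape must match `data`")
    }
    storage.mode(brain_mask) <- "integer"
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         modality = as.character(modality), brain_mask = brain_mask),
    class = "bs_volume"
  )
}

#' @export
print.bs_volume <- function(x, ...) {
  cat(sprintf("<bs_volume> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.bs_volume <- function(x) dim(x$data)

# Coerce volumes or arrays to a plain 3D array.
as_vol_array <- function(x) {
  if (inherits(x, "bs_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("expected a bs_volume or a 3D array")
}

# Validate a binary mask array (0/1 or logical); returns an integer array.
as_mask_array <- function(x, what = "mask") {
  m <- as_vol_array(x)
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) {
    stop(sprintf("`%s` must be binary (0/1)", what))
  }
  storage.mode(m) <- "integer"
  m
}
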