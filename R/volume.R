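#' CT volume and tumor mask containers
#'
#' A `ct_volume` holds one contrast phase of a CE-CT acquisition: a 3D array of
#' attenuation values in Hounsfield units (HU), the voxel spacing in mm, the
#' phase label and the acquisition time in seconds after contrast injection.
#' A `tumor_mask` holds the binary tumor segmentation aligned to the volumes of
#' the same subject.
#'
#' World coordinates follow the convention `position = (index - 1) * spacing`
#' with 0-based voxel centers, i.e. the first voxel center sits at the origin.
#'
#' @param grid 3D numeric (HU) or logical array.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly positive.
#' @param phase One of `"precontrast"`, `"portal_venous"`, `"delayed"`.
#' @param acquisition_time Seconds since contrast injection.
#' @return `ct_volume()` returns an object of class `rccad_volume`;
#'   `tumor_mask()` an object of class `rccad_mask`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2.5))
#' dim(v$grid)
#' @export
ct_volume <- function(grid, spacing = c(1, 1, 1), phase = "portal_venous",
                      acquisition_time = default_phase_time(phase)) {
  check_grid3d(grid)
  check_spacing(spacing)
  phase <- match.arg(phase, c("precontrast", "portal_venous", "delayed"))
  structure(
    list(grid = grid, spacing = as.numeric(spacing), phase = phase,
         acquisition_time = as.numeric(acquisition_time)),
    class = "rccad_volume"
  )
}

#' @rdname ct_volume
#' @export
tumor_mask <- function(grid, spacing = c(1, 1, 1)) {
  check_grid3d(grid)
  check_spacing(spacing)
  g <- array(as.logical(grid), dim(grid))
  if (!any(g)) abort("tumor mask has no foreground voxel")
  ncomp <- cpp_n_components(g, dim(g))
  if (ncomp != 1L) {
    abort(sprintf("tumor mask foreground must be a single 26-connected component (found %d)", ncomp))
  }
  structure(list(grid = g, spacing = as.numeric(spacing)), class = "rccad_mask")
}

default_phase_time <- function(phase) {
  switch(phase, precontrast = 0, portal_venous = 80, delayed = 300)
}

check_grid3d <- function(grid) {
  if (is.null(dim(grid)) || length(dim(grid)) != 3L) {
    abort("expected 3D volume")
  }
  if (any(dim(grid) < 1L)) abort("grid dimensions must all be >= 1")
  invisible(grid)
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("spacing must be three strictly positive voxel sizes (mm)")
  }
  invisible(spacing)
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$grid), dim(mask$grid))) {
    abort("volume and mask dimensions differ")
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    abort("volume and mask spacing differ")
  }
  invisible(TRUE)
}

#' @export
print.rccad_volume <- function(x, ...) {
  cat(sprintf("<CE-CT volume> %s phase, t = %gs, %s voxels @ %s mm\n",
              x$phase, x$acquisition_time,
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.rccad_mask <- function(x, ...) {
  cat(sprintf("<tumor mask> %s voxels @ %s mm, %d foreground\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              sum(x$grid)))
  invisible(x)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()].
#' Integer-typed files round-trip bit-exact.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param phase,acquisition_time Passed to [ct_volume()].
#' @return `read_ct_volume()` a `rccad_volume`; `read_tumor_mask()` a
#'   `rccad_mask`.
#' @export
read_ct_volume <- function(path, phase = "portal_venous",
                           acquisition_time = default_phase_time(phase)) {
  img <- read_nifti3d(path)
  ct_volume(img$grid, img$spacing, phase = phase,
            acquisition_time = acquisition_time)
}

#' @rdname read_ct_volume
#' @export
read_tumor_mask <- function(path) {
  img <- read_nifti3d(path)
  tumor_mask(img$grid != 0, img$spacing)
}

read_nifti3d <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort("expected 3D volume")
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) || any(spacing[1:3] <= 0)) {
    abort("NIfTI header field pixdim must hold three positive voxel sizes")
  }
  list(grid = array(as.vector(img), dim(img)), spacing = as.numeric(spacing[1:3]))
}

#' @rdname read_ct_volume
#' @param x A `rccad_volume` or `rccad_mask`.
#' @export
write_nifti_volume <- function(x, path) {
  grid <- if (inherits(x, "rccad_mask")) array(as.integer(x$grid), dim(x$grid)) else x$grid
  datatype <- if (all(grid == round(grid)) && max(abs(grid)) < 32767) "int16" else "double"
  img <- RNifti::asNifti(grid, reference = list(pixdim = c(-1, x$spacing, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Stack per-slice 2D ROIs into a 3D tumor mask
#'
#' Reconstructs the 3D tumor object from an ordered list of axial 2D
#' delineations, the way per-slice expert segmentations are combined.
#'
#' @param roi_slices List of 2D logical/0-1 matrices, ascending axial position.
#' @param spacing Voxel size in mm (x, y, z).
#' @return A `rccad_mask`.
#' @examples
#' sq <- matrix(0, 8, 8); sq[2:6, 2:6] <- 1
#' m <- stack_rois(list(sq, sq, sq), spacing = c(1, 1, 2.5))
#' sum(m$grid)
#' @export
stack_rois <- function(roi_slices, spacing = c(1, 1, 1)) {
  if (!length(roi_slices)) abort("no ROI slices supplied")
  dims <- lapply(roi_slices, dim)
  if (any(vapply(dims, is.null, logical(1)))) abort("each ROI slice must be a 2D matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    abort("ROI slices have inconsistent in-plane dimensions")
  }
  grid <- array(FALSE, c(dims[[1]], length(roi_slices)))
  for (k in seq_along(roi_slices)) grid[, , k] <- as.logical(roi_slices[[k]])
  if (!any(grid)) abort("all ROI slices are empty")
  tumor_mask(grid, spacing)
}
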