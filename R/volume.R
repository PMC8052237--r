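#' Voxel volumes in Hounsfield units
#'
#' An `hu_volume` is a 3D numeric array of CT attenuation values in
#' Hounsfield units (HU; air ~ -1000, water 0) with voxel spacing in mm
#' and anatomical orientation labels.  The package convention, used by
#' all phantoms, is axis 1 = right-to-left (index increasing towards the
#' subject's left), axis 2 = anterior-to-posterior, axis 3 =
#' inferior-to-superior.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing voxel edge length(s) in mm; length 1 (isotropic) or 3.
#' @param orientation character vector of length 3 naming each axis; must
#'   be a permutation of `c("LR", "AP", "IS")`.
#' @return An `hu_volume` object (array with `spacing` and `orientation`
#'   attributes).
#' @export
hu_volume <- function(values, spacing, orientation = c("LR", "AP", "IS")) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive (mm per voxel)")
  if (!setequal(orientation, c("LR", "AP", "IS")) || length(orientation) != 3L)
    stop("orientation must name LR, AP and IS exactly once")
  structure(values,
            spacing = as.numeric(spacing),
            orientation = orientation,
            class = c("hu_volume", "array"))
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %s mm (%s)\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = " x "),
              paste(attr(x, "orientation"), collapse = "/")))
  cat(sprintf("  HU range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of a volume or mask
#' @param x an `hu_volume` or any object carrying a `spacing` attribute.
#' @return numeric length-3 vector, mm per voxel.
#' @export
voxel_spacing <- function(x) {
  s <- attr(x, "spacing")
  if (is.null(s)) stop("object has no spacing attribute")
  s
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()].
#' Voxel spacing is taken from (written to) the NIfTI pixdim field.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param orientation axis labels to attach on read (the file is assumed
#'   to follow the package axis convention).
#' @return `read_volume_nifti` returns an `hu_volume`;
#'   `write_volume_nifti` returns `path` invisibly.
#' @export
read_volume_nifti <- function(path, orientation = c("LR", "AP", "IS")) {
  img <- RNifti::readNifti(path)
  hu_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3],
            orientation = orientation)
}

#' @rdname read_volume_nifti
#' @param vol an `hu_volume` (or numeric/logical array with a `spacing`
#'   attribute) to write.
#' @export
write_volume_nifti <- function(vol, path) {
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- voxel_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# internal: linear index <-> (i,j,k) helpers for 3D arrays
.grid_index <- function(dim, i, j, k) {
  as.integer(i + dim[1] * ((j - 1) + dim[2] * (k - 1)))
}

.index_to_ijk <- function(dim, idx) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i + 1L, j + 1L, k + 1L)
}
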