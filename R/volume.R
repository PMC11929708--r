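#' Construct a 3D scalar volume
#'
#' A `fissure_volume` is the basic image container of the pipeline: a 3D
#' scalar grid (CT intensities in Hounsfield units or normalized values)
#' together with its voxel spacing in millimetres and its physical origin.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, millimetres per voxel along each axis;
#'   must be strictly positive.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `fissure_volume`.
#' @export
new_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) {
    stop_fmt("volume must be a 3D array, got %d dimension(s)",
             length(dim(voxels)))
  }
  if (any(dim(voxels) < 2L)) stop_fmt("volume shape must be >= 2 per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_fmt("spacing must be 3 strictly positive numbers")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "fissure_volume")
}

#' @export
print.fissure_volume <- function(x, ...) {
  cat(sprintf("<fissure_volume %s, spacing %s mm, range [%.3g, %.3g]>\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `load_volume` returns a [new_volume()] object.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L]
  if (length(dim(a)) != 3L) {
    stop_fmt("expected a 3D NIfTI image, got %dD", length(dim(a)))
  }
  hdr <- RNifti::niftiHeader(img)
  new_volume(a, spacing = hdr$pixdim[2:4],
             origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

#' @rdname load_volume
#' @param vol a [new_volume()] object.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fissure_volume"))
  img <- RNifti::asNifti(vol$voxels)
  hdr <- RNifti::niftiHeader(img)
  hdr$pixdim[2:4] <- vol$spacing
  hdr$qform_code <- 1L
  hdr$quatern_b <- 0; hdr$quatern_c <- 0; hdr$quatern_d <- 0
  hdr$qoffset_x <- vol$origin[1]
  hdr$qoffset_y <- vol$origin[2]
  hdr$qoffset_z <- vol$origin[3]
  img <- RNifti::asNifti(vol$voxels, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Window and normalize CT intensities to [0, 1]
#'
#' Clips intensities to the window `[low, high]` (default a lung window of
#' -1000 to 600 HU) and maps the window affinely onto `[0, 1]`. A fixed
#' window keeps patch features comparable across cases.
#'
#' @param vol a [new_volume()].
#' @param window numeric length-2 `(low, high)` in HU, `low < high`.
#' @return a volume with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, window = c(-1000, 600)) {
  stopifnot(inherits(vol, "fissure_volume"))
  low <- window[1]; high <- window[2]
  if (!(low < high)) stop_fmt("degenerate intensity window [%g, %g]", low, high)
  v <- pmin(pmax(vol$voxels, low), high)
  vol$voxels <- (v - low) / (high - low)
  vol
}

#' Voxel index to normalized coordinates
#'
#' Maps 0-based voxel indices onto the cube `[-1, 1]^3` per axis:
#' `c = 2 * i / (shape - 1) - 1`. The index lattice, not physical
#' millimetres, is normalized; spacing is only reapplied when distances are
#' reported in mm.
#'
#' @param indices n x 3 matrix of 0-based voxel indices.
#' @param shape integer length-3 grid shape.
#' @return n x 3 matrix with entries in `[-1, 1]`.
#' @export
voxel_to_norm <- function(indices, shape) {
  indices <- rbind(indices)
  if (any(indices < 0) ||
      any(sweep(indices, 2, shape - 1, `>`))) {
    stop_fmt("voxel index out of range for shape %s",
             paste(shape, collapse = "x"))
  }
  sweep(sweep(indices, 2, (shape - 1) / 2, `/`), 2, 1, `-`)
}

#' @rdname voxel_to_norm
#' @param coords n x 3 matrix of normalized coordinates in `[-1, 1]`.
#' @export
norm_to_voxel <- function(coords, shape) {
  coords <- rbind(coords)
  idx <- sweep(sweep(coords, 2, 1, `+`), 2, (shape - 1) / 2, `*`)
  round(idx)
}

# Pad a 3D array by `r` voxels on every side with edge replication.
pad_replicate <- function(a, r) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1] + 2 * r) - r, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * r) - r, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * r) - r, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

#' Extract flattened intensity patches around voxels
#'
#' For each 0-based voxel index, the 5x5x5 neighborhood of normalized
#' intensities is flattened (x-fastest order, a frozen convention) into a
#' 125-dimensional feature row. Voxels outside the grid are filled by edge
#' replication so the lung border introduces no artificial intensity step.
#'
#' @param vol a volume with intensities in `[0, 1]` (see
#'   [normalize_intensity()]).
#' @param indices n x 3 matrix of 0-based voxel indices.
#' @param size odd patch edge length (default 5).
#' @return n x `size^3` feature matrix.
#' @export
extract_patch_features <- function(vol, indices, size = 5L) {
  stopifnot(inherits(vol, "fissure_volume"), size %% 2L == 1L)
  indices <- rbind(indices)
  d <- dim(vol$voxels)
  if (any(indices < 0) || any(sweep(indices, 2, d - 1, `>`))) {
    stop_fmt("patch index out of range")
  }
  r <- (size - 1L) %/% 2L
  pad <- pad_replicate(vol$voxels, r)
  dp <- dim(pad)
  n <- nrow(indices)
  # centre positions in the padded array (1-based)
  cx <- indices[, 1] + r + 1L
  cy <- indices[, 2] + r + 1L
  cz <- indices[, 3] + r + 1L
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)  # x fastest
  feat <- matrix(0, n, size^3)
  for (j in seq_len(nrow(offs))) {
    lin <- (cx + offs$dx[j]) +
      dp[1] * (cy + offs$dy[j] - 1L) +
      dp[1] * dp[2] * (cz + offs$dz[j] - 1L)
    feat[, j] <- pad[lin]
  }
  feat
}
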