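#' Define a common analysis voxel grid
#'
#' A `volume_grid` pins the geometry every volumetric object in the package
#' shares: the voxel counts along each axis and the 4x4 affine mapping
#' 0-based voxel indices `(i, j, k)` to world (mm) coordinates, as in the
#' NIfTI-1 sform convention.
#'
#' @param dim integer vector of length 3, voxel counts `(nx, ny, nz)`.
#' @param affine numeric 4x4 voxel-index-to-mm matrix; its upper-left 3x3
#'   block must be invertible. Defaults to a 3 mm isotropic grid centred on
#'   the world origin, the resolution the analysis pipeline assumes.
#' @return An object of class `volume_grid` with elements `dim`, `affine`
#'   and the derived `voxel_size` (mm per axis).
#' @examples
#' g <- volume_grid(c(30, 36, 30))
#' g$voxel_size
#' @export
volume_grid <- function(dim, affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L))
  if (is.null(affine)) {
    affine <- diag(c(3, 3, 3, 1))
    affine[1:3, 4] <- -(dim - 1L) / 2 * 3
  }
  affine <- as.matrix(affine)
  stopifnot(identical(base::dim(affine), c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("grid affine is singular")
  structure(
    list(
      dim = dim,
      affine = affine,
      voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))
    ),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels, voxel size %s mm\n",
    x$dim[1], x$dim[2], x$dim[3],
    paste(signif(x$voxel_size, 4), collapse = " x ")
  ))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("%dx%dx%d@%smm", x$dim[1], x$dim[2], x$dim[3],
          paste(signif(x$voxel_size, 4), collapse = "x"))
}

same_grid <- function(a, b) {
  identical(a$dim, b$dim) && isTRUE(all.equal(a$affine, b$affine,
                                              tolerance = 1e-8))
}

check_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (%s vs %s)",
                 what, format(a), format(b)))
  invisible(TRUE)
}

n_voxels <- function(grid) prod(grid$dim)

#' Convert world (mm) coordinates to voxel indices
#'
#' Applies the inverse of the grid affine and rounds to the nearest voxel.
#' Indices are 0-based. Coordinates whose nearest voxel falls outside the
#' grid are flagged, never silently clipped.
#'
#' @param coords numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @param grid a [volume_grid()].
#' @return Integer matrix (n x 3) of 0-based voxel indices with a logical
#'   attribute `"in_grid"` marking rows that fall inside the grid.
#' @seealso [voxel_to_mm()]
#' @export
mm_to_voxel <- function(coords, grid) {
  coords <- coord_matrix(coords)
  inv <- solve(grid$affine)
  hom <- cbind(coords, 1) %*% t(inv)
  idx <- round(hom[, 1:3, drop = FALSE])
  in_grid <- idx[, 1] >= 0 & idx[, 1] < grid$dim[1] &
    idx[, 2] >= 0 & idx[, 2] < grid$dim[2] &
    idx[, 3] >= 0 & idx[, 3] < grid$dim[3]
  storage.mode(idx) <- "integer"
  dimnames(idx) <- list(NULL, c("i", "j", "k"))
  attr(idx, "in_grid") <- as.logical(in_grid)
  idx
}

#' Convert 0-based voxel indices to world (mm) coordinates
#'
#' @param idx integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @inheritParams mm_to_voxel
#' @return Numeric matrix (n x 3) of mm coordinates of the voxel centres.
#' @export
voxel_to_mm <- function(idx, grid) {
  idx <- coord_matrix(idx)
  out <- cbind(idx, 1) %*% t(grid$affine)
  out <- out[, 1:3, drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  storage.mode(x) <- "double"
  x
}

# column-major linear index (1-based) of 0-based voxel triplets
voxel_linear_index <- function(idx, grid) {
  idx <- coord_matrix(idx)
  as.integer(1 + idx[, 1] + grid$dim[1] * (idx[, 2] + grid$dim[2] * idx[, 3]))
}

# mm coordinates of every voxel centre, cached per call site via the three
# axis coordinate vectors (cheap: outer sums, no n_voxels x 3 matmul)
grid_axis_mm <- function(grid) {
  A <- grid$affine
  list(
    x = lapply(1:3, function(a) A[a, 1] * (seq_len(grid$dim[1]) - 1)),
    y = lapply(1:3, function(a) A[a, 2] * (seq_len(grid$dim[2]) - 1)),
    z = lapply(1:3, function(a) A[a, 3] * (seq_len(grid$dim[3]) - 1) + A[a, 4])
  )
}

#' Create a binary mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param voxels logical array with `dim = grid$dim` (or a logical vector of
#'   length `prod(grid$dim)` in column-major order).
#' @return An object of class `binary_mask` with elements `grid` and `vox`.
#' @export
binary_mask <- function(grid, voxels) {
  if (is.null(dim(voxels))) dim(voxels) <- grid$dim
  stopifnot(is.logical(voxels), identical(dim(voxels), as.integer(grid$dim)))
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  structure(list(grid = grid, vox = voxels), class = "binary_mask")
}

#' Number of voxels set in a binary mask
#' @param mask a [binary_mask()].
#' @return Integer count of `TRUE` voxels.
#' @export
mask_size <- function(mask) sum(mask$vox)

# 1-based linear indices of the voxels set in a mask
mask_which <- function(mask) which(mask$vox)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<%s> %d / %d voxels on %s\n", class(x)[1], mask_size(x),
              n_voxels(x$grid), format(x$grid)))
  invisible(x)
}

#' Read a NIfTI volume as a mask, label volume or grid
#'
#' `read_mask` binarises a NIfTI volume (non-zero = in mask);
#' `read_labels` reads an integer label volume; both carry the file's
#' sform/qform as the grid affine.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return `read_mask`: a [binary_mask()]; `read_labels`: a list with
#'   `grid` and integer array `labels`.
#' @export
read_mask <- function(path) {
  im <- RNifti::readNifti(path)
  grid <- grid_from_nifti(im)
  binary_mask(grid, array(as.vector(im) != 0, dim = grid$dim))
}

#' @rdname read_mask
#' @export
read_labels <- function(path) {
  im <- RNifti::readNifti(path)
  grid <- grid_from_nifti(im)
  list(grid = grid,
       labels = array(as.integer(round(as.vector(im))), dim = grid$dim))
}

grid_from_nifti <- function(im) {
  d <- dim(im)
  aff <- RNifti::xform(im)
  attributes(aff) <- list(dim = dim(aff))
  volume_grid(d[1:3], affine = aff)
}

#' Write a volumetric object to NIfTI-1
#'
#' Masks are written as uint8, label volumes as int16 and real-valued maps
#' as float32, each carrying the grid affine as sform and qform.
#'
#' @param x a [binary_mask()], [probability_map], [group_stat_map] or plain
#'   numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid required when `x` is a plain array.
#' @param datatype NIfTI datatype string passed to [RNifti::writeNifti()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL, datatype = "auto") {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$vox), dim = x$grid$dim)
    grid <- x$grid
    if (identical(datatype, "auto")) datatype <- "uint8"
  } else if (inherits(x, c("probability_map", "group_stat_map"))) {
    field <- if (inherits(x, "probability_map")) x$prob else x$t
    arr <- array(as.numeric(field), dim = x$grid$dim)
    grid <- x$grid
    if (identical(datatype, "auto")) datatype <- "float"
  } else {
    stopifnot(!is.null(grid))
    arr <- array(as.numeric(x), dim = grid$dim)
    if (identical(datatype, "auto")) datatype <- "float"
  }
  im <- RNifti::asNifti(
    arr,
    reference = list(pixdim = c(-1, grid$voxel_size, 0, 0, 0, 0)),
    datatype = datatype)
  im <- RNifti::`sform<-`(im, structure(grid$affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}
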