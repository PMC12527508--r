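#' Parse a contrast coordinate table
#'
#' Reads a delimited text table of reported peak coordinates, one row per
#' peak, and groups rows into contrast records. The table must have a header
#' naming the columns `study_id, contrast_id, disorder, modality, space, x,
#' y, z` (tab- or comma-delimited; the delimiter is sniffed from the
#' header). `disorder` must be `SZ` or `BD`, `modality` `functional` or
#' `structural`, `space` `MNI` or `TAL`.
#'
#' @param path path to the delimited text file.
#' @return A list of `contrast_record` objects, each with fields
#'   `study_id`, `contrast_id`, `disorder`, `modality`, `space` and `peaks`
#'   (an n x 3 numeric matrix of mm coordinates in the stated space, row
#'   order as in the file).
#' @export
parse_contrast_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("contrast table is empty: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = FALSE, comment.char = "")
  required <- c("study_id", "contrast_id", "disorder", "modality",
                "space", "x", "y", "z")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("contrast table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop("contrast table has no data rows: ", path)

  for (ax in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[ax]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      # +1 for the header row so the number matches the file line
      stop(sprintf("non-numeric %s coordinate at line %d: '%s'",
                   ax, bad[1] + 1L, tab[[ax]][bad[1]]))
    tab[[ax]] <- v
  }
  check_enum <- function(col, allowed) {
    bad <- !tab[[col]] %in% allowed
    if (any(bad))
      stop(sprintf("invalid %s value '%s' at line %d (allowed: %s)",
                   col, tab[[col]][which(bad)[1]], which(bad)[1] + 1L,
                   paste(allowed, collapse = ", ")))
  }
  check_enum("disorder", c("SZ", "BD"))
  check_enum("modality", c("functional", "structural"))
  check_enum("space", c("MNI", "TAL"))

  ids <- unique(tab$contrast_id)
  records <- lapply(ids, function(id) {
    rows <- tab[tab$contrast_id == id, , drop = FALSE]
    meta <- c("study_id", "disorder", "modality", "space")
    for (m in meta)
      if (length(unique(rows[[m]])) != 1L)
        stop(sprintf("contrast '%s' has inconsistent %s values", id, m))
    contrast_record(
      study_id = rows$study_id[1], contrast_id = id,
      disorder = rows$disorder[1], modality = rows$modality[1],
      space = rows$space[1],
      peaks = as.matrix(rows[, c("x", "y", "z")])
    )
  })
  names(records) <- ids
  records
}

#' Construct a contrast record
#'
#' One reported group-difference contrast with its peak coordinates.
#'
#' @param study_id,contrast_id identifier strings.
#' @param disorder `"SZ"` or `"BD"`.
#' @param modality `"functional"` or `"structural"`.
#' @param space `"MNI"` or `"TAL"`.
#' @param peaks n x 3 numeric matrix of peak coordinates in mm.
#' @return An object of class `contrast_record`.
#' @export
contrast_record <- function(study_id, contrast_id, disorder, modality,
                            space, peaks) {
  peaks <- coord_matrix(peaks)
  if (nrow(peaks) == 0L) stop("contrast must have at least one peak")
  if (!all(is.finite(peaks))) stop("peak coordinates must be finite")
  stopifnot(disorder %in% c("SZ", "BD"),
            modality %in% c("functional", "structural"),
            space %in% c("MNI", "TAL"))
  dimnames(peaks) <- list(NULL, c("x", "y", "z"))
  structure(list(study_id = as.character(study_id),
                 contrast_id = as.character(contrast_id),
                 disorder = disorder, modality = modality, space = space,
                 peaks = peaks),
            class = "contrast_record")
}

#' @export
print.contrast_record <- function(x, ...) {
  cat(sprintf("<contrast_record> %s (%s, %s, %s): %d peak(s)\n",
              x$contrast_id, x$disorder, x$modality, x$space,
              nrow(x$peaks)))
  invisible(x)
}

# Lancaster et al. (2007) best-fit affine taking ICBM/MNI coordinates (as
# produced by SPM normalisation) to Talairach space. The Talairach-to-MNI
# conversion applies its inverse, as in the reference tal2icbm_spm tool.
ICBM_SPM2TAL <- matrix(c(
  0.9254,  0.0024, -0.0118, -1.0207,
 -0.0048,  0.9316, -0.0871, -1.7667,
  0.0152,  0.0883,  0.8924,  4.0926,
  0,       0,       0,       1), nrow = 4, byrow = TRUE)

#' Convert Talairach coordinates to MNI space
#'
#' The default method applies the inverse of the Lancaster `icbm_spm2tal`
#' affine (the current best-practice transform for coordinates reported by
#' SPM-normalised studies). `method = "brett"` uses the older Brett
#' piecewise transform, with the branch chosen by the sign of the
#' Talairach z coordinate.
#'
#' @param coords n x 3 matrix (or length-3 vector) of Talairach mm
#'   coordinates.
#' @param method `"lancaster"` (default) or `"brett"`.
#' @return n x 3 matrix of MNI mm coordinates.
#' @export
tal_to_mni <- function(coords, method = c("lancaster", "brett")) {
  method <- match.arg(method)
  coords <- coord_matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  out <- if (method == "lancaster") {
    cbind(coords, 1) %*% t(solve(ICBM_SPM2TAL))
  } else {
    rotn <- diag(4)
    rotn[2:3, 2:3] <- matrix(c(cos(0.05),  sin(0.05),
                               -sin(0.05), cos(0.05)), 2, byrow = TRUE)
    upz <- diag(c(0.99, 0.97, 0.92, 1))
    downz <- diag(c(0.99, 0.97, 0.84, 1))
    up <- solve(rotn %*% upz)
    down <- solve(rotn %*% downz)
    hom <- cbind(coords, 1)
    below <- coords[, 3] < 0
    res <- hom
    if (any(!below)) res[!below, ] <- hom[!below, , drop = FALSE] %*% t(up)
    if (any(below)) res[below, ] <- hom[below, , drop = FALSE] %*% t(down)
    res
  }
  out <- out[, 1:3, drop = FALSE]
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Harmonise a contrast record to MNI space
#'
#' Records already in MNI space are returned unchanged (identity); records
#' in Talairach space have their peaks converted with [tal_to_mni()].
#'
#' @param record a [contrast_record()].
#' @inheritParams tal_to_mni
#' @return The record with `space = "MNI"`.
#' @export
harmonize_space <- function(record, method = c("lancaster", "brett")) {
  stopifnot(inherits(record, "contrast_record"))
  if (record$space == "MNI") return(record)
  record$peaks <- tal_to_mni(record$peaks, method = match.arg(method))
  record$space <- "MNI"
  record
}

#' Build the merged spherical seed mask of a contrast
#'
#' Places a sphere of radius `radius_mm` at each peak of the contrast,
#' takes their union and intersects with the brain mask. Sphere membership
#' is Euclidean distance from the voxel centre to the peak, in mm. Peaks
#' whose nearest voxel falls outside the brain mask are dropped with a
#' warning; if all peaks drop, or the merged sphere contains no in-brain
#' voxel, an error names the contrast.
#'
#' @param record a [contrast_record()] already in MNI space.
#' @param radius_mm sphere radius in mm (default 4).
#' @param grid the analysis [volume_grid()].
#' @param brain [binary_mask()] of in-brain voxels on `grid`.
#' @return A `seed_mask` (a [binary_mask()] with extra fields
#'   `contrast_id` and `radius_mm`).
#' @export
build_contrast_seed <- function(record, radius_mm = 4, grid, brain) {
  stopifnot(inherits(record, "contrast_record"), radius_mm > 0)
  if (record$space != "MNI")
    stop("contrast '", record$contrast_id,
         "' must be harmonised to MNI space first")
  check_same_grid(grid, brain$grid, "grid and brain mask")

  nearest <- mm_to_voxel(record$peaks, grid)
  in_grid <- attr(nearest, "in_grid")
  in_brain <- rep(FALSE, nrow(nearest))
  if (any(in_grid))
    in_brain[in_grid] <- brain$vox[
      voxel_linear_index(nearest[in_grid, , drop = FALSE], grid)]
  if (any(!in_brain))
    warning(sprintf("contrast '%s': dropping %d peak(s) outside the brain mask",
                    record$contrast_id, sum(!in_brain)))
  peaks <- record$peaks[in_brain, , drop = FALSE]
  if (nrow(peaks) == 0L)
    stop(sprintf("empty seed for contrast '%s': all peaks outside the brain mask",
                 record$contrast_id))

  vox <- sphere_union(peaks, radius_mm, grid) & brain$vox
  if (!any(vox))
    stop(sprintf("empty seed for contrast '%s': no in-brain voxel within %g mm of any peak",
                 record$contrast_id, radius_mm))
  m <- binary_mask(grid, vox)
  m$contrast_id <- record$contrast_id
  m$radius_mm <- radius_mm
  class(m) <- c("seed_mask", class(m))
  m
}

# union of spheres over peak rows; bounding-box scan per peak
sphere_union <- function(peaks, radius_mm, grid) {
  vox <- array(FALSE, dim = grid$dim)
  inv <- solve(grid$affine)
  # conservative index halo: radius divided by the smallest voxel extent
  halo <- ceiling(radius_mm / min(grid$voxel_size)) + 1L
  for (p in seq_len(nrow(peaks))) {
    centre <- peaks[p, ]
    ijk0 <- (inv %*% c(centre, 1))[1:3]
    lo <- pmax(floor(ijk0) - halo, 0)
    hi <- pmin(ceiling(ijk0) + halo, grid$dim - 1L)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    mm <- voxel_to_mm(box, grid)
    d2 <- (mm[, 1] - centre[1])^2 + (mm[, 2] - centre[2])^2 +
      (mm[, 3] - centre[3])^2
    inside <- d2 <= radius_mm^2
    if (any(inside))
      vox[voxel_linear_index(box[inside, , drop = FALSE], grid)] <- TRUE
  }
  vox
}
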