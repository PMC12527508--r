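#' Mean time course over a seed mask
#'
#' @param bold a [bold_series()].
#' @param seed a non-empty [binary_mask()] (typically a seed mask from
#'   [build_contrast_seed()]) on the same grid.
#' @return Numeric vector, the unweighted mean over seed voxels at each
#'   timepoint.
#' @export
seed_timecourse <- function(bold, seed) {
  check_same_grid(bold$grid, seed$grid, "BOLD and seed")
  idx <- mask_which(seed)
  if (length(idx) == 0L) stop("empty seed mask")
  rowMeans(bold$data[, idx, drop = FALSE])
}

#' Seed-to-whole-brain functional connectivity map
#'
#' Pearson correlation between the seed mean time course and every
#' in-brain voxel time course, Fisher z-transformed (`atanh`). Correlations
#' are clamped to `|r| <= 1 - 1e-7` before the transform so that voxels
#' inside the seed itself stay finite. Voxels with zero temporal variance,
#' and voxels outside the brain mask, are marked invalid (`NA`).
#'
#' @inheritParams seed_timecourse
#' @param brain [binary_mask()] restricting the map.
#' @return An object of class `fc_map`: grid, per-voxel `z` (NA where
#'   invalid), `subject_id`, `contrast_id`.
#' @export
fc_map <- function(bold, seed, brain) {
  s <- seed_timecourse(bold, seed)
  if (n_timepoints(bold) < 3L) stop("need at least 3 timepoints")
  if (stats::sd(s) == 0) stop("seed time course is constant")
  check_same_grid(bold$grid, brain$grid, "BOLD and brain mask")
  bidx <- mask_which(brain)
  r <- fast_cor(bold$data[, bidx, drop = FALSE], s)
  z <- rep(NA_real_, n_voxels(bold$grid))
  z[bidx] <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  structure(list(grid = bold$grid, z = z, subject_id = bold$subject_id,
                 contrast_id = if (is.null(seed$contrast_id)) NA_character_
                               else seed$contrast_id),
            class = "fc_map")
}

# correlation of each column of X with vector s; NA for zero-variance
# columns. With s centred, crossprod(X, s) is already the covariance
# numerator, so X itself never needs to be centred (one pass, no copy).
fast_cor <- function(X, s, xc = NULL, xs = NULL) {
  tp <- length(s)
  s <- s - mean(s)
  ss <- sqrt(sum(s^2))
  if (is.null(xc)) xc <- colMeans(X)
  if (is.null(xs)) xs <- sqrt(pmax(colSums(X^2) - tp * xc^2, 0))
  r <- as.vector(crossprod(X, s)) / (xs * ss)
  # roundoff floor for exactly-constant columns
  degenerate <- xs <= 10 * sqrt(tp * .Machine$double.eps) * (abs(xc) + 1)
  r[degenerate | !is.finite(r)] <- NA_real_
  r
}

#' Compute one subject's FC maps for many contrast seeds
#'
#' Equivalent to calling [fc_map()] per seed but shares the per-voxel
#' centring and scale computations across seeds, which dominates the cost
#' on full-size grids.
#'
#' @inheritParams fc_map
#' @param seeds list of seed masks.
#' @return List of `fc_map` objects, one per seed, in order.
#' @export
fc_maps_for_subject <- function(bold, seeds, brain) {
  if (n_timepoints(bold) < 3L) stop("need at least 3 timepoints")
  check_same_grid(bold$grid, brain$grid, "BOLD and brain mask")
  tp <- n_timepoints(bold)
  bidx <- mask_which(brain)
  X <- bold$data[, bidx, drop = FALSE]
  xc <- colMeans(X)
  xs <- sqrt(pmax(colSums(X^2) - tp * xc^2, 0))
  lapply(seeds, function(seed) {
    check_same_grid(bold$grid, seed$grid, "BOLD and seed")
    s <- rowMeans(bold$data[, mask_which(seed), drop = FALSE])
    if (stats::sd(s) == 0)
      stop("seed time course is constant (contrast '",
           seed$contrast_id, "')")
    r <- fast_cor(X, s, xc = xc, xs = xs)
    z <- rep(NA_real_, n_voxels(bold$grid))
    z[bidx] <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
    structure(list(grid = bold$grid, z = z, subject_id = bold$subject_id,
                   contrast_id = if (is.null(seed$contrast_id))
                     NA_character_ else seed$contrast_id),
              class = "fc_map")
  })
}

#' Voxelwise one-sample t-test over subject FC maps
#'
#' Tests the mean Fisher-z connectivity against zero at every voxel:
#' `t = mean(z) / (sd(z) / sqrt(n))` with the sample (n - 1) standard
#' deviation; degrees of freedom `n - 1`. Voxels that are invalid in any
#' subject, or whose across-subject standard deviation is zero, are marked
#' invalid rather than given infinite t.
#'
#' @param maps list of `fc_map` objects on identical grids (>= 3).
#' @return An object of class `group_stat_map`: grid, per-voxel `t`
#'   (`NA` where invalid), `df = n - 1`, `n`.
#' @export
group_ttest <- function(maps) {
  n <- length(maps)
  if (n < 3L) stop("need at least 3 subject maps")
  grid <- maps[[1]]$grid
  for (m in maps[-1]) check_same_grid(grid, m$grid, "subject maps")
  Z <- vapply(maps, `[[`, numeric(n_voxels(grid)), "z")
  mu <- rowMeans(Z)
  sdv <- sqrt(pmax(rowSums((Z - mu)^2), 0) / (n - 1))
  tval <- mu / (sdv / sqrt(n))
  tval[!is.finite(tval)] <- NA_real_
  structure(list(grid = grid, t = tval, df = n - 1L, n = n),
            class = "group_stat_map")
}

#' Benjamini-Hochberg selection of significant p-values
#'
#' Step-up FDR control at level `q`; returns which hypotheses are
#' rejected.
#'
#' @param p numeric vector of p-values.
#' @param q FDR level in (0, 1).
#' @return Logical vector, `TRUE` for rejected (significant) hypotheses.
#' @export
bh_reject <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 1, all(is.finite(p)), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH") <= q
}

#' Threshold a group t map by voxel-level FDR
#'
#' One-sided (right-tail) p-values from the t distribution — only positive
#' connectivity is considered — corrected by Benjamini-Hochberg over the
#' valid in-brain voxels, then binarised.
#'
#' @param stat a [group_ttest()] result.
#' @param q FDR level (default 0.05).
#' @param brain [binary_mask()] on the same grid.
#' @return A [binary_mask()] of surviving voxels.
#' @export
fdr_binarize <- function(stat, q = 0.05, brain) {
  stopifnot(inherits(stat, "group_stat_map"), q > 0, q < 1)
  check_same_grid(stat$grid, brain$grid, "t map and brain mask")
  valid <- as.vector(brain$vox) & is.finite(stat$t)
  if (!any(valid)) stop("no valid in-brain voxels to test")
  p <- stats::pt(stat$t[valid], df = stat$df, lower.tail = FALSE)
  sig <- bh_reject(p, q)
  vox <- rep(FALSE, n_voxels(stat$grid))
  vox[which(valid)[sig]] <- TRUE
  binary_mask(stat$grid, vox)
}

#' Overlay binarised contrast maps into a probability map
#'
#' Per voxel, the fraction of contrasts whose thresholded connectivity map
#' contains the voxel.
#'
#' @param masks non-empty list of [binary_mask()]s on identical grids.
#' @return An object of class `probability_map`: grid, per-voxel `prob`,
#'   `n_contrasts`.
#' @export
overlay_probability <- function(masks) {
  if (length(masks) < 1L) stop("need at least one binarised map")
  grid <- masks[[1]]$grid
  for (m in masks[-1]) check_same_grid(grid, m$grid, "binarised maps")
  counts <- Reduce(`+`, lapply(masks, function(m) as.numeric(m$vox)))
  structure(list(grid = grid, prob = as.vector(counts) / length(masks),
                 n_contrasts = length(masks)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d contrasts on %s; max fraction %.3g\n",
              x$n_contrasts, format(x$grid), max(x$prob)))
  invisible(x)
}

#' Threshold a probability map into a susceptibility network
#'
#' Voxels present in at least `threshold` of the contrasts (inclusive,
#' `>=`) form the network mask.
#'
#' @param prob a [overlay_probability()] result.
#' @param threshold overlay fraction in (0, 1] (default 0.60).
#' @param provenance optional named list recorded on the mask (disorder,
#'   modality, seed radius, FDR level, ...).
#' @return A `network_mask` (a [binary_mask()] with fields
#'   `overlay_threshold` and `provenance`).
#' @export
threshold_network <- function(prob, threshold = 0.60, provenance = list()) {
  stopifnot(inherits(prob, "probability_map"), threshold > 0, threshold <= 1)
  m <- binary_mask(prob$grid, prob$prob >= threshold)
  m$overlay_threshold <- threshold
  m$provenance <- provenance
  class(m) <- c("network_mask", class(m))
  m
}

#' Union of two susceptibility networks
#'
#' Combines (for example) the functional and structural damage networks of
#' one disorder into a single brain damage network.
#'
#' @param a,b `network_mask`s on the same grid.
#' @return A `network_mask` with `modality = "combined"` in its
#'   provenance.
#' @export
combine_networks <- function(a, b) {
  check_same_grid(a$grid, b$grid, "networks")
  m <- binary_mask(a$grid, a$vox | b$vox)
  m$overlay_threshold <- a$overlay_threshold
  prov <- a$provenance
  prov$modality <- "combined"
  m$provenance <- prov
  class(m) <- c("network_mask", class(m))
  m
}

#' Build one susceptibility network from per-contrast subject maps
#'
#' The group-level tail of the mapping procedure: per contrast, a voxelwise
#' one-sample t-test over the subject z maps, FDR binarisation, then the
#' probability overlay across contrasts thresholded into a network mask.
#'
#' @param maps_by_contrast list (one element per contrast) of lists of
#'   `fc_map`s (one per subject).
#' @param brain [binary_mask()].
#' @param q voxel-level FDR level.
#' @param overlay_threshold overlay fraction.
#' @param provenance recorded on the resulting mask.
#' @return A list with `network` (the `network_mask`), `prob` (the
#'   [overlay_probability()] map), `tmaps` and `binarized` (per-contrast
#'   lists).
#' @export
network_from_maps <- function(maps_by_contrast, brain, q = 0.05,
                              overlay_threshold = 0.60,
                              provenance = list()) {
  tmaps <- lapply(maps_by_contrast, group_ttest)
  binarized <- lapply(tmaps, fdr_binarize, q = q, brain = brain)
  prob <- overlay_probability(binarized)
  provenance$fdr_q <- q
  net <- threshold_network(prob, overlay_threshold, provenance)
  list(network = net, prob = prob, tmaps = tmaps, binarized = binarized)
}
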