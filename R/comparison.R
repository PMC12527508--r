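#' Dice similarity of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical non-empty masks, 0
#' for disjoint ones.
#'
#' @param a,b [binary_mask()]s on the same grid, not both empty.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  na <- mask_size(a); nb <- mask_size(b)
  if (na + nb == 0L) stop("Dice is undefined for two empty masks")
  2 * sum(a$vox & b$vox) / (na + nb)
}

#' Construct a canonical network atlas
#'
#' An integer-labelled parcellation (0 = background, 1..K networks) with a
#' name per network.
#'
#' @param grid a [volume_grid()].
#' @param labels integer array with `dim = grid$dim`, values in `0..K`.
#' @param names character vector of K unique network names.
#' @return An object of class `canonical_atlas`.
#' @export
canonical_atlas <- function(grid, labels, names) {
  if (is.null(dim(labels))) dim(labels) <- grid$dim
  stopifnot(identical(dim(labels), as.integer(grid$dim)))
  storage.mode(labels) <- "integer"
  K <- length(names)
  if (anyDuplicated(names)) stop("atlas network names must be unique")
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && max(present) > K)
    stop("atlas has labels beyond the ", K, " provided names")
  counts <- tabulate(labels[labels > 0L], nbins = K)
  if (any(counts == 0L))
    stop("empty atlas network(s): ",
         paste(names[counts == 0L], collapse = ", "))
  structure(list(grid = grid, labels = labels, names = as.character(names)),
            class = "canonical_atlas")
}

#' @export
print.canonical_atlas <- function(x, ...) {
  cat(sprintf("<canonical_atlas> %d networks on %s\n",
              length(x$names), format(x$grid)))
  invisible(x)
}

#' Extract one atlas network as a binary mask
#' @param atlas a [canonical_atlas()].
#' @param label integer network label (1..K).
#' @return A [binary_mask()].
#' @export
atlas_network_mask <- function(atlas, label) {
  stopifnot(label >= 1L, label <= length(atlas$names))
  binary_mask(atlas$grid, atlas$labels == as.integer(label))
}

#' Read / write an atlas (NIfTI labels + sidecar name table)
#'
#' The sidecar is a two-column delimited table `label, name`.
#'
#' @param nifti_path integer-label NIfTI volume.
#' @param names_path delimited text with columns `label` and `name`.
#' @return `read_atlas`: a [canonical_atlas()].
#' @export
read_atlas <- function(nifti_path, names_path) {
  lab <- read_labels(nifti_path)
  header <- readLines(names_path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  nm <- utils::read.table(names_path, header = TRUE, sep = sep,
                          strip.white = TRUE)
  stopifnot(all(c("label", "name") %in% names(nm)))
  nm <- nm[order(nm$label), ]
  if (!identical(as.integer(nm$label), seq_len(nrow(nm))))
    stop("atlas sidecar labels must be 1..K")
  canonical_atlas(lab$grid, lab$labels, as.character(nm$name))
}

#' @rdname read_atlas
#' @param atlas a [canonical_atlas()] to write.
#' @export
write_atlas <- function(atlas, nifti_path, names_path) {
  write_volume(array(as.numeric(atlas$labels), dim = atlas$grid$dim),
               nifti_path, grid = atlas$grid, datatype = "int16")
  utils::write.csv(
    data.frame(label = seq_along(atlas$names), name = atlas$names),
    names_path, row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}

#' Overlap of a network mask with each canonical network
#'
#' For each atlas network k, the proportion of its voxels covered by the
#' network mask: `|net intersect atlas_k| / |atlas_k|`. Proportions need
#' not sum to 1 (the mask may also cover background and networks overlap
#' nothing).
#'
#' @param net a [binary_mask()] (typically a `network_mask`).
#' @param atlas a [canonical_atlas()] on the same grid.
#' @return Data frame with columns `label`, `name`, `overlap_voxels`,
#'   `canonical_voxels`, `proportion`, sorted by decreasing proportion
#'   (ties by label), classed `overlap_report`.
#' @export
canonical_overlap <- function(net, atlas) {
  check_same_grid(net$grid, atlas$grid, "network and atlas")
  K <- length(atlas$names)
  lab <- as.vector(atlas$labels)
  size <- tabulate(lab[lab > 0L], nbins = K)
  inside <- lab[as.vector(net$vox)]
  overlap <- tabulate(inside[inside > 0L], nbins = K)
  rep <- data.frame(label = seq_len(K), name = atlas$names,
                    overlap_voxels = overlap, canonical_voxels = size,
                    proportion = overlap / size)
  rep <- rep[order(-rep$proportion, rep$label), ]
  rownames(rep) <- NULL
  class(rep) <- c("overlap_report", "data.frame")
  rep
}

#' Long-format table of overlap proportions for polar plotting
#'
#' Stacks several overlap reports (for example the four
#' disorder-by-modality networks) into one tidy table in atlas label
#' order, suitable for polar plots or export.
#'
#' @param reports named list of [canonical_overlap()] reports sharing one
#'   atlas.
#' @return Data frame with columns `network`, `label`, `canonical_name`,
#'   `proportion`; rows grouped by report in atlas label order.
#' @export
overlap_polar_table <- function(reports) {
  stopifnot(length(reports) >= 1L)
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("network_", seq_along(reports))
  ref <- reports[[1]][order(reports[[1]]$label), c("label", "name")]
  out <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]][order(reports[[i]]$label), ]
    if (!identical(r$name, ref$name))
      stop("overlap reports do not share the same atlas")
    data.frame(network = nm[i], label = r$label, canonical_name = r$name,
               proportion = r$proportion)
  }))
  rownames(out) <- NULL
  out
}
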