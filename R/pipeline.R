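#' Fit disorder-susceptibility networks from coordinates and a cohort
#'
#' The central estimator. Given contrast records (reported peak
#' coordinates) and a normative resting-state cohort on a common grid, it
#' (1) harmonises coordinates to MNI space and builds a merged spherical
#' seed per contrast, (2) computes each subject's seed-to-whole-brain
#' Fisher-z connectivity map, (3) runs a voxelwise one-sample t-test per
#' contrast, (4) binarises at voxel-level FDR `q` keeping positive
#' connectivity only, and (5) overlays the binarised contrast maps of each
#' disorder-by-modality group into a probability map thresholded at
#' `overlay_threshold` to yield the group's susceptibility network.
#' Functional and structural networks of a disorder are additionally
#' combined by union. Networks are compared pairwise by Dice and, when an
#' atlas is supplied, decomposed against the canonical networks.
#'
#' @param contrasts list of [contrast_record()]s (or the result of
#'   [parse_contrast_table()]).
#' @param cohort either an `fcnm_cohort` from [simulate_cohort()] or a
#'   plain list of [bold_series()] objects.
#' @param brain,wm,csf [binary_mask()]s on the cohort grid (taken from
#'   the cohort when it carries tissue masks). `wm`/`csf` are only needed
#'   when `clean = TRUE`.
#' @param motion optional list of motion matrices (per subject, same
#'   order); taken from the cohort when present.
#' @param atlas optional [canonical_atlas()] for composition reports.
#' @param radius_mm seed sphere radius in mm (default 4).
#' @param q voxel-level FDR level (default 0.05).
#' @param overlay_threshold overlay fraction (default 0.60).
#' @param band band-pass edges in Hz (default `c(0.01, 0.1)`).
#' @param fd_spike_mm FD scrubbing threshold (default 0.5).
#' @param clean run temporal cleaning ([clean_bold()]) before mapping;
#'   set `FALSE` when the series are already cleaned.
#' @param tal_method Talairach conversion method, see [tal_to_mni()].
#' @param workers forked workers for the per-subject maps (results are
#'   independent of this value).
#' @return An object of class `fcnm`; see [print.fcnm()],
#'   [summary.fcnm()], [plot.fcnm()].
#' @export
fcnm <- function(contrasts, cohort, brain = NULL, wm = NULL, csf = NULL,
                 motion = NULL, atlas = NULL, radius_mm = 4, q = 0.05,
                 overlay_threshold = 0.60, band = c(0.01, 0.1),
                 fd_spike_mm = 0.5, clean = TRUE,
                 tal_method = c("lancaster", "brett"), workers = 1L) {
  tal_method <- match.arg(tal_method)
  if (inherits(cohort, "fcnm_cohort")) {
    if (is.null(brain)) brain <- cohort$tissue$brain
    if (is.null(wm)) wm <- cohort$tissue$wm
    if (is.null(csf)) csf <- cohort$tissue$csf
    if (is.null(motion)) motion <- lapply(cohort$subjects, `[[`, "motion")
    bolds <- lapply(cohort$subjects, `[[`, "bold")
  } else {
    bolds <- cohort
  }
  if (length(bolds) < 3L) stop("need at least 3 subjects")
  if (is.null(brain)) stop("a brain mask is required")
  if (inherits(contrasts, "contrast_record")) contrasts <- list(contrasts)

  contrasts <- lapply(contrasts, harmonize_space, method = tal_method)
  grid <- bolds[[1]]$grid
  seeds <- lapply(contrasts, build_contrast_seed, radius_mm = radius_mm,
                  grid = grid, brain = brain)
  seed_sizes <- vapply(seeds, mask_size, 0L)
  names(seed_sizes) <- vapply(contrasts, `[[`, "", "contrast_id")

  if (clean) {
    if (is.null(motion) || is.null(wm) || is.null(csf))
      stop("clean = TRUE requires motion traces and wm/csf masks")
    bolds <- lapply(seq_along(bolds), function(s)
      clean_bold(bolds[[s]], motion[[s]], brain, wm, csf,
                 fd_spike_mm = fd_spike_mm,
                 low_hz = band[1], high_hz = band[2]))
  }

  subject_maps <- subject_fc_maps(bolds, seeds, brain, workers = workers)

  groups <- split(seq_along(contrasts),
                  paste(vapply(contrasts, `[[`, "", "disorder"),
                        vapply(contrasts, `[[`, "", "modality"),
                        sep = "_"))
  networks <- list(); prob_maps <- list(); tmaps <- list()
  for (g in names(groups)) {
    ci <- groups[[g]]
    maps_by_contrast <- lapply(ci, function(i)
      lapply(subject_maps, `[[`, i))
    parts <- strsplit(g, "_", fixed = TRUE)[[1]]
    res <- network_from_maps(
      maps_by_contrast, brain, q = q,
      overlay_threshold = overlay_threshold,
      provenance = list(disorder = parts[1], modality = parts[2],
                        radius_mm = radius_mm, fdr_q = q))
    networks[[g]] <- res$network
    prob_maps[[g]] <- res$prob
    tmaps[[g]] <- res$tmaps
  }
  for (dis in unique(vapply(contrasts, `[[`, "", "disorder"))) {
    fk <- paste0(dis, "_functional"); sk <- paste0(dis, "_structural")
    if (!is.null(networks[[fk]]) && !is.null(networks[[sk]]))
      networks[[paste0(dis, "_combined")]] <-
        combine_networks(networks[[fk]], networks[[sk]])
  }

  dm <- dice_matrix(networks)
  overlap <- NULL
  if (!is.null(atlas))
    overlap <- lapply(networks, canonical_overlap, atlas = atlas)

  structure(list(networks = networks, prob_maps = prob_maps,
                 tmaps = tmaps, dice = dm, overlap = overlap,
                 seed_sizes = seed_sizes, n_subjects = length(bolds),
                 n_contrasts = length(contrasts), grid = grid,
                 params = list(radius_mm = radius_mm, q = q,
                               overlay_threshold = overlay_threshold,
                               band = band, fd_spike_mm = fd_spike_mm,
                               clean = clean, tal_method = tal_method)),
            class = "fcnm")
}

#' Per-subject FC maps for a set of seeds
#'
#' @param bolds list of [bold_series()].
#' @param seeds list of seed masks.
#' @param brain [binary_mask()].
#' @param workers forked workers (the result does not depend on this).
#' @return List over subjects of lists over seeds of `fc_map`s.
#' @export
subject_fc_maps <- function(bolds, seeds, brain, workers = 1L) {
  fun <- function(b) fc_maps_for_subject(b, seeds, brain)
  if (workers > 1L) {
    out <- parallel::mclapply(bolds, fun, mc.cores = workers)
    errs <- vapply(out, inherits, TRUE, "try-error")
    if (any(errs)) stop("subject map worker failed: ", out[errs][[1]])
    out
  } else {
    lapply(bolds, fun)
  }
}

dice_matrix <- function(networks) {
  n <- length(networks)
  dm <- matrix(NA_real_, n, n, dimnames = list(names(networks),
                                               names(networks)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (mask_size(networks[[i]]) + mask_size(networks[[j]]) == 0L) next
    dm[i, j] <- dice(networks[[i]], networks[[j]])
  }
  dm
}

#' @export
print.fcnm <- function(x, ...) {
  cat(sprintf(
    "Functional connectivity network mapping\n  %d contrasts, %d subjects on %s\n  seed radius %g mm, FDR q = %g, overlay threshold %g\n",
    x$n_contrasts, x$n_subjects, format(x$grid), x$params$radius_mm,
    x$params$q, x$params$overlay_threshold))
  for (g in names(x$networks))
    cat(sprintf("  %-24s %6d voxels\n", g, mask_size(x$networks[[g]])))
  invisible(x)
}

#' Summarise a fitted network mapping
#'
#' @param object an `fcnm` fit.
#' @param ... unused.
#' @return A list with a per-network table (`networks`), the Dice matrix
#'   and the top canonical overlap per network (when an atlas was given),
#'   classed `summary.fcnm`.
#' @export
summary.fcnm <- function(object, ...) {
  tab <- data.frame(
    network = names(object$networks),
    voxels = vapply(object$networks, mask_size, 0L),
    row.names = NULL)
  if (!is.null(object$overlap)) {
    tab$top_canonical <- vapply(object$overlap, function(r) r$name[1], "")
    tab$top_proportion <- vapply(object$overlap, function(r)
      r$proportion[1], 0)
  }
  structure(list(networks = tab, dice = object$dice,
                 params = object$params,
                 seed_sizes = object$seed_sizes), class = "summary.fcnm")
}

#' @export
print.summary.fcnm <- function(x, ...) {
  cat("Susceptibility networks:\n")
  print(x$networks, row.names = FALSE)
  cat("\nPairwise Dice:\n")
  print(round(x$dice, 3))
  invisible(x)
}

#' Plot axial slices of a fitted network
#'
#' Base-graphics mosaic of evenly spaced axial slices with the network
#' mask drawn over the grid extent.
#'
#' @param x an `fcnm` fit.
#' @param network name of the network to draw (default: first).
#' @param slices number of axial slices (default 6).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.fcnm <- function(x, network = names(x$networks)[1], slices = 6, ...) {
  net <- x$networks[[network]]
  if (is.null(net)) stop("no network named '", network, "'")
  d <- net$grid$dim
  zi <- unique(round(seq(1, d[3], length.out = slices + 2)))[-c(1, slices + 2)]
  op <- graphics::par(mfrow = c(2, ceiling(length(zi) / 2)),
                      mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (z in zi) {
    graphics::image(seq_len(d[1]), seq_len(d[2]),
                    matrix(as.numeric(net$vox[, , z]), d[1], d[2]),
                    col = c("grey15", "firebrick"), axes = FALSE,
                    xlab = "", ylab = "", main = paste0("z = ", z), ...)
  }
  graphics::mtext(network, outer = TRUE, line = -1.5)
  invisible(x)
}

#' Screen a cohort on age and head motion
#'
#' Retains subjects whose age lies within `age_range` and whose motion
#' trace passes [motion_screen()] (max translation < 2 mm and max
#' rotation < 2 degrees by default). Subjects with a missing motion trace
#' are excluded with a logged reason rather than causing an error.
#'
#' @param subjects list with per-subject `subject_id`, `age` and `motion`
#'   (an `fcnm_cohort$subjects` works directly).
#' @param age_range inclusive bounds (default `c(18, 60)`).
#' @param trans_limit_mm,rot_limit_deg motion limits.
#' @return Data frame `subject_id`, `age`, `retained`, `reason` (`NA`
#'   when retained).
#' @export
subject_screen <- function(subjects, age_range = c(18, 60),
                           trans_limit_mm = 2, rot_limit_deg = 2) {
  rows <- lapply(subjects, function(s) {
    reason <- NA_character_
    if (is.null(s$age) || is.na(s$age) ||
        s$age < age_range[1] || s$age > age_range[2]) {
      reason <- "age"
    } else if (is.null(s$motion)) {
      reason <- "missing motion trace"
    } else {
      ok <- motion_screen(s$motion, trans_limit_mm, rot_limit_deg)
      if (!ok) reason <- attr(ok, "reason")
    }
    data.frame(subject_id = s$subject_id,
               age = if (is.null(s$age)) NA_real_ else s$age,
               retained = is.na(reason), reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
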