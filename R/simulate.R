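#' Configuration for the synthetic study generator
#'
#' Defines a download-free emulation of the study's inputs: a cohort of 4D
#' resting-state volumes whose voxel time courses mix shared
#' planted-network signals with noise, motion traces, tissue masks, a toy
#' canonical atlas, and coordinate tables planted inside a chosen network.
#'
#' The data model is `voxel series = amplitude * network latent + N(0,
#' sigma^2)` for voxels of a planted network (the latent is an independent
#' standard-normal series per network and subject) and pure noise
#' elsewhere, so the expected within-network voxel-voxel correlation is
#' `amplitude^2 / (amplitude^2 + sigma^2)`. Out-of-brain voxels are
#' identically zero and are never analysed.
#'
#' @param grid_dim voxel counts (default `c(30, 36, 30)`, a reduced grid
#'   on which the end-to-end analysis runs in minutes).
#' @param voxel_mm isotropic voxel size (default 3, the analysis
#'   resolution).
#' @param n_subjects cohort size.
#' @param n_timepoints volumes per subject.
#' @param tr_seconds repetition time (default 2).
#' @param n_networks number of planted networks K (>= 2).
#' @param amplitude network signal amplitude `a`.
#' @param sigma noise standard deviation.
#' @param ar1 optional AR(1) coefficient for temporally autocorrelated
#'   noise (default 0, white).
#' @param motion_mag_mm,motion_mag_deg peak amplitude of the smooth
#'   random-walk motion traces; defaults (0.3 mm, 0.3 deg) keep every
#'   synthetic subject inside the 2 mm / 2 degree screening limits.
#' @param spike_prob per-frame probability of an injected motion spike
#'   large enough to exceed the 0.5 mm FD scrubbing threshold (default 0).
#' @param seed mandatory integer random seed; every generator output is a
#'   pure function of this configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_dim = c(30, 36, 30), voxel_mm = 3,
                       n_subjects = 40, n_timepoints = 200,
                       tr_seconds = 2, n_networks = 5,
                       amplitude = 1, sigma = 1, ar1 = 0,
                       motion_mag_mm = 0.3, motion_mag_deg = 0.3,
                       spike_prob = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  stopifnot(n_subjects >= 1, n_timepoints >= 2, tr_seconds > 0,
            n_networks >= 2, amplitude >= 0, sigma >= 0,
            ar1 >= 0, ar1 < 1, spike_prob >= 0, spike_prob <= 1)
  grid <- volume_grid(grid_dim,
                      affine = {
                        A <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
                        A[1:3, 4] <- -(as.integer(grid_dim) - 1L) / 2 * voxel_mm
                        A
                      })
  structure(list(grid = grid, n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 n_networks = as.integer(n_networks),
                 amplitude = amplitude, sigma = sigma, ar1 = ar1,
                 motion_mag_mm = motion_mag_mm,
                 motion_mag_deg = motion_mag_deg,
                 spike_prob = spike_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# normalised squared ellipsoidal radius of every voxel (1 = brain surface)
ellipsoid_u <- function(grid, scale = 0.46) {
  d <- grid$dim
  ax <- (d - 1) / 2
  semi <- scale * d
  u1 <- ((seq_len(d[1]) - 1 - ax[1]) / semi[1])^2
  u2 <- ((seq_len(d[2]) - 1 - ax[2]) / semi[2])^2
  u3 <- ((seq_len(d[3]) - 1 - ax[3]) / semi[3])^2
  outer(outer(u1, u2, `+`), u3, `+`)
}

#' Synthetic tissue masks
#'
#' Brain = an ellipsoid filling most of the grid; white matter = a central
#' ellipsoidal core; CSF = a thin outer shell. Purely geometric stand-ins
#' giving the nuisance design non-degenerate tissue regressors.
#'
#' @param cfg a [sim_config()].
#' @return List of [binary_mask()]s: `brain`, `wm`, `csf`.
#' @export
make_tissue_masks <- function(cfg) {
  u <- ellipsoid_u(cfg$grid)
  brain <- u <= 1
  list(brain = binary_mask(cfg$grid, brain),
       wm = binary_mask(cfg$grid, u <= 0.12),
       csf = binary_mask(cfg$grid, brain & u > 0.85))
}

#' Generate a toy canonical atlas of planted networks
#'
#' Places K mutually exclusive, spatially contiguous spherical blobs
#' (radius `blob_radius_mm`) inside the synthetic brain, at centres drawn
#' in a mid-depth shell (clear of the white-matter core and the CSF rim)
#' with a minimum pairwise separation that guarantees disjointness.
#' Deterministic given the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @param blob_radius_mm radius of each network blob (default 9).
#' @param min_separation_mm minimum centre-to-centre distance (default
#'   2 * blob_radius_mm + voxel size).
#' @return A [canonical_atlas()] with names `net_1 .. net_K`.
#' @export
make_toy_atlas <- function(cfg, blob_radius_mm = 9,
                           min_separation_mm = NULL) {
  if (is.null(min_separation_mm))
    min_separation_mm <- 2 * blob_radius_mm + max(cfg$grid$voxel_size)
  u <- ellipsoid_u(cfg$grid)
  tissue <- make_tissue_masks(cfg)
  eligible <- tissue$brain$vox & !tissue$wm$vox & !tissue$csf$vox
  candidate <- which(u >= 0.12 & u <= 0.5 & eligible)
  if (length(candidate) < cfg$n_networks)
    stop("grid too small for ", cfg$n_networks, " networks")

  d <- cfg$grid$dim
  idx0 <- arrayInd(candidate, d) - 1L
  mm <- voxel_to_mm(idx0, cfg$grid)

  set.seed(cfg$seed)
  centres <- matrix(NA_real_, cfg$n_networks, 3)
  placed <- 0L
  for (try in seq_len(5000L)) {
    cand <- mm[sample.int(nrow(mm), 1L), ]
    if (placed > 0L) {
      dmin <- min(sqrt(rowSums(sweep(centres[seq_len(placed), , drop = FALSE],
                                     2, cand)^2)))
      if (dmin < min_separation_mm) next
    }
    placed <- placed + 1L
    centres[placed, ] <- cand
    if (placed == cfg$n_networks) break
  }
  if (placed < cfg$n_networks)
    stop("could not place ", cfg$n_networks,
         " networks with separation ", min_separation_mm, " mm; ",
         "grid too small or K too large")

  labels <- array(0L, dim = d)
  for (k in seq_len(cfg$n_networks)) {
    blob <- sphere_union(centres[k, , drop = FALSE], blob_radius_mm,
                         cfg$grid) & eligible
    labels[blob] <- k
  }
  canonical_atlas(cfg$grid, labels, paste0("net_", seq_len(cfg$n_networks)))
}

# smooth bounded motion trace: a centred random walk rescaled to a target
# peak amplitude, with optional injected displacement spikes
simulate_motion <- function(tp, mag_mm, mag_rad, spike_prob) {
  walk <- function(mag) {
    w <- cumsum(stats::rnorm(tp))
    w <- w - mean(w)
    peak <- max(abs(w))
    if (peak > 0) w * (mag / peak) else w
  }
  m <- cbind(walk(mag_mm), walk(mag_mm), walk(mag_mm),
             walk(mag_rad), walk(mag_rad), walk(mag_rad))
  if (spike_prob > 0) {
    hit <- which(stats::runif(tp) < spike_prob)
    hit <- hit[hit > 1L]
    # 1 mm single-frame x-translation excursion: FD > 0.5 mm at the spike
    for (h in hit) m[h, 1] <- m[h, 1] + 1
  }
  as_motion(m)
}

#' Simulate a cohort of resting-state series with planted networks
#'
#' Per subject, each network gets an independent standard-normal latent
#' time course; voxels of network k receive `amplitude * latent_k` plus
#' i.i.d. (or AR(1)) Gaussian noise of standard deviation `sigma`; other
#' in-brain voxels receive noise only; out-of-brain voxels are zero.
#' Motion traces are smooth random walks within the screening limits,
#' with optional injected spikes. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param atlas a [canonical_atlas()] on the config grid, typically from
#'   [make_toy_atlas()].
#' @param tissue tissue masks from [make_tissue_masks()] (recomputed when
#'   `NULL`).
#' @return An `fcnm_cohort`: list with `subjects` (each a list of `bold`,
#'   `motion`, `age`, `subject_id`), `truth` (`atlas`, per-subject latent
#'   matrices), `tissue`, and `config`.
#' @export
simulate_cohort <- function(cfg, atlas, tissue = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(atlas, "canonical_atlas"))
  check_same_grid(cfg$grid, atlas$grid, "config grid and atlas")
  if (is.null(tissue)) tissue <- make_tissue_masks(cfg)
  tp <- cfg$n_timepoints
  inbrain <- mask_which(tissue$brain)
  net_idx <- lapply(seq_len(cfg$n_networks),
                    function(k) which(atlas$labels == k))

  set.seed(cfg$seed + 1L)
  subjects <- vector("list", cfg$n_subjects)
  latents <- vector("list", cfg$n_subjects)
  ages <- sample(20:35, cfg$n_subjects, replace = TRUE)
  for (s in seq_len(cfg$n_subjects)) {
    L <- matrix(stats::rnorm(tp * cfg$n_networks), tp, cfg$n_networks)
    data <- matrix(0, tp, n_voxels(cfg$grid))
    noise <- stats::rnorm(tp * length(inbrain), sd = cfg$sigma)
    dim(noise) <- c(tp, length(inbrain))
    if (cfg$ar1 > 0) {
      # recursive AR(1) colour, rescaled to keep the marginal sd at sigma
      noise <- apply(noise, 2, function(x)
        as.numeric(stats::filter(x, cfg$ar1, method = "recursive")))
      noise <- noise * sqrt(1 - cfg$ar1^2)
    }
    data[, inbrain] <- noise
    for (k in seq_len(cfg$n_networks))
      data[, net_idx[[k]]] <- data[, net_idx[[k]]] +
        cfg$amplitude * L[, k]
    motion <- simulate_motion(tp, cfg$motion_mag_mm,
                              cfg$motion_mag_deg * pi / 180,
                              cfg$spike_prob)
    id <- sprintf("sub%03d", s)
    subjects[[s]] <- list(
      bold = bold_series(cfg$grid, data, cfg$tr_seconds, id),
      motion = motion, age = ages[s], subject_id = id)
    latents[[s]] <- L
  }
  structure(list(subjects = subjects,
                 truth = list(atlas = atlas, latents = latents),
                 tissue = tissue, config = cfg),
            class = "fcnm_cohort")
}

#' @export
print.fcnm_cohort <- function(x, ...) {
  cat(sprintf(
    "<fcnm_cohort> %d subjects x %d timepoints on %s; K = %d, a = %g, sigma = %g\n",
    length(x$subjects), x$config$n_timepoints, format(x$config$grid),
    x$config$n_networks, x$config$amplitude, x$config$sigma))
  invisible(x)
}

#' Plant contrast coordinate records inside a network
#'
#' Emulates a corpus of reported peak coordinates: peaks are sampled
#' uniformly (without replacement within a contrast) from the voxel
#' centres of the chosen atlas network. By default they are reported
#' exactly at voxel centres, as published peak coordinates are (cluster
#' peaks lie on each study's analysis grid); `jitter_mm > 0` perturbs
#' them by up to that much per axis to emulate grid mismatch between
#' studies, reverting to the unjittered centre whenever the jittered
#' point leaves the brain. Note that sub-voxel seed radii (such as the
#' 1 mm robustness sweep) require peaks at or near voxel centres to
#' produce non-empty seeds. Deterministic given `seed`.
#'
#' @param atlas a [canonical_atlas()].
#' @param network_id nonzero network label to plant in.
#' @param n_contrasts,peaks_per_contrast corpus shape.
#' @param jitter_mm maximum per-axis jitter (default 0).
#' @param seed integer seed.
#' @param disorder,modality metadata stamped on every record.
#' @param brain [binary_mask()] used for the in-brain re-projection;
#'   defaults to the union of the atlas networks (pass the real brain
#'   mask to let jittered peaks land in background tissue).
#' @return List of [contrast_record()]s in MNI space.
#' @export
plant_contrasts <- function(atlas, network_id, n_contrasts,
                            peaks_per_contrast, jitter_mm = 0, seed,
                            disorder = "SZ", modality = "functional",
                            brain = NULL) {
  stopifnot(network_id >= 1L, network_id <= length(atlas$names))
  if (missing(seed)) stop("plant_contrasts requires a seed")
  if (is.null(brain)) brain <- binary_mask(atlas$grid, atlas$labels > 0L)
  net_lin <- which(atlas$labels == as.integer(network_id))
  if (peaks_per_contrast > length(net_lin))
    stop("peaks_per_contrast (", peaks_per_contrast,
         ") exceeds network size (", length(net_lin), ")")
  d <- atlas$grid$dim
  set.seed(seed)
  lapply(seq_len(n_contrasts), function(i) {
    pick <- sample(net_lin, peaks_per_contrast)
    centres <- voxel_to_mm(arrayInd(pick, d) - 1L, atlas$grid)
    jit <- matrix(stats::runif(3 * peaks_per_contrast, -jitter_mm,
                               jitter_mm), ncol = 3)
    peaks <- centres + jit
    near <- mm_to_voxel(peaks, atlas$grid)
    ok <- attr(near, "in_grid")
    ok[ok] <- brain$vox[voxel_linear_index(near[ok, , drop = FALSE],
                                           atlas$grid)]
    peaks[!ok, ] <- centres[!ok, ]
    contrast_record(study_id = sprintf("study%02d", i),
                    contrast_id = sprintf("%s_%s_c%02d", disorder,
                                          modality, i),
                    disorder = disorder, modality = modality,
                    space = "MNI", peaks = peaks)
  })
}

#' Write a list of contrast records as a delimited table
#'
#' The same format [parse_contrast_table()] reads.
#'
#' @param records list of [contrast_record()]s.
#' @param path output path (`.csv` comma-delimited, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(study_id = r$study_id, contrast_id = r$contrast_id,
               disorder = r$disorder, modality = r$modality,
               space = r$space, x = r$peaks[, 1], y = r$peaks[, 2],
               z = r$peaks[, 3])))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Materialise a synthetic fixture directory
#'
#' Writes everything the file-based pipeline reads: per-subject 4D BOLD
#' NIfTI volumes and motion text files, brain/wm/csf masks, the toy atlas
#' with its name sidecar, a participants table with ages, and a contrast
#' coordinate table.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param contrasts list of [contrast_record()]s.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, contrasts, dir, gzip = TRUE) {
  ext <- if (gzip) ".nii.gz" else ".nii"
  dir.create(file.path(dir, "bold"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_bold(s$bold, file.path(dir, "bold", paste0(s$subject_id, ext)))
    utils::write.table(s$motion,
                       file.path(dir, "motion",
                                 paste0(s$subject_id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  write_volume(cohort$tissue$brain, file.path(dir, paste0("brain", ext)))
  write_volume(cohort$tissue$wm, file.path(dir, paste0("wm", ext)))
  write_volume(cohort$tissue$csf, file.path(dir, paste0("csf", ext)))
  write_atlas(cohort$truth$atlas, file.path(dir, paste0("atlas", ext)),
              file.path(dir, "atlas_labels.csv"))
  utils::write.csv(
    data.frame(subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
               age = vapply(cohort$subjects, `[[`, 0, "age")),
    file.path(dir, "participants.csv"), row.names = FALSE, quote = FALSE)
  write_contrast_table(contrasts, file.path(dir, "contrasts.csv"))
  invisible(dir)
}
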