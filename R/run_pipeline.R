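#' Assemble a pipeline configuration
#'
#' File-level configuration for [run_pipeline()]: input paths plus the
#' analysis parameters, each defaulting to the values of the standard
#' procedure. A configuration round-trips losslessly through JSON/YAML
#' (see [read_pipeline_config()]).
#'
#' @param bold_dir directory of per-subject 4D NIfTI volumes.
#' @param motion_dir directory of 6-column motion text files named
#'   `<subject>.txt` matching the BOLD file stems.
#' @param brain_mask,wm_mask,csf_mask NIfTI mask paths.
#' @param contrast_table delimited coordinate table
#'   (see [parse_contrast_table()]).
#' @param atlas,atlas_names optional canonical atlas NIfTI + name sidecar.
#' @param participants optional CSV with columns `subject_id`, `age`.
#' @param out_dir output directory.
#' @param radius_mm,fdr_q,overlay_threshold,band_low_hz,band_high_hz,fd_spike_mm
#'   analysis parameters (defaults 4, 0.05, 0.60, 0.01, 0.1, 0.5).
#' @param age_range screening bounds (default `c(18, 60)`).
#' @param tal_method Talairach conversion method.
#' @param tr_seconds repetition time override (`NULL`: NIfTI header).
#' @param drop_initial initial volumes to discard (default 0; set 10 for
#'   raw acquisitions that include equilibration dummies).
#' @param clean run temporal cleaning (default TRUE).
#' @param workers forked workers for subject maps.
#' @param run_seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bold_dir, motion_dir = NULL, brain_mask,
                            wm_mask = NULL, csf_mask = NULL,
                            contrast_table, atlas = NULL,
                            atlas_names = NULL, participants = NULL,
                            out_dir, radius_mm = 4, fdr_q = 0.05,
                            overlay_threshold = 0.60, band_low_hz = 0.01,
                            band_high_hz = 0.1, fd_spike_mm = 0.5,
                            age_range = c(18, 60),
                            tal_method = "lancaster", tr_seconds = NULL,
                            drop_initial = 0L, clean = TRUE,
                            workers = 1L, run_seed = 1L) {
  stopifnot(radius_mm > 0, fdr_q > 0, fdr_q < 1,
            overlay_threshold > 0, overlay_threshold <= 1,
            band_low_hz >= 0, band_low_hz < band_high_hz,
            fd_spike_mm >= 0, length(age_range) == 2L)
  # stable field order (environment listing order is not deterministic)
  structure(mget(names(formals(pipeline_config)), environment()),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' JSON (default) or YAML when the `yaml` package is available and the
#' path ends in `.yml`/`.yaml`.
#'
#' @param path configuration file.
#' @return `read_pipeline_config`: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lst <- lst[!vapply(lst, is.null, TRUE)]
  do.call(pipeline_config, lst)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("writing YAML configs requires the 'yaml' package")
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# md5 of a canonical serialisation; used to key the stage cache
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full coordinate-to-network pipeline on files
#'
#' Loads the cohort and coordinate table named in the configuration,
#' screens subjects (age and motion), performs temporal cleaning, fits the
#' susceptibility networks with [fcnm()], and writes per-group
#' probability maps and network masks (NIfTI), per-contrast t and
#' binarised maps, the Dice table, the canonical overlap table and a JSON
#' run manifest with per-output checksums. Subject-level mapping results
#' are cached under `out_dir/cache` keyed by a hash of the inputs and the
#' map-stage parameters, so a rerun that changes only the overlay
#' threshold reuses the cached t maps.
#'
#' @param config a `pipeline_config` (or path to one).
#' @return The run manifest, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- load ----
  contrasts <- stage("coordinates",
                     parse_contrast_table(config$contrast_table))
  brain <- stage("masks", read_mask(config$brain_mask))
  wm <- if (!is.null(config$wm_mask)) read_mask(config$wm_mask)
  csf <- if (!is.null(config$csf_mask)) read_mask(config$csf_mask)
  atlas <- if (!is.null(config$atlas))
    stage("atlas", read_atlas(config$atlas, config$atlas_names))

  bold_files <- sort(list.files(config$bold_dir,
                                pattern = "\\.nii(\\.gz)?$",
                                full.names = TRUE))
  if (length(bold_files) == 0L)
    stop("pipeline stage 'load' failed: no NIfTI volumes in ",
         config$bold_dir)
  ids <- sub("\\.nii(\\.gz)?$", "", basename(bold_files))

  ages <- NULL
  if (!is.null(config$participants)) {
    ptab <- utils::read.csv(config$participants)
    ages <- stats::setNames(ptab$age, ptab$subject_id)
  }
  subjects <- lapply(seq_along(ids), function(i) {
    mfile <- if (!is.null(config$motion_dir))
      file.path(config$motion_dir, paste0(ids[i], ".txt"))
    list(subject_id = ids[i], file = bold_files[i],
         age = if (is.null(ages)) mean(config$age_range)
               else unname(ages[ids[i]]),
         motion = if (!is.null(mfile) && file.exists(mfile))
           read_motion(mfile))
  })

  # ---- screen ----
  screen <- subject_screen(subjects, age_range = config$age_range)
  keep <- which(screen$retained)
  if (length(keep) < 3L)
    stop("pipeline stage 'screen' failed: only ", length(keep),
         " subject(s) retained")
  subjects <- subjects[keep]

  # ---- map (cached) ----
  map_key <- config_hash(list(
    files = basename(vapply(subjects, `[[`, "", "file")),
    file_md5 = unname(tools::md5sum(vapply(subjects, `[[`, "", "file"))),
    table_md5 = unname(tools::md5sum(config$contrast_table)),
    radius = config$radius_mm, q = config$fdr_q,
    band = c(config$band_low_hz, config$band_high_hz),
    fd = config$fd_spike_mm, clean = config$clean,
    tal = config$tal_method, drop = config$drop_initial))
  cache_dir <- file.path(config$out_dir, "cache", map_key)
  cache_file <- file.path(cache_dir, "stage_map.rds")

  if (file.exists(cache_file)) {
    stage_map <- readRDS(cache_file)
  } else {
    bolds <- lapply(subjects, function(s)
      read_bold(s$file, tr_seconds = config$tr_seconds,
                drop_initial = config$drop_initial,
                subject_id = s$subject_id))
    motion <- lapply(subjects, `[[`, "motion")
    recs <- lapply(contrasts, harmonize_space, method = config$tal_method)
    grid <- bolds[[1]]$grid
    seeds <- lapply(recs, build_contrast_seed,
                    radius_mm = config$radius_mm, grid = grid,
                    brain = brain)
    if (config$clean)
      bolds <- lapply(seq_along(bolds), function(i)
        clean_bold(bolds[[i]], motion[[i]], brain, wm, csf,
                   fd_spike_mm = config$fd_spike_mm,
                   low_hz = config$band_low_hz,
                   high_hz = config$band_high_hz))
    maps <- subject_fc_maps(bolds, seeds, brain,
                            workers = config$workers)
    groups <- split(seq_along(recs),
                    paste(vapply(recs, `[[`, "", "disorder"),
                          vapply(recs, `[[`, "", "modality"),
                          sep = "_"))
    tmaps <- lapply(groups, function(ci)
      lapply(ci, function(i)
        group_ttest(lapply(maps, `[[`, i))))
    binarized <- lapply(tmaps, function(tl)
      lapply(tl, fdr_binarize, q = config$fdr_q, brain = brain))
    stage_map <- list(
      grid = grid, groups = groups, tmaps = tmaps,
      binarized = binarized,
      contrast_ids = vapply(recs, `[[`, "", "contrast_id"),
      seed_sizes = stats::setNames(vapply(seeds, mask_size, 0L),
                                   vapply(recs, `[[`, "", "contrast_id")))
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(stage_map, cache_file, version = 2)
  }

  # ---- overlay / threshold / compare ----
  networks <- list(); prob_maps <- list()
  for (g in names(stage_map$groups)) {
    prob <- overlay_probability(stage_map$binarized[[g]])
    parts <- strsplit(g, "_", fixed = TRUE)[[1]]
    networks[[g]] <- threshold_network(
      prob, config$overlay_threshold,
      provenance = list(disorder = parts[1], modality = parts[2],
                        radius_mm = config$radius_mm,
                        fdr_q = config$fdr_q))
    prob_maps[[g]] <- prob
  }
  for (dis in unique(sub("_.*", "", names(stage_map$groups)))) {
    fk <- paste0(dis, "_functional"); sk <- paste0(dis, "_structural")
    if (!is.null(networks[[fk]]) && !is.null(networks[[sk]]))
      networks[[paste0(dis, "_combined")]] <-
        combine_networks(networks[[fk]], networks[[sk]])
  }

  # ---- write outputs ----
  outputs <- character()
  emit <- function(x, name, ...) {
    p <- file.path(config$out_dir, name)
    write_volume(x, p, ...)
    outputs <<- c(outputs, p)
  }
  for (g in names(stage_map$groups)) {
    ci <- stage_map$groups[[g]]
    for (j in seq_along(ci)) {
      id <- stage_map$contrast_ids[ci[j]]
      emit(stage_map$tmaps[[g]][[j]], sprintf("%s_tmap_%s.nii.gz", g, id))
      emit(stage_map$binarized[[g]][[j]],
           sprintf("%s_binarized_%s.nii.gz", g, id))
    }
    emit(prob_maps[[g]], sprintf("%s_probability.nii.gz", g))
  }
  for (g in names(networks))
    emit(networks[[g]], sprintf("%s_network.nii.gz", g))

  dm <- dice_matrix(networks)
  dice_path <- file.path(config$out_dir, "dice.csv")
  utils::write.csv(as.data.frame(dm), dice_path)
  outputs <- c(outputs, dice_path)

  if (!is.null(atlas)) {
    reports <- lapply(networks, canonical_overlap, atlas = atlas)
    ov_path <- file.path(config$out_dir, "canonical_overlap.csv")
    utils::write.csv(overlap_polar_table(reports), ov_path,
                     row.names = FALSE)
    outputs <- c(outputs, ov_path)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fcnm")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    map_cache_key = map_key,
    subjects_total = nrow(screen),
    subjects_retained = length(keep),
    exclusions = screen[!screen$retained, c("subject_id", "reason"),
                        drop = FALSE],
    seed_sizes = as.list(stage_map$seed_sizes),
    output_md5 = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  invisible(manifest)
}

#' Seed-radius robustness sweep
#'
#' Reruns the network construction at each sweep radius and reports the
#' Dice agreement of every network with its counterpart at the reference
#' radius.
#'
#' @param config a `pipeline_config`.
#' @param radii radii to sweep (default `c(1, 4, 7)` mm).
#' @param reference_mm reference radius (default `config$radius_mm`).
#' @return Data frame `radius_mm`, `network`, `dice_vs_reference`.
#' @export
sweep_radius <- function(config, radii = c(1, 4, 7),
                         reference_mm = config$radius_mm) {
  nets <- lapply(radii, function(r) {
    cfg <- config
    cfg$radius_mm <- r
    cfg$out_dir <- file.path(config$out_dir, sprintf("radius_%gmm", r))
    run_pipeline(cfg)
    nm <- list.files(cfg$out_dir, pattern = "_network\\.nii\\.gz$",
                     full.names = TRUE)
    stats::setNames(lapply(nm, read_mask),
                    sub("_network\\.nii\\.gz$", "", basename(nm)))
  })
  names(nets) <- as.character(radii)
  ref <- nets[[as.character(reference_mm)]]
  if (is.null(ref)) stop("reference radius must be one of the sweep radii")
  out <- do.call(rbind, lapply(as.character(radii), function(r)
    do.call(rbind, lapply(names(ref), function(g)
      data.frame(radius_mm = as.numeric(r), network = g,
                 dice_vs_reference = dice(nets[[r]][[g]], ref[[g]]))))))
  rownames(out) <- NULL
  out
}
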