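# Shared builders and independent oracles. Oracles are deliberately naive
# (loops, whole-grid scans) so they share no code path with the package.

tiny_grid <- function(dim = c(12, 12, 12), voxel = 3) {
  A <- diag(c(voxel, voxel, voxel, 1))
  A[1:3, 4] <- -(dim - 1) / 2 * voxel
  volume_grid(dim, A)
}

full_mask <- function(grid) binary_mask(grid, array(TRUE, dim = grid$dim))

rand_mask <- function(grid, p = 0.3) {
  binary_mask(grid, array(runif(prod(grid$dim)) < p, dim = grid$dim))
}

# fc_map built directly from a z vector (bypasses the correlation path)
map_from_z <- function(grid, z, id = "s") {
  structure(list(grid = grid, z = z, subject_id = id,
                 contrast_id = "c"), class = "fc_map")
}

stat_from_t <- function(grid, tval, df, n = df + 1L) {
  structure(list(grid = grid, t = tval, df = df, n = n),
            class = "group_stat_map")
}

# brute-force Dice: explicit voxel index sets
oracle_dice <- function(a, b) {
  ia <- which(as.vector(a$vox)); ib <- which(as.vector(b$vox))
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# textbook step-up BH over sorted p-values
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= (seq_len(m) / m) * q)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

# whole-grid distance scan for a union of spheres
oracle_sphere <- function(peaks, radius, grid) {
  hit <- array(FALSE, dim = grid$dim)
  for (i in seq_len(grid$dim[1])) for (j in seq_len(grid$dim[2]))
    for (k in seq_len(grid$dim[3])) {
      centre <- (grid$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
      for (p in seq_len(nrow(peaks))) {
        if (sqrt(sum((centre - peaks[p, ])^2)) <= radius) {
          hit[i, j, k] <- TRUE
          break
        }
      }
    }
  hit
}

# minimal compliant synthetic study on a reduced grid
small_study <- function(seed = 5, n_subjects = 6, n_timepoints = 100,
                        n_networks = 3, ...) {
  cfg <- sim_config(grid_dim = c(20, 24, 20), n_subjects = n_subjects,
                    n_timepoints = n_timepoints, n_networks = n_networks,
                    seed = seed, ...)
  atlas <- make_toy_atlas(cfg)
  cohort <- simulate_cohort(cfg, atlas)
  list(cfg = cfg, atlas = atlas, cohort = cohort)
}

write_small_fixture <- function(dir, seed = 5) {
  st <- small_study(seed)
  recs_f <- plant_contrasts(st$atlas, 1, 3, 3, seed = seed + 100,
                            disorder = "SZ", modality = "functional",
                            brain = st$cohort$tissue$brain)
  recs_s <- plant_contrasts(st$atlas, 2, 3, 3, seed = seed + 200,
                            disorder = "SZ", modality = "structural",
                            brain = st$cohort$tissue$brain)
  write_fixture(st$cohort, c(recs_f, recs_s), dir)
  st
}

fixture_pipeline_config <- function(fixture_dir, out_dir, ...) {
  pipeline_config(
    bold_dir = file.path(fixture_dir, "bold"),
    motion_dir = file.path(fixture_dir, "motion"),
    brain_mask = file.path(fixture_dir, "brain.nii.gz"),
    wm_mask = file.path(fixture_dir, "wm.nii.gz"),
    csf_mask = file.path(fixture_dir, "csf.nii.gz"),
    contrast_table = file.path(fixture_dir, "contrasts.csv"),
    atlas = file.path(fixture_dir, "atlas.nii.gz"),
    atlas_names = file.path(fixture_dir, "atlas_labels.csv"),
    participants = file.path(fixture_dir, "participants.csv"),
    out_dir = out_dir, ...)
}
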