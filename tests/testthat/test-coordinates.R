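write_table_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("rows sharing a contrast id group into one record, peaks in file order", {
  path <- write_table_file(c(
    "study_id,contrast_id,disorder,modality,space,x,y,z",
    "s01,s01_c1,SZ,functional,MNI,10,20,30",
    "s01,s01_c1,SZ,functional,MNI,-10,-20,-30",
    "s02,s02_c1,BD,structural,TAL,5,6,7"))
  recs <- parse_contrast_table(path)
  expect_length(recs, 2)
  expect_equal(unname(recs[["s01_c1"]]$peaks),
               matrix(c(10, 20, 30, -10, -20, -30), 2, byrow = TRUE))
  expect_equal(recs[["s01_c1"]]$disorder, "SZ")
  expect_equal(recs[["s02_c1"]]$space, "TAL")
})

test_that("malformed tables fail with informative errors", {
  missing_col <- write_table_file(c(
    "study_id,contrast_id,disorder,modality,x,y,z",
    "s01,c1,SZ,functional,1,2,3"))
  expect_error(parse_contrast_table(missing_col), "space")

  bad_coord <- write_table_file(c(
    "study_id,contrast_id,disorder,modality,space,x,y,z",
    "s01,c1,SZ,functional,MNI,1,2,3",
    "s01,c2,SZ,functional,MNI,abc,2,3"))
  expect_error(parse_contrast_table(bad_coord), "line 3")

  empty <- write_table_file(
    "study_id,contrast_id,disorder,modality,space,x,y,z")
  expect_error(parse_contrast_table(empty), "no data rows")

  bad_enum <- write_table_file(c(
    "study_id,contrast_id,disorder,modality,space,x,y,z",
    "s01,c1,MDD,functional,MNI,1,2,3"))
  expect_error(parse_contrast_table(bad_enum), "disorder")
})

test_that("generated contrast tables parse back with the planted shape", {
  cfg <- sim_config(grid_dim = c(20, 24, 20), n_subjects = 1,
                    n_timepoints = 10, n_networks = 3, seed = 9)
  atlas <- make_toy_atlas(cfg)
  recs <- plant_contrasts(atlas, 2, n_contrasts = 3,
                          peaks_per_contrast = 5, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contrast_table(recs, path)
  parsed <- parse_contrast_table(path)
  expect_length(parsed, 3)
  expect_true(all(vapply(parsed, function(r) nrow(r$peaks), 0L) == 5L))
  expect_equal(unname(parsed[[1]]$peaks), unname(recs[[1]]$peaks))
})

test_that("Talairach conversion is the Lancaster inverse affine, identity on MNI", {
  rec <- contrast_record("s", "c", "SZ", "functional", "MNI",
                         matrix(c(10, 20, 30), 1))
  expect_identical(harmonize_space(rec)$peaks, rec$peaks)

  # inverse of the published MNI->Talairach affine applied to the origin
  origin_mni <- tal_to_mni(c(0, 0, 0))
  expect_equal(unname(origin_mni[1, ]),
               c(1.038658684, 1.457851751, -4.748000809),
               tolerance = 1e-8)

  # affine linearity: f(a) + f(b) - f(0) = f(a + b)
  set.seed(3)
  for (i in 1:10) {
    a <- runif(3, -50, 50); b <- runif(3, -50, 50)
    expect_equal(tal_to_mni(a) + tal_to_mni(b) - tal_to_mni(c(0, 0, 0)),
                 tal_to_mni(a + b), tolerance = 1e-10)
  }

  tal_rec <- contrast_record("s", "c", "SZ", "functional", "TAL",
                             matrix(c(0, 0, 0), 1))
  conv <- harmonize_space(tal_rec)
  expect_equal(conv$space, "MNI")
  expect_equal(unname(conv$peaks[1, ]), unname(origin_mni[1, ]))
})

test_that("the Brett variant differs from Lancaster and respects the z branches", {
  p_up <- c(10, 20, 30); p_down <- c(10, 20, -30)
  expect_false(isTRUE(all.equal(tal_to_mni(p_up, "brett"),
                                tal_to_mni(p_up, "lancaster"))))
  # above-AC branch scales z by 1/0.92, below-AC by 1/0.84 (plus rotation)
  up <- tal_to_mni(p_up, "brett"); down <- tal_to_mni(p_down, "brett")
  expect_gt(up[1, 3], 30)
  expect_lt(down[1, 3], -30)
})

test_that("seed spheres match a whole-grid distance scan", {
  g <- tiny_grid(c(10, 10, 10))
  brain <- full_mask(g)
  peak <- voxel_to_mm(c(5, 5, 5), g)
  for (r in c(1, 4, 7)) {
    rec <- contrast_record("s", "c", "SZ", "functional", "MNI", peak)
    seed <- build_contrast_seed(rec, r, g, brain)
    expect_identical(seed$vox, oracle_sphere(peak, r, g))
  }
  # frozen counts for a peak on a voxel centre of a 3 mm grid
  sizes <- vapply(c(1, 4, 7), function(r)
    mask_size(build_contrast_seed(
      contrast_record("s", "c", "SZ", "functional", "MNI", peak),
      r, g, brain)), 0L)
  expect_equal(sizes, c(1L, 7L, 57L))
})

test_that("off-centre peaks still match the brute-force scan", {
  g <- tiny_grid(c(10, 10, 10))
  brain <- full_mask(g)
  set.seed(4)
  for (i in 1:5) {
    peak <- voxel_to_mm(c(5, 5, 5), g) + runif(3, -1.5, 1.5)
    rec <- contrast_record("s", "c", "SZ", "functional", "MNI", peak)
    seed <- build_contrast_seed(rec, 4, g, brain)
    expect_identical(seed$vox, oracle_sphere(matrix(peak, 1), 4, g))
  }
})

test_that("distant peaks contribute disjoint spheres that add up", {
  g <- volume_grid(c(40, 10, 10),
                   affine = {
                     A <- diag(c(3, 3, 3, 1)); A[1:3, 4] <- c(-58.5, -13.5, -13.5); A
                   })
  brain <- full_mask(g)
  p1 <- voxel_to_mm(c(3, 5, 5), g); p2 <- p1 + c(100, 0, 0)
  both <- contrast_record("s", "c", "SZ", "functional", "MNI", rbind(p1, p2))
  single1 <- contrast_record("s", "c1", "SZ", "functional", "MNI", p1)
  single2 <- contrast_record("s", "c2", "SZ", "functional", "MNI", p2)
  expect_equal(mask_size(build_contrast_seed(both, 4, g, brain)),
               mask_size(build_contrast_seed(single1, 4, g, brain)) +
                 mask_size(build_contrast_seed(single2, 4, g, brain)))
})

test_that("seeds grow monotonically with radius and ignore peak order", {
  g <- tiny_grid(c(14, 14, 14))
  brain <- full_mask(g)
  set.seed(6)
  peaks <- voxel_to_mm(cbind(sample(3:10, 4), sample(3:10, 4),
                             sample(3:10, 4)), g) + runif(12, -1, 1)
  rec <- contrast_record("s", "c", "SZ", "functional", "MNI", peaks)
  rev_rec <- contrast_record("s", "c", "SZ", "functional", "MNI",
                             peaks[4:1, ])
  radii <- c(1, 2, 4, 6)
  seeds <- lapply(radii, function(r) build_contrast_seed(rec, r, g, brain))
  for (i in seq_along(radii)[-1])
    expect_true(all(seeds[[i - 1]]$vox <= seeds[[i]]$vox))
  expect_identical(build_contrast_seed(rev_rec, 4, g, brain)$vox,
                   seeds[[3]]$vox)
})

test_that("seeds stay inside the brain; out-of-brain peaks drop or error", {
  g <- tiny_grid(c(12, 12, 12))
  vox <- array(FALSE, dim = c(12, 12, 12))
  vox[1:6, , ] <- TRUE   # left half of the grid only
  left <- binary_mask(g, vox)
  inside <- voxel_to_mm(c(3, 6, 6), g)
  outside <- voxel_to_mm(c(10, 6, 6), g)

  rec <- contrast_record("s", "cx", "SZ", "functional", "MNI",
                         rbind(inside, outside))
  expect_warning(seed <- build_contrast_seed(rec, 4, g, left),
                 "dropping 1 peak")
  expect_true(all(!seed$vox | left$vox))
  expect_identical(seed$vox,
                   oracle_sphere(inside, 4, g) & left$vox)

  all_out <- contrast_record("s", "cy", "SZ", "functional", "MNI", outside)
  expect_error(suppressWarnings(build_contrast_seed(all_out, 4, g, left)),
               "empty seed.*cy")
})
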