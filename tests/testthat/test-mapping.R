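mask_at <- function(grid, lin) {
  vox <- array(FALSE, grid$dim); vox[lin] <- TRUE
  binary_mask(grid, vox)
}

test_that("seed time course is the unweighted mean over seed voxels", {
  g <- tiny_grid(c(3, 3, 3))
  set.seed(31)
  bold <- bold_series(g, matrix(rnorm(15 * 27), 15), 2)

  expect_equal(seed_timecourse(bold, mask_at(g, 5)), bold$data[, 5])

  bold2 <- bold; bold2$data[, 2] <- -bold2$data[, 1]
  expect_equal(seed_timecourse(bold2, mask_at(g, 1:2)), rep(0, 15))

  idx <- c(1, 4, 9, 13, 20, 22, 27)
  hand <- apply(bold$data[, idx], 1, function(row) sum(row) / 7)
  expect_equal(seed_timecourse(bold, mask_at(g, idx)), hand)

  expect_error(seed_timecourse(bold, mask_at(g, integer(0))), "empty seed")
})

test_that("fc maps are clamped Fisher-z correlations with invalid voxels flagged", {
  g <- tiny_grid(c(3, 3, 3))
  tp <- 40
  set.seed(32)
  dat <- matrix(rnorm(tp * 27), tp)
  # orthonormal construction giving an exact sample correlation of 0.5
  u <- scale(rnorm(tp))[, 1]; v <- residuals(lm(rnorm(tp) ~ u))
  v <- v / sd(v) * sd(u)
  dat[, 1] <- u
  dat[, 2] <- 0.5 * u + sqrt(0.75) * v
  dat[, 3] <- -u          # perfect anti-correlation with the seed
  dat[, 4] <- 2.5         # zero variance
  bold <- bold_series(g, dat, 2)
  brain <- full_mask(g)

  fm <- fc_map(bold, mask_at(g, 1), brain)
  expect_equal(fm$z[2], atanh(0.5), tolerance = 1e-6)
  expect_equal(fm$z[1], atanh(1 - 1e-7))   # self-correlation, clamped
  expect_true(all(is.finite(fm$z[-4])))
  expect_lt(fm$z[3], 0)
  expect_true(is.na(fm$z[4]))
  expect_equal(fm$z[1], max(fm$z, na.rm = TRUE))

  # z agrees with plain cor() everywhere valid (column 4 is constant, so
  # cor() itself warns and returns NA there)
  zz <- suppressWarnings(
    atanh(pmin(pmax(cor(dat[, 1], dat), -1 + 1e-7), 1 - 1e-7)))
  expect_equal(fm$z[-4], zz[-4], tolerance = 1e-10)

  # out-of-brain voxels are invalid
  half <- mask_at(g, 1:13)
  fm2 <- fc_map(bold, mask_at(g, 1), half)
  expect_true(all(is.na(fm2$z[14:27])))

  const_seed <- bold; const_seed$data[, 5] <- 1
  expect_error(fc_map(const_seed, mask_at(g, 5), brain), "constant")
})

test_that("batched per-subject maps equal individual fc_map calls", {
  g <- tiny_grid(c(4, 4, 4))
  set.seed(33)
  bold <- bold_series(g, matrix(rnorm(30 * 64), 30), 2)
  brain <- rand_mask(g, 0.8)
  seeds <- lapply(list(1:3, 10:12, 40), function(lin) {
    m <- mask_at(g, lin); m$contrast_id <- paste0("c", lin[1]); m
  })
  brain$vox[c(1:3, 10:12, 40)] <- TRUE  # seeds must lie in brain
  batch <- fc_maps_for_subject(bold, seeds, brain)
  for (i in seq_along(seeds))
    expect_equal(batch[[i]]$z, fc_map(bold, seeds[[i]], brain)$z)
})

test_that("the voxelwise one-sample t-test matches hand computation", {
  g <- tiny_grid(c(2, 2, 2))
  maps <- lapply(c(1, 2, 3), function(v) map_from_z(g, rep(v, 8)))
  st <- group_ttest(maps)
  expect_equal(st$df, 2L)
  expect_equal(unname(st$t), rep(2 * sqrt(3), 8), tolerance = 1e-12)

  # identical non-constant maps: sd = 0 everywhere, flagged invalid
  same <- lapply(1:3, function(i) map_from_z(g, seq_len(8) / 10))
  expect_true(all(is.na(group_ttest(same)$t)))

  other <- map_from_z(tiny_grid(c(2, 2, 3)), rep(0, 12))
  expect_error(group_ttest(list(maps[[1]], maps[[2]], other)), "grid")
  expect_error(group_ttest(maps[1:2]), "at least 3")
})

test_that("null t statistics follow the Student-t reference distribution", {
  g <- volume_grid(c(25, 20, 20))
  n <- 10
  set.seed(34)
  maps <- lapply(seq_len(n), function(i) map_from_z(g, rnorm(10000)))
  st <- group_ttest(maps)
  ks <- ks.test(st$t, "pt", df = n - 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("BH selection matches the step-up oracle and its edge cases", {
  # m = 1 reduces to p <= q
  expect_true(bh_reject(0.01, 0.05))
  expect_false(bh_reject(0.06, 0.05))

  p <- 0.001 * (1:100)
  expect_identical(bh_reject(p, 0.05), oracle_bh(p, 0.05))

  set.seed(35)
  for (i in 1:20) {
    m <- sample(c(5, 50, 500), 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(bh_reject(p, 0.05), oracle_bh(p, 0.05))
  }
})

test_that("FDR binarisation is one-sided and restricted to valid voxels", {
  g <- tiny_grid(c(4, 4, 4))
  brain <- full_mask(g)

  neg <- stat_from_t(g, rep(-3, 64), df = 19)
  expect_equal(mask_size(fdr_binarize(neg, 0.05, brain)), 0L)

  # a single testable voxel: survives iff its right-tail p <= q
  tv <- rep(NA_real_, 64); tv[10] <- qt(0.99, df = 19)
  one <- stat_from_t(g, tv, df = 19)
  expect_identical(which(fdr_binarize(one, 0.05, brain)$vox), 10L)
  tv[10] <- qt(0.93, df = 19)
  expect_equal(mask_size(fdr_binarize(stat_from_t(g, tv, df = 19),
                                      0.05, brain)), 0L)

  # random t map: survivors equal the oracle applied to one-sided p
  set.seed(36)
  tv <- rnorm(64, mean = 1)
  st <- stat_from_t(g, tv, df = 9)
  got <- fdr_binarize(st, 0.05, brain)
  p <- pt(tv, 9, lower.tail = FALSE)
  expect_identical(as.vector(got$vox), oracle_bh(p, 0.05))

  # invalid voxels are excluded from the multiplicity burden
  tv2 <- tv; tv2[1:32] <- NA
  got2 <- fdr_binarize(stat_from_t(g, tv2, df = 9), 0.05, brain)
  expect_identical(as.vector(got2$vox)[33:64],
                   oracle_bh(p[33:64], 0.05))

  all_na <- stat_from_t(g, rep(NA_real_, 64), df = 9)
  expect_error(fdr_binarize(all_na, 0.05, brain), "no valid")
})

test_that("probability overlay counts contrasts and is order-invariant", {
  g <- tiny_grid(c(3, 3, 3))
  set.seed(37)
  masks <- lapply(1:10, function(i) rand_mask(g, 0.4))

  single <- overlay_probability(masks[1])
  expect_equal(single$prob, as.numeric(masks[[1]]$vox))

  prob <- overlay_probability(masks)
  counts <- Reduce(`+`, lapply(masks, function(m) as.numeric(m$vox)))
  expect_equal(prob$prob, as.vector(counts) / 10)
  expect_true(all(abs(prob$prob * 10 - round(prob$prob * 10)) < 1e-9))

  shuf <- overlay_probability(masks[sample(10)])
  expect_equal(shuf$prob, prob$prob)
})

test_that("network thresholding is inclusive and nested", {
  g <- tiny_grid(c(3, 3, 3))
  set.seed(38)
  masks <- lapply(1:10, function(i) rand_mask(g, 0.5))
  prob <- overlay_probability(masks)

  net60 <- threshold_network(prob, 0.60)
  at60 <- which(abs(prob$prob - 0.6) < 1e-12)
  expect_true(all(net60$vox[at60]))   # exactly 60% is included

  net80 <- threshold_network(prob, 0.80)
  expect_true(all(!net80$vox | net60$vox))

  inter <- threshold_network(prob, 1.0)
  expect_identical(inter$vox, Reduce(`&`, lapply(masks, `[[`, "vox")))
})

test_that("combining networks is a voxelwise union with combined provenance", {
  g <- tiny_grid(c(3, 3, 3))
  mk <- function(lin) {
    prob <- overlay_probability(list(mask_at(g, lin)))
    threshold_network(prob, 0.6, provenance = list(disorder = "SZ",
                                                   modality = "functional"))
  }
  a <- mk(1:5); b <- mk(10:12); b_sub <- mk(c(1:5, 10:12))

  expect_equal(mask_size(combine_networks(a, b)), 8L)
  expect_identical(combine_networks(a, b_sub)$vox, b_sub$vox)
  expect_equal(combine_networks(a, a)$provenance$modality, "combined")
})
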