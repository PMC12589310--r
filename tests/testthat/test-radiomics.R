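test_that("filter bank yields 8 wavelet bands; high-pass kills constants; LoG kills ramps", {
  vol <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  wb <- wavelet_bands(vol)
  expect_length(wb, 8)
  expect_setequal(names(wb), c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH",
                               "LHH", "HHH"))
  const <- array(4, c(8, 8, 8))
  wbc <- wavelet_bands(const)
  for (b in setdiff(names(wbc), "LLL")) {
    expect_lt(max(abs(wbc[[b]])), 1e-10)
  }
  ## Laplacian of a linear field vanishes in the interior
  ramp <- array(0, c(14, 14, 14))
  for (x in 1:14) ramp[x, , ] <- 3 * x
  lg <- log_response(ramp, 1.0)
  interior <- lg[5:10, 5:10, 5:10]
  expect_lt(max(abs(interior)), 1e-8)
  expect_error(log_response(ramp, -1), "sigma")

  bank <- filter_bank(vol)
  expect_length(bank, 11)
  expect_identical(names(bank)[1], "original")
})

test_that("the default inventory is exactly 1015 uniquely named deterministic features", {
  cfg <- small_phantom(n_subjects = 2, seed = 40)
  s <- generate_cohort(cfg)[[1]]
  pair <- subject_pair(s)
  fv <- extract_features(pair, pair$voi_mask)
  expect_length(fv, 1015)
  expect_identical(anyDuplicated(names(fv)), 0L)
  expect_identical(names(fv), feature_names(feature_config()))
  expect_false(any(is.na(fv)))
  ## repeated extraction is bitwise identical
  fv2 <- extract_features(pair, pair$voi_mask)
  expect_identical(fv, fv2)
})

test_that("constant-intensity regions degenerate to single-bin texture", {
  pet <- array(5, c(6, 6, 4))
  ct <- array(rnorm(144), c(6, 6, 4))
  mask <- array(1L, c(6, 6, 4))
  pair <- volume_pair(pet, ct, mask)
  fv <- extract_features(pair, mask, feature_config(image_types = "original"))
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
  expect_equal(unname(fv["original_firstorder_Entropy"]), 0)
  expect_equal(unname(fv["original_glcm_Contrast"]), 0)
})

test_that("small regions yield a flagged missing-value vector", {
  pet <- array(rnorm(64), c(4, 4, 4))
  mask <- array(0L, c(4, 4, 4)); mask[1:3] <- 1L
  pair <- volume_pair(pet, pet, array(1L, c(4, 4, 4)))
  fv <- extract_features(pair, mask)
  expect_true(all(is.na(fv)))
  expect_match(attr(fv, "reason"), "voxels")
})

test_that("GLCM matches hand enumeration on strips and checkerboards", {
  ## 1D strip bins (1,1,2,2), distance 1: symmetrized pair multiset
  lev <- array(NA_integer_, c(4, 1, 1))
  lev[, 1, 1] <- c(1L, 1L, 2L, 2L)
  P <- glcm_matrix(lev, 2)
  expect_equal(sum(P), 1)
  expect_equal(P, matrix(c(2, 1, 1, 2) / 6, 2, 2))

  ## checkerboard: all mass off-diagonal
  chk <- array(NA_integer_, c(6, 1, 1))
  chk[, 1, 1] <- rep(c(1L, 2L), 3)
  Pc <- glcm_matrix(chk, 2)
  expect_equal(Pc[1, 1] + Pc[2, 2], 0)
  expect_equal(sum(Pc), 1)

  ## random 4x4x1 block vs brute-force pair counting over 13 directions
  set.seed(77)
  lv <- array(NA_integer_, c(4, 4, 2))
  lv[] <- sample(1:3, 32, replace = TRUE)
  lv[sample(32, 6)] <- NA
  P3 <- glcm_matrix(lv, 3)
  counts <- matrix(0, 3, 3)
  dims <- dim(lv)
  for (x in 1:4) for (y in 1:4) for (z in 1:2) {
    for (r in seq_len(nrow(habitatPET:::DIRECTIONS_3D))) {
      d <- habitatPET:::DIRECTIONS_3D[r, ]
      xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
      if (xx < 1 || xx > 4 || yy < 1 || yy > 4 || zz < 1 || zz > 2) next
      a <- lv[x, y, z]; b <- lv[xx, yy, zz]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  expect_equal(P3, counts / sum(counts))
})

test_that("probability matrices sum to one and aggregated features are rotation invariant", {
  cfg <- small_phantom(n_subjects = 2, seed = 55)
  s <- generate_cohort(cfg)[[1]]
  pair <- subject_pair(s)
  in_region <- pair$voi_mask != 0
  lev <- array(NA_integer_, dim(pair$pet))
  lev[in_region] <- discretize(pair$pet[in_region], 0.5,
                               min(pair$pet[in_region]))
  P <- glcm_matrix(lev, max(lev, na.rm = TRUE))
  expect_equal(sum(P), 1, tolerance = 1e-9)

  ## 90-degree in-plane rotation leaves angle-aggregated features unchanged
  cfg_t <- feature_config(image_types = "original")
  set.seed(5)
  vol <- array(rnorm(14 * 14 * 8, 5, 2), c(14, 14, 8))
  msk <- array(0L, c(14, 14, 8))
  for (x in 1:14) for (y in 1:14) for (z in 1:8) {
    if ((x - 6)^2 / 25 + (y - 8)^2 / 16 + (z - 4)^2 / 9 <= 1)
      msk[x, y, z] <- 1L
  }
  rot <- function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  p1 <- volume_pair(vol, vol, msk)
  p2 <- volume_pair(rot(vol), rot(vol), array(as.integer(rot(msk)),
                                              dim(rot(msk))))
  f1 <- extract_features(p1, p1$voi_mask, cfg_t)
  f2 <- extract_features(p2, p2$voi_mask, cfg_t)
  tex <- grep("glcm|glrlm|glszm|gldm|ngtdm|firstorder", names(f1),
              value = TRUE)
  expect_equal(f1[tex], f2[tex], tolerance = 1e-6)
})

test_that("texture families are invariant to intensity shifts under region-anchored binning", {
  cfg <- small_phantom(n_subjects = 2, seed = 66)
  s <- generate_cohort(cfg)[[1]]
  pair1 <- subject_pair(s)
  pair2 <- volume_pair(pair1$pet + 100, pair1$ct, pair1$voi_mask,
                       pair1$spacing)
  cfg_t <- feature_config(image_types = "original")
  f1 <- extract_features(pair1, pair1$voi_mask, cfg_t)
  f2 <- extract_features(pair2, pair2$voi_mask, cfg_t)
  tex <- grep("glcm|glrlm|glszm|gldm|ngtdm", names(f1), value = TRUE)
  expect_equal(f1[tex], f2[tex], tolerance = 1e-9)
})

test_that("single-voxel regions produce an empty co-occurrence matrix", {
  lev <- array(NA_integer_, c(3, 3, 3))
  lev[2, 2, 2] <- 1L
  P <- glcm_matrix(lev, 1)
  expect_equal(sum(P), 0)
})
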