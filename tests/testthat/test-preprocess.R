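test_that("identity resample returns the input and constants stay constant", {
  pair <- ramp_pair()
  expect_identical(resample_to_grid(pair, c(1, 1, 1)), pair)

  const <- volume_pair(array(7, c(8, 8, 8)), array(-3, c(8, 8, 8)),
                       array(1L, c(8, 8, 8)), spacing = c(2, 1.5, 1))
  rs <- resample_to_grid(const, c(1, 1, 1))
  expect_true(all(abs(rs$pet - 7) < 1e-12))
  expect_true(all(abs(rs$ct + 3) < 1e-12))
  expect_true(all(rs$voi_mask %in% c(0L, 1L)))
  expect_error(resample_to_grid(pair, c(0, 1, 1)), "positive")
})

test_that("downsampling a linear ramp reproduces the analytic ramp at new centres", {
  pair <- ramp_pair(n = c(16L, 8L, 6L))
  rs <- resample_to_grid(pair, c(2, 2, 2))
  ## PET value at new centre x_new = 2 * (i - 1) equals the ramp value there
  for (i in seq_len(dim(rs$pet)[1])) {
    expect_equal(rs$pet[i, 2, 2], 2 * (i - 1), tolerance = 1e-10)
  }
  ## physical extent preserved within one voxel
  old_extent <- (dim(pair$pet) - 1) * pair$spacing
  new_extent <- (dim(rs$pet) - 1) * rs$spacing
  expect_true(all(abs(old_extent - new_extent) <= 2))
})

test_that("mask volume is approximately conserved under resampling of an ellipsoid", {
  cfg <- small_phantom(n_subjects = 2, seed = 8)
  s <- generate_cohort(cfg)[[1]]
  pair <- subject_pair(s)
  rs <- resample_to_grid(pair, c(0.8, 0.8, 0.8))
  v0 <- sum(pair$voi_mask) * prod(pair$spacing)
  v1 <- sum(rs$voi_mask) * prod(rs$spacing)
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("super-resolution is identity at factor 1 and exact on constants and ramps", {
  vol <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  expect_identical(super_resolve(vol, 1L), vol)
  expect_error(super_resolve(vol, 3L), "factor")

  const <- array(2.5, c(4, 4, 4))
  up <- super_resolve(const, 2L)
  expect_identical(dim(up), c(8L, 8L, 8L))
  expect_true(all(abs(up - 2.5) < 1e-12))

  ramp <- array(0, c(6, 4, 4))
  for (x in 1:6) ramp[x, , ] <- 2 * (x - 1)
  up2 <- super_resolve(ramp, 2L)
  ## new centre j (1-based) sits at old index (j-1)/2: value 2*(j-1)/2
  for (j in seq_len(dim(up2)[1])) {
    expect_equal(up2[j, 1, 1], (j - 1), tolerance = 1e-9)
  }
  ## VOI mean preserved within 1% for an intensity field smooth at the
  ## voxel scale (sharp lesion-background edges bleed at the boundary and
  ## are not a property of the interpolant)
  n <- c(20L, 20L, 14L)
  sm <- array(0, n)
  for (x in 1:n[1]) for (y in 1:n[2]) for (z in 1:n[3]) {
    sm[x, y, z] <- 5 + 2 * sin(x / 6) + cos(y / 5) + 0.5 * sin(z / 4)
  }
  msk <- array(0L, n)
  for (x in 1:n[1]) for (y in 1:n[2]) for (z in 1:n[3]) {
    if ((x - 10)^2 / 36 + (y - 10)^2 / 36 + (z - 7)^2 / 16 <= 1)
      msk[x, y, z] <- 1L
  }
  prs <- preprocess_pair(volume_pair(sm, sm, msk),
                         preprocess_config(sr_factor = 2L))
  m0 <- mean(sm[msk == 1])
  m1 <- mean(prs$pet[prs$voi_mask == 1])
  expect_lt(abs(m1 - m0) / abs(m0), 0.01)
})

test_that("intensity normalization modes implement their affine maps", {
  vol <- array(c(2, 4, 6, 100), c(2, 2, 1))
  mask <- array(c(1, 1, 1, 0), c(2, 2, 1))
  expect_identical(normalize_intensity(vol, mask, "none"), vol)
  mm <- normalize_intensity(vol, mask, "minmax")
  expect_equal(mm[c(1, 2, 3)], c(0, 0.5, 1))
  expect_equal(mm[4], (100 - 2) / 4)  # same affine map outside the VOI
  zs <- normalize_intensity(vol, mask, "zscore")
  v <- zs[c(1, 2, 3)]
  expect_equal(mean(v), 0)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1)
  expect_error(normalize_intensity(array(5, c(2, 1, 1)),
                                   array(1, c(2, 1, 1)), "zscore"),
               "variance")
})

test_that("discretization follows the floor rule and matches a histogram oracle", {
  expect_identical(discretize(c(0, 0.24, 0.25), 0.25, 0), c(1L, 1L, 2L))
  expect_identical(discretize(rep(3.3, 5), 10), rep(1L, 5))
  set.seed(9)
  v <- rnorm(500)
  bw <- 0.3
  idx <- discretize(v, bw)
  ## order-preserving
  expect_true(all(diff(idx[order(v)]) >= 0))
  ## counts equal a brute-force histogram with the same edges
  edges <- min(v) + bw * (0:ceiling((max(v) - min(v)) / bw + 1))
  hist_counts <- as.integer(table(cut(v, edges, right = FALSE,
                                      include.lowest = FALSE)))
  got <- tabulate(idx, nbins = length(edges) - 1)
  expect_identical(got, hist_counts)
  ## un-discretization to bin centres moves values by < bin_width / 2
  centres <- min(v) + (idx - 0.5) * bw
  expect_lt(max(abs(centres - v)), bw / 2 + 1e-12)
})

test_that("the pipeline is idempotent on already-conformed input", {
  pair <- ramp_pair()
  out <- preprocess_pair(pair, preprocess_config(target_spacing = c(1, 1, 1),
                                                 sr_factor = 1L,
                                                 normalization = "none"))
  expect_identical(out, pair)
})
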