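test_that("resampling to the native grid is the identity", {
  g <- generate_pre(phantom_config(grid_shape = 32, seed = 1))
  out <- normalize_resolution(g$volume, 1, 32)
  expect_identical(out$data, g$volume$data)
})

test_that("a constant coarse volume resamples to a constant", {
  v <- vol3d(array(7, c(16, 16, 16)), spacing = c(2, 2, 2))
  out <- suppressWarnings(normalize_resolution(v, 1, 24))  # 32 mm fov -> crop
  expect_true(all(abs(out$data - 7) < 1e-12))
  expect_equal(dim(out$data), c(24L, 24L, 24L))
})

test_that("mask volume in mm^3 is preserved across resampling", {
  cfg <- phantom_config(grid_shape = 48, voxel_spacing = c(2, 2, 2), seed = 6)
  g <- generate_pre(cfg)
  s <- apply_surgery(g$volume, g$truth, cfg)
  m <- s$resection_mask
  vol_in <- sum(m$data) * prod(m$spacing)
  out <- normalize_resolution(m, 1, 96)
  vol_out <- sum(out$data) * 1
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.05)
})

test_that("oversized fields of view are cropped with a warning", {
  v <- vol3d(array(1, c(20, 20, 20)), spacing = c(2, 2, 2))
  expect_warning(normalize_resolution(v, 1, 24), "centre-cropped")
})

test_that("top-percentile clamping matches direct computation", {
  d <- c(10, 10, 10)
  arr <- array(0, d)
  arr[1:100] <- 1:100
  brain <- array(FALSE, d); brain[1:100] <- TRUE
  v <- vol3d(arr)
  out <- clamp_top_percentile(v, binary_mask(brain))
  expect_equal(out$data[100], 50.5)   # the top voxel -> median
  expect_equal(out$data[99], 99)      # below the 99th percentile threshold
  # constant volumes are unchanged
  vc <- vol3d(array(5, d))
  expect_equal(clamp_top_percentile(vc, binary_mask(brain))$data, vc$data)
})

test_that("clamping is idempotent up to the percentile shift", {
  g <- generate_pre(phantom_config(grid_shape = 48, seed = 8))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  c1 <- clamp_top_percentile(mb$masked, mb$brain)
  c2 <- clamp_top_percentile(c1, mb$brain)
  changed <- mean(c2$data[mb$brain$data] != c1$data[mb$brain$data])
  expect_lt(changed, 0.015)
})

test_that("bias estimation recovers the phantom field", {
  g <- cached("bias48", generate_pre(phantom_config(grid_shape = 48,
                                                    noise_sigma = 0.02,
                                                    bias_amplitude = 0.1,
                                                    seed = 11)))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  bc <- correct_bias(mb$masked, mb$brain)
  rel <- (bc$field$data - g$truth$bias_field$data) / g$truth$bias_field$data
  expect_lt(sqrt(mean(rel[mb$brain$data]^2)), 0.05)
  # corrected volume is exactly input / field
  expect_equal(bc$corrected$data, mb$masked$data / bc$field$data, tolerance = 0)
})

test_that("with no bias present the estimated field is flat", {
  g <- generate_pre(phantom_config(grid_shape = 48, noise_sigma = 0.02,
                                   bias_amplitude = 0, seed = 12))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  bc <- correct_bias(mb$masked, mb$brain)
  expect_true(all(abs(bc$field$data[mb$brain$data] - 1) < 0.02))
})

test_that("lobe atlas assembly maps codes and rejects unmapped ones", {
  g <- generate_pre(phantom_config(grid_shape = 32, seed = 2))
  atlas <- build_lobe_atlas(g$truth$regions)
  # round trip: on labelled grey matter the atlas equals the phantom lobes
  gm <- atlas$data %in% c(1:6, 11:16)
  expect_true(all(atlas$data[gm] == g$truth$lobe_labels$data[gm]))
  # ventricles go to Excluded
  vents <- g$truth$regions$data %in% c(4L, 43L)
  expect_true(all(atlas$data[vents] == 7L))
  # unmapped codes are named in the error
  bad <- g$truth$regions
  bad$data[1] <- 999L
  bad$legend <- c(bad$legend, mystery = 999L)
  expect_error(build_lobe_atlas(bad), "999")
})

test_that("a single mapped region yields a single nonzero lobe code", {
  d <- c(12, 12, 12)
  arr <- array(0L, d); arr[5:7, 5:7, 5:7] <- 17L
  regions <- label_volume(arr, c(hippo = 17L))
  mapping <- data.frame(code = 17L, region = "hippocampus",
                        lobe = "SubCortical", hemisphere = "L")
  atlas <- build_lobe_atlas(regions, mapping)
  expect_identical(sort(unique(atlas$data[atlas$data > 0L])), 6L)
})

test_that("brain masking zeroes exactly the voxels outside the atlas", {
  g <- generate_pre(phantom_config(grid_shape = 32, seed = 2))
  atlas <- build_lobe_atlas(g$truth$regions)
  v <- g$volume
  v$data[1, 1, 1] <- 500
  mb <- mask_brain(v, atlas)
  expect_equal(mb$masked$data[1, 1, 1], 0)
  inside <- atlas$data > 0L
  expect_true(all(mb$masked$data[inside] == v$data[inside]))
  expect_lte(sum(mb$masked$data != 0), sum(inside))
})

test_that("atlas dilation labels every brain voxel deterministically", {
  g <- generate_pre(phantom_config(grid_shape = 48, seed = 2))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  f1 <- dilate_atlas_through_wm(atlas, mb$brain)
  f2 <- dilate_atlas_through_wm(atlas, mb$brain)
  expect_identical(f1$data, f2$data)
  expect_true(all(f1$data[mb$brain$data] %in% c(1:7, 11:16)))
  # Excluded voxels keep their code
  expect_true(all(f1$data[atlas$data == 7L] == 7L))
  # no left code appears in the right half-space and vice versa
  d <- dim(f1$data)
  left <- array(seq_len(d[1]), d) < (d[1] + 1) / 2
  expect_false(any(f1$data[!left] %in% 1:6))
  expect_false(any(f1$data[left] %in% 11:16))
})

test_that("dilation assigns the nearest label (propagation-distance oracle)", {
  # open 13^3 box, two grey labels at opposite x-ends -> nearest-label (by
  # 6-connected propagation rounds = Manhattan distance) partition
  d <- c(13, 13, 13)
  arr <- array(8L, d)                 # unassigned white matter everywhere
  arr[1, 7, 7] <- 3L                  # Temporal-L seed
  arr[13, 7, 7] <- 1L                 # would be Frontal, but same hemisphere:
  arr[13, 7, 7] <- 4L                 # use Occipital-L to keep one hemisphere
  regions <- label_volume(arr, c(wm = 8L, t = 3L, o = 4L))
  atlas <- regions
  brain <- binary_mask(array(TRUE, d))
  # restrict to a single hemisphere by keeping all x in the left half: embed
  # into a 26-wide volume instead
  d2 <- c(26, 13, 13)
  arr2 <- array(0L, d2)
  arr2[1:13, , ] <- arr
  atlas2 <- label_volume(arr2, lobe_atlas_legend_codes())
  brain2 <- binary_mask(array(c(rep(TRUE, 13), rep(FALSE, 13))[
    rep(1:26, times = 13 * 13)] , d2))
  full <- dilate_atlas_through_wm(atlas2, brain2)
  ix <- array(seq_len(d2[1]), d2)
  iy <- array(rep(seq_len(d2[2]), each = d2[1]), d2)
  iz <- array(rep(seq_len(d2[3]), each = d2[1] * d2[2]), d2)
  man_t <- abs(ix - 1) + abs(iy - 7) + abs(iz - 7)
  man_o <- abs(ix - 13) + abs(iy - 7) + abs(iz - 7)
  inb <- brain2$data
  expect_true(all(full$data[inb & man_t < man_o] == 3L))
  expect_true(all(full$data[inb & man_o < man_t] == 4L))
  # ties broken toward the lowest lobe code (3 = Temporal < 4 = Occipital)
  expect_true(all(full$data[inb & man_o == man_t] == 3L))
})

test_that("a WM voxel surrounded only by Temporal-L grey becomes Temporal-L", {
  d <- c(9, 9, 9)
  arr <- array(0L, d)
  arr[4:6, 4:6, 4:6] <- 3L
  arr[5, 5, 5] <- 8L
  atlas <- label_volume(arr, lobe_atlas_legend_codes())
  brain <- binary_mask(arr > 0L)
  full <- dilate_atlas_through_wm(atlas, brain)
  expect_equal(full$data[5, 5, 5], 3L)
})

test_that("lobe splitting is disjoint and exhaustive with T-expansion", {
  g <- generate_pre(phantom_config(grid_shape = 48, seed = 2))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  full <- dilate_atlas_through_wm(atlas, mb$brain)
  spl <- split_resection_lobes(full, resection_spec("L", "T"))
  expect_false(any(spl$resected$data & spl$other$data))
  non_excl <- full$data %in% c(1:6, 11:16)
  expect_true(all((spl$resected$data | spl$other$data) == non_excl))
  # temporal filter includes SubCortical and Insula of the same hemisphere
  expect_true(any(spl$resected$data & full$data == 6L))
  expect_true(any(spl$resected$data & full$data == 5L))
  # left selection stays in the left hemisphere
  d <- dim(full$data)
  left <- array(seq_len(d[1]), d) < (d[1] + 1) / 2
  expect_false(any(spl$resected$data & !left))
  # the default spec selects everything
  spl_all <- split_resection_lobes(full, resection_spec())
  expect_equal(sum(spl_all$other$data), 0)
  # selecting an absent region errors
  d1 <- c(8, 8, 8)
  arr <- array(0L, d1); arr[3:5, 3:5, 3:5] <- 3L
  small <- label_volume(arr, lobe_atlas_legend_codes())
  expect_error(split_resection_lobes(small, resection_spec("R", "F")),
               "empty region")
})
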