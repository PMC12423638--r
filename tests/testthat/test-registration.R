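reg_fixture <- function() {
  cached("reg48", {
    pair <- make_misalignment_pair(seed = 5, grid_shape = 48)
    atlas <- build_lobe_atlas(pair$truth$regions)
    mb <- mask_brain(pair$pre, atlas)
    c(pair, list(brain = mb$brain))
  })
}

test_that("registering a volume to itself returns the identity", {
  fx <- reg_fixture()
  est <- suppressWarnings(register_rigid(fx$pre, fx$pre, fx$brain))
  dev <- rigid_deviation(est, rigid_transform(center = est$center))
  expect_lt(dev[["trans_mm"]], 0.1)
  expect_lt(dev[["rot_deg"]], 0.1)
})

test_that("a known rigid offset is recovered within 0.5 mm and 0.5 degrees", {
  fx <- reg_pair96()
  dev <- rigid_deviation(fx$est, fx$truth$rigid_transform)
  expect_lt(dev[["trans_mm"]], 0.5)
  expect_lt(dev[["rot_deg"]], 0.5)
})

test_that("rigid registration is deterministic across reruns", {
  fx <- reg_fixture()
  est <- suppressWarnings(register_rigid(fx$pre, fx$post, fx$brain))
  est2 <- suppressWarnings(register_rigid(fx$pre, fx$post, fx$brain))
  expect_identical(est$rot_deg, est2$rot_deg)
  expect_identical(est$trans_mm, est2$trans_mm)
})

test_that("forward and reverse registrations compose to near-identity", {
  fx <- reg_fixture()
  atlas_post <- build_lobe_atlas(fx$truth$labels_post)
  brain_post <- binary_mask(atlas_post$data > 0L, fx$post$spacing, fx$post$origin)
  ab <- suppressWarnings(register_rigid(fx$pre, fx$post, fx$brain))
  ba <- suppressWarnings(register_rigid(fx$post, fx$pre, brain_post))
  comp <- compose_rigid(ab, ba)
  idx <- which(fx$brain$data, arr.ind = TRUE)
  idx <- idx[seq(1, nrow(idx), length.out = 500), , drop = FALSE]
  w <- sweep(idx - 1, 2, fx$pre$spacing, `*`)
  mp <- map_rigid(comp, w[, 1], w[, 2], w[, 3])
  disp <- sqrt((mp$x - w[, 1])^2 + (mp$y - w[, 2])^2 + (mp$z - w[, 3])^2)
  expect_lt(max(disp), 1)
})

test_that("identity chains and integer translations behave exactly", {
  g <- generate_pre(phantom_config(grid_shape = 24, seed = 3))
  ch <- transform_chain(rigid = rigid_transform(center = grid_center_of(g$volume)),
                        fixed_grid = g$volume)
  out <- apply_chain(g$volume, ch)
  expect_equal(out$data, g$volume$data, tolerance = 1e-12)
  # a pure 3 mm (3 voxel) translation applied to a mask shifts it exactly
  m <- binary_mask(g$truth$tissue_labels$data == 4L)
  tr <- rigid_transform(trans_mm = c(3, 0, 0), center = grid_center_of(g$volume))
  shifted <- apply_chain(m, transform_chain(rigid = tr, fixed_grid = g$volume))
  d <- dim(m$data)
  expect_identical(shifted$data[1:(d[1] - 3), , ], m$data[4:d[1], , ])
})

test_that("deformable stage returns a null field for identical images", {
  fx <- reg_fixture()
  fld <- register_deformable(fx$pre, fx$pre, fx$brain)
  mag <- sqrt(fld$ux^2 + fld$uy^2 + fld$uz^2)
  expect_lt(quantile(mag, 0.99, names = FALSE), 0.2)
})

test_that("field vanishes outside the brain mask margin", {
  fx <- reg_fixture()
  fld <- register_deformable(fx$pre, fx$post, fx$brain)
  margin <- mask_dilate(fx$brain, rounds = 3L, conn = 6L)$data
  mag <- sqrt(fld$ux^2 + fld$uy^2 + fld$uz^2)
  expect_true(all(mag[!margin] == 0))
})

test_that("deformable stage recovers a recoverable smooth deformation", {
  g <- cached("def48", generate_pre(phantom_config(
    grid_shape = 48, noise_sigma = 0, bias_amplitude = 0,
    sagging_magnitude = 0,
    rigid_offset = c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0),
    seed = 11)))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  d <- dim(g$volume$data)
  base_idx <- resectr_index_arrays(d)
  shifted <- array(resectr:::cpp_sample(as.numeric(g$volume$data), d,
                   (base_idx$x - 1) + 2, base_idx$y - 1, base_idx$z - 1, 1L, 0), d)
  mv <- vol3d(shifted, g$volume$spacing)
  fld <- register_deformable(g$volume, mv, mb$brain)
  f_arr <- resectr:::robust_unit(g$volume$data, mb$brain$data)
  m_arr <- resectr:::robust_unit(mv$data, mb$brain$data)
  mw <- array(resectr:::cpp_sample(as.numeric(m_arr), d,
              (base_idx$x - 1) + fld$ux, (base_idx$y - 1) + fld$uy,
              (base_idx$z - 1) + fld$uz, 1L, NA_real_), d)
  mw[is.na(mw)] <- f_arr[is.na(mw)]
  ratio <- mean(((f_arr - mw)[mb$brain$data])^2) /
    mean(((f_arr - m_arr)[mb$brain$data])^2)
  expect_lt(ratio, 0.6)
})

test_that("deformable stage does not degrade a sagging-only phantom", {
  # the sag field moves same-class tissue by sub-voxel to ~2-voxel amounts;
  # even the exact inverse map cannot halve the masked MSD here (interface
  # interpolation blur dominates), so the contract is non-degradation
  cfg <- phantom_config(grid_shape = 48, noise_sigma = 0, bias_amplitude = 0,
                        sagging_magnitude = 2,
                        rigid_offset = c(tx = 0, ty = 0, tz = 0,
                                         rx = 0, ry = 0, rz = 0), seed = 11)
  g <- generate_pre(cfg)
  s <- apply_surgery(g$volume, g$truth, cfg, carve = FALSE)
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  fld <- register_deformable(g$volume, s$volume, mb$brain)
  d <- dim(g$volume$data)
  base_idx <- resectr_index_arrays(d)
  f_arr <- resectr:::robust_unit(g$volume$data, mb$brain$data)
  m_arr <- resectr:::robust_unit(s$volume$data, mb$brain$data)
  mw <- array(resectr:::cpp_sample(as.numeric(m_arr), d,
              (base_idx$x - 1) + fld$ux, (base_idx$y - 1) + fld$uy,
              (base_idx$z - 1) + fld$uz, 1L, NA_real_), d)
  mw[is.na(mw)] <- f_arr[is.na(mw)]
  ratio <- mean(((f_arr - mw)[mb$brain$data])^2) /
    mean(((f_arr - m_arr)[mb$brain$data])^2)
  expect_lt(ratio, 1)
})

test_that("label agreement in the brain rises after registration", {
  cs <- suite48()$d
  atlas <- build_lobe_atlas(cs$truth$regions)
  mb <- mask_brain(cs$pre, atlas)
  est <- suppressWarnings(register_rigid(cs$pre, cs$post, mb$brain))
  chain <- transform_chain(rigid = est, fixed_grid = cs$pre)
  warped <- apply_chain(cs$truth$labels_post, chain)
  inb <- mb$brain$data
  before <- mean(cs$truth$labels_post$data[inb] == cs$truth$regions$data[inb])
  after <- mean(warped$data[inb] == cs$truth$regions$data[inb])
  expect_gt(after, before)
})
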