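test_that("unit rescale maps the robust range onto [0, 1]", {
  d <- c(4, 4, 4)
  arr <- array(0, d); arr[1:3] <- c(10, 15, 20)
  brain <- array(FALSE, d); brain[1:3] <- TRUE
  out <- rescale_unit(vol3d(arr), binary_mask(brain))
  expect_equal(as.numeric(out$data[1:3]), c(0, 0.5, 1), tolerance = 1e-9)
  # scale invariance: a global gain cancels
  g <- generate_pre(phantom_config(grid_shape = 32, seed = 4))
  atlas <- build_lobe_atlas(g$truth$regions)
  mb <- mask_brain(g$volume, atlas)
  r1 <- rescale_unit(mb$masked, mb$brain)
  v2 <- mb$masked; v2$data <- v2$data * 3.7
  r2 <- rescale_unit(v2, mb$brain)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
  expect_true(all(r1$data[mb$brain$data] >= 0 & r1$data[mb$brain$data] <= 1))
  # constant brain errors
  expect_error(rescale_unit(vol3d(array(1, d)), binary_mask(array(TRUE, d))),
               "degenerate")
})

test_that("prior-guided mixture finds the CSF-filled cavity", {
  cs <- suite48()$a
  atlas <- build_lobe_atlas(cs$truth$regions)
  mb <- mask_brain(cs$post, atlas)   # aligned case: post shares the pre grid
  full <- dilate_atlas_through_wm(atlas, mb$brain)
  spl <- split_resection_lobes(full, cs$spec)
  post_r <- rescale_unit(mb$masked, mb$brain)
  priors <- list(csf_prior = ventricle_mask(cs$truth$regions),
                 tissue_prior = spl$other, search_region = spl$resected)
  cav <- prior_mixture_segment(post_r, priors)
  cmp <- compare_masks(cs$truth$resection_mask, cav)
  expect_gte(cmp$dsc, 0.90)
})

test_that("a search region of pure tissue yields an empty cavity", {
  d <- c(12, 12, 12)
  arr <- array(0.8, d)
  arr[1:3, 1, 1] <- 0.05            # ventricle prior voxels (CSF-like)
  csf <- array(FALSE, d); csf[1:3, 1, 1] <- TRUE
  tis <- array(FALSE, d); tis[, 6:8, ] <- TRUE
  sr <- array(FALSE, d); sr[, 10:12, ] <- TRUE
  out <- prior_mixture_segment(vol3d(arr),
                               list(csf_prior = binary_mask(csf),
                                    tissue_prior = binary_mask(tis),
                                    search_region = binary_mask(sr)))
  expect_equal(sum(out$data), 0)
})

test_that("two-means CSF split matches the brute-force grouping", {
  d <- c(5, 4, 1)
  arr <- array(0, c(5, 4, 1))
  vals <- c(rep(0.05, 10), rep(0.5, 10))
  arr[1:20] <- vals
  cav <- array(FALSE, dim(arr)); cav[1:20] <- TRUE
  out <- kmeans2_csf(vol3d(arr), binary_mask(cav))
  expect_identical(which(out$data), which(arr == 0.05 & cav))
  expect_true(all(out$data[!cav] == FALSE))
  # single distinct intensity: whole cavity returned with a warning
  arr2 <- array(0.3, dim(arr))
  expect_warning(out2 <- kmeans2_csf(vol3d(arr2), binary_mask(cav)),
                 "single distinct intensity")
  expect_identical(out2$data, cav)
})

test_that("image subtraction is masked and signed as expected", {
  d <- c(6, 6, 6)
  pre <- array(1, d); post <- array(1, d)
  post[3, 3, 3] <- 0                # post-op CSF under pre-op tissue
  brain <- array(TRUE, d); brain[1, , ] <- FALSE
  pre[1, 2, 2] <- 9                 # outside brain; must be zeroed
  dif <- subtract_images(vol3d(pre), vol3d(post), binary_mask(brain))
  expect_equal(dif$data[3, 3, 3], 1)
  expect_true(all(dif$data[1, , ] == 0))
  expect_equal(sum(dif$data != 0), 1)
  expect_error(subtract_images(vol3d(pre), vol3d(array(1, c(5, 6, 6))),
                               binary_mask(brain)), "grid")
})

test_that("cavity expansion keeps only the largest difference component", {
  d <- c(24, 16, 16)
  dif <- array(0, d)
  dif[2:11, 2:11, 2:11] <- 0.8       # 1000-voxel blob
  dif[20:22, 4:7, 4:7] <- 0.8        # 48-voxel blob, disconnected
  lobe <- array(TRUE, d)
  seed <- array(FALSE, d); seed[4:6, 4:6, 4:6] <- TRUE
  out <- expand_cavity(vol3d(dif), binary_mask(seed), binary_mask(lobe))
  lab <- brute_components(dif > 0, 26)
  big <- lab == min(lab[lab > 0])
  expect_identical(out$data, big)
  expect_true(all(out$data | !seed))
  expect_error(expand_cavity(vol3d(dif), binary_mask(array(FALSE, d)),
                             binary_mask(lobe)), "no cavity found")
})

test_that("spur removal preserves solid shapes and cuts narrow bridges", {
  d <- c(30, 14, 14)
  cube <- array(FALSE, d); cube[3:12, 3:12, 3:12] <- TRUE
  out <- remove_misalignment_spurs(binary_mask(cube))
  expect_identical(out$data, cube)
  # 8^3 and 6^3 blobs joined by a 1-voxel-wide, 6-voxel-long bridge
  m <- array(FALSE, d)
  m[3:10, 4:11, 4:11] <- TRUE                  # large blob
  m[11:16, 7, 7] <- TRUE                       # bridge
  m[17:22, 5:10, 5:10] <- TRUE                 # smaller blob
  big <- array(FALSE, d); big[3:10, 4:11, 4:11] <- TRUE
  out2 <- remove_misalignment_spurs(binary_mask(m))
  expect_identical(out2$data, big)
  expect_true(all(out2$data <= m))             # always a subset of the input
  # erosion emptying a tiny mask returns it with a warning
  tiny <- array(FALSE, d); tiny[5, 5, 5] <- TRUE
  expect_warning(out3 <- remove_misalignment_spurs(binary_mask(tiny)),
                 "erosion")
  expect_identical(out3$data, tiny)
})

test_that("boundary dilation traces discrete segments toward nearby CSF", {
  d <- c(12, 12, 12)
  m <- array(FALSE, d); m[5, 5, 5] <- TRUE
  csf <- array(FALSE, d); csf[8, 5, 5] <- TRUE
  out <- directional_boundary_dilation(binary_mask(m), binary_mask(csf),
                                       max_passes = 1L)
  added <- out$data & !m
  expect_identical(which(added), which(arr_shift(m, -1, 0, 0) | arr_shift(m, -2, 0, 0)))
  # CSF two voxels away along an axis: exactly the one between voxel is added
  csf2 <- array(FALSE, d); csf2[7, 5, 5] <- TRUE
  out2 <- directional_boundary_dilation(binary_mask(m), binary_mask(csf2),
                                        max_passes = 1L)
  expect_identical(which(out2$data & !m), which(arr_shift(m, -1, 0, 0)))
  # no CSF within reach: unchanged
  csf3 <- array(FALSE, d); csf3[10, 5, 5] <- TRUE
  out3 <- directional_boundary_dilation(binary_mask(m), binary_mask(csf3))
  expect_identical(out3$data, m)
  # added voxels stay within the search radius of the original boundary
  g <- random_blob_mask(d)
  csf4 <- array(FALSE, d); csf4[, 11:12, ] <- TRUE
  out4 <- directional_boundary_dilation(binary_mask(g), binary_mask(csf4))
  reach <- g
  for (k in 1:3) {
    r2 <- reach
    for (s in neighbour_shifts(26)) r2 <- r2 | arr_shift(reach, s[1], s[2], s[3])
    reach <- r2
  }
  expect_true(all(!(out4$data & !g) | reach))
})

test_that("finalisation fills holes, filters by lobe, keeps one component", {
  d <- c(14, 14, 14)
  shell <- array(FALSE, d)
  shell[3:11, 3:11, 3:11] <- TRUE
  shell[4:10, 4:10, 4:10] <- FALSE             # hollow 9^3 shell
  lobe <- array(TRUE, d)
  out <- finalize_mask(binary_mask(shell), binary_mask(lobe))
  solid <- array(FALSE, d); solid[3:11, 3:11, 3:11] <- TRUE
  expect_identical(out$data, solid)
  # oracle: border flood fill marks the same internal holes
  expect_identical(shell | flood_holes(shell), solid)
  # voxels outside the lobe are removed; fully disjoint lobe errors
  lobe2 <- array(FALSE, d); lobe2[3:11, 3:11, 3:7] <- TRUE
  out2 <- finalize_mask(binary_mask(shell), binary_mask(lobe2))
  expect_true(all(out2$data <= lobe2))
  lobe3 <- array(FALSE, d); lobe3[13:14, 13:14, 13:14] <- TRUE
  expect_error(finalize_mask(binary_mask(shell), binary_mask(lobe3)),
               "outside specified lobe")
  # same-grid resampling is the identity
  out3 <- finalize_mask(binary_mask(shell), binary_mask(lobe),
                        original_grid = vol3d(array(0, d)))
  expect_identical(out3$data, solid)
})
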