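# Synthetic 3D brain phantoms with known ground-truth resections.
#
# The phantom is a layered ellipsoidal "brain": a white-matter core, a
# grey-matter shell, an outer CSF rim, two CSF ventricles, a subcortical grey
# nucleus and a small insular wedge per hemisphere. Lobes are assigned by
# angular sector around the volume centre (anterior/posterior x
# superior/inferior quadrants), split into hemispheres at the mid-sagittal
# plane. Surgery carves an ellipsoidal cavity (filled with CSF-like
# intensity), optionally followed by tissue sagging toward the cavity, a
# smooth multiplicative bias field, additive Gaussian noise, and a rigid
# pre/post misalignment.

# Atlas lobe codes (left hemisphere 1..8; right = +10; Excluded is unsided).
LOBE_CODE <- c(Frontal = 1L, Parietal = 2L, Temporal = 3L, Occipital = 4L,
               Insula = 5L, SubCortical = 6L, Excluded = 7L, WM = 8L)
HEMI_OFFSET <- c(L = 0L, R = 10L)

lobe_atlas_legend <- function() {
  codes <- c()
  for (h in c("L", "R")) {
    for (nm in c("Frontal", "Parietal", "Temporal", "Occipital", "Insula",
                 "SubCortical", "WM")) {
      codes[paste0(nm, "-", h)] <- LOBE_CODE[[nm]] + HEMI_OFFSET[[h]]
    }
  }
  codes["Excluded"] <- LOBE_CODE[["Excluded"]]
  codes
}

#' Region-code to lobe mapping for the phantom segmenter
#'
#' The phantom emits integer region codes in the style of a whole-brain
#' segmenter (per-hemisphere cortical parcels, cerebral white matter,
#' ventricles, extracerebral CSF). This table maps each code to its lobe
#' category: one of Frontal, Parietal, Temporal, Occipital, Insula,
#' SubCortical, `WM` (unassigned white matter, filled by atlas dilation) or
#' `Excluded` (regions where a resection cannot occur). The same table ships
#' as `inst/extdata/phantom_lobe_map.tsv` and custom tables with identical
#' columns may be supplied to [build_lobe_atlas()].
#'
#' @return A data.frame with columns `code`, `region`, `lobe`, `hemisphere`.
#' @export
phantom_lobe_map <- function() {
  data.frame(
    code = c(2L, 41L, 4L, 43L, 24L,
             1001L, 1002L, 1003L, 1004L, 1005L, 1010L,
             2001L, 2002L, 2003L, 2004L, 2005L, 2010L),
    region = c("left-cerebral-white-matter", "right-cerebral-white-matter",
               "left-lateral-ventricle", "right-lateral-ventricle", "csf",
               "left-frontal-cortex", "left-parietal-cortex",
               "left-temporal-cortex", "left-occipital-cortex",
               "left-insula-cortex", "left-subcortical-grey",
               "right-frontal-cortex", "right-parietal-cortex",
               "right-temporal-cortex", "right-occipital-cortex",
               "right-insula-cortex", "right-subcortical-grey"),
    lobe = c("WM", "WM", "Excluded", "Excluded", "Excluded",
             "Frontal", "Parietal", "Temporal", "Occipital", "Insula",
             "SubCortical",
             "Frontal", "Parietal", "Temporal", "Occipital", "Insula",
             "SubCortical"),
    hemisphere = c("L", "R", "L", "R", "",
                   "L", "L", "L", "L", "L", "L",
                   "R", "R", "R", "R", "R", "R"),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Defines the acquisition and surgery conditions emulated by the phantom.
#' Geometric defaults scale with the grid so the same anatomy is produced at
#' any resolution.
#'
#' @param grid_shape Voxel counts per axis (default 96^3; use 160^3 for demos).
#' @param voxel_spacing mm per axis (default 1 mm isotropic).
#' @param tissue_means Intensities for background, CSF, grey matter, white
#'   matter; must be strictly increasing.
#' @param noise_sigma Additive Gaussian noise SD as a fraction of the WM mean.
#' @param bias_amplitude Peak deviation of the multiplicative bias field from 1.
#' @param cavity_center Cavity centre in voxel coordinates (default: left
#'   anterior-inferior, i.e. temporal, placed so the cavity reaches the
#'   cortical surface).
#' @param cavity_radii Ellipsoidal cavity radii in voxels.
#' @param sagging_magnitude Peak inward tissue displacement at the cavity wall,
#'   in voxels (decay constant 3 voxels).
#' @param rigid_offset Named vector `tx, ty, tz` (mm) and `rx, ry, rz`
#'   (degrees) applied to the post-operative volume.
#' @param seed RNG seed for noise and bias coefficients.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 96),
                           voxel_spacing = c(1, 1, 1),
                           tissue_means = c(background = 0, csf = 80,
                                            gm = 160, wm = 240),
                           noise_sigma = 0.03,
                           bias_amplitude = 0.10,
                           cavity_center = NULL,
                           cavity_radii = NULL,
                           sagging_magnitude = 2.5,
                           rigid_offset = c(tx = 4, ty = -2.5, tz = 1.5,
                                            rx = 3, ry = -1.5, rz = 1),
                           seed = 1L) {
  d <- as.integer(grid_shape)
  if (length(d) == 1L) d <- rep(d, 3L)
  ctr <- (d + 1) / 2
  if (is.null(cavity_center)) cavity_center <- ctr + c(-1/6, 1/6, -1/8) * d
  if (is.null(cavity_radii)) cavity_radii <- c(0.115, 0.104, 0.094) * d
  if (length(tissue_means) != 4L || any(diff(tissue_means) <= 0))
    stop("tissue_means must be 4 strictly increasing values ",
         "(background < CSF < GM < WM)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (sagging_magnitude < 0) stop("sagging_magnitude must be >= 0")
  ro <- c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
  ro[names(rigid_offset)] <- rigid_offset
  cfg <- list(grid_shape = d, voxel_spacing = as.numeric(voxel_spacing),
              tissue_means = tissue_means, noise_sigma = noise_sigma,
              bias_amplitude = bias_amplitude,
              cavity_center = as.numeric(cavity_center),
              cavity_radii = as.numeric(cavity_radii),
              sagging_magnitude = sagging_magnitude,
              rigid_offset = ro, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# Fractional brain geometry shared by all phantom builders.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  ctr <- (d + 1) / 2
  list(
    center = ctr,
    brain_radii = c(0.375, 0.4375, 0.354) * d,
    vent_offset = c(0.094 * d[1], 0, 0),
    vent_radii = c(0.052, 0.094, 0.0625) * d,
    sub_offset = c(0.125 * d[1], 0, 0),
    sub_radii = c(0.083, 0.135, 0.094) * d
  )
}

# Squared-normalised ellipsoid coordinate: <= 1 inside.
ellipsoid_rho <- function(ix, iy, iz, center, radii) {
  sqrt(((ix - center[1]) / radii[1])^2 +
       ((iy - center[2]) / radii[2])^2 +
       ((iz - center[3]) / radii[3])^2)
}

index_arrays <- function(d) {
  list(x = array(seq_len(d[1]), d),
       y = array(rep(seq_len(d[2]), each = d[1]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# Smooth multiplicative field: product of per-axis degree-1 polynomials,
# scaled to peak deviation `amplitude`, then normalised to mean 1 over `brain`.
phantom_bias_field <- function(d, amplitude, brain) {
  if (amplitude <= 0) return(array(1, d))
  co <- runif(3, -1, 1)
  u <- 2 * (seq_len(d[1]) - 1) / (d[1] - 1) - 1
  v <- 2 * (seq_len(d[2]) - 1) / (d[2] - 1) - 1
  w <- 2 * (seq_len(d[3]) - 1) / (d[3] - 1) - 1
  q <- outer(outer(1 + co[1] * u, 1 + co[2] * v), 1 + co[3] * w)
  q <- q - mean(q)
  field <- 1 + amplitude * q / max(abs(q))
  field / mean(field[brain])
}

#' Generate the pre-operative phantom volume
#'
#' Builds the layered ellipsoidal brain with lobe-labelled parcels in two
#' hemispheres and returns the volume together with the partial ground truth
#' (tissue labels, lobe labels, segmenter-style region labels, bias field and
#' the clean noise-free anatomy used later by [apply_surgery()]).
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` (a [vol3d()]) and `truth` (a list;
#'   see Details).
#' @export
generate_pre <- function(config) {
  cfg <- config
  d <- cfg$grid_shape
  geo <- phantom_geometry(cfg)
  idx <- index_arrays(d)

  rho_brain <- ellipsoid_rho(idx$x, idx$y, idx$z, geo$center, geo$brain_radii)
  # structural classes: 0 bg, 1 csf rim, 2 ventricle, 3 cortical gm, 4 wm,
  # 5 subcortical grey, 6 insula
  struct <- array(0L, d)
  struct[rho_brain <= 1] <- 1L
  struct[rho_brain <= 0.92] <- 3L
  struct[rho_brain <= 0.75] <- 4L
  for (s in c(-1, 1)) {
    vc <- geo$center + s * geo$vent_offset
    sc <- geo$center + s * geo$sub_offset
    sub <- ellipsoid_rho(idx$x, idx$y, idx$z, sc, geo$sub_radii)
    struct[sub <= 1 & struct == 4L] <- 5L
    ins <- sub > 1 & sub <= 1.35 & struct == 4L &
      idx$y > geo$center[2] & idx$z < geo$center[3]
    struct[ins] <- 6L
    vent <- ellipsoid_rho(idx$x, idx$y, idx$z, vc, geo$vent_radii)
    struct[vent <= 1 & rho_brain <= 0.92] <- 2L
  }

  # cavity must lie inside the brain envelope
  rho_cav <- ellipsoid_rho(idx$x, idx$y, idx$z, cfg$cavity_center, cfg$cavity_radii)
  if (any(rho_cav <= 1 & rho_brain > 1))
    stop("configuration error: cavity extends outside the brain envelope")

  means <- cfg$tissue_means
  intens_of <- c(means[["background"]], means[["csf"]], means[["csf"]],
                 means[["gm"]], means[["wm"]], means[["gm"]], means[["gm"]])
  clean <- array(intens_of[struct + 1L], d)

  # tissue truth: 0 bg, 1 CSF, 2 ventricle, 3 GM, 4 WM
  tissue_of <- c(0L, 1L, 2L, 3L, 4L, 3L, 3L)
  tissue <- array(tissue_of[struct + 1L], d)

  left <- idx$x < geo$center[1]
  quad <- array(0L, d)  # angular lobes over cortex + wm
  ant <- idx$y >= geo$center[2]; sup <- idx$z >= geo$center[3]
  quad[ant & sup] <- LOBE_CODE[["Frontal"]]
  quad[!ant & sup] <- LOBE_CODE[["Parietal"]]
  quad[ant & !sup] <- LOBE_CODE[["Temporal"]]
  quad[!ant & !sup] <- LOBE_CODE[["Occipital"]]

  lobes <- array(0L, d)
  tissue_vox <- struct %in% c(3L, 4L)
  lobes[tissue_vox] <- quad[tissue_vox]
  lobes[struct == 5L] <- LOBE_CODE[["SubCortical"]]
  lobes[struct == 6L] <- LOBE_CODE[["Insula"]]
  lobes[lobes > 0L & !left] <- lobes[lobes > 0L & !left] + HEMI_OFFSET[["R"]]
  lobes[struct %in% c(1L, 2L)] <- LOBE_CODE[["Excluded"]]

  # segmenter-style region codes
  regions <- array(0L, d)
  cort_code <- c(0L, 1001L, 1002L, 1003L, 1004L)  # indexed by quad for left
  cg <- struct == 3L
  regions[cg & left] <- cort_code[quad[cg & left] + 1L]
  regions[cg & !left] <- cort_code[quad[cg & !left] + 1L] + 1000L
  regions[struct == 6L & left] <- 1005L
  regions[struct == 6L & !left] <- 2005L
  regions[struct == 5L & left] <- 1010L
  regions[struct == 5L & !left] <- 2010L
  regions[struct == 4L & left] <- 2L
  regions[struct == 4L & !left] <- 41L
  regions[struct == 2L & left] <- 4L
  regions[struct == 2L & !left] <- 43L
  regions[struct == 1L] <- 24L

  set.seed(cfg$seed)
  brain <- struct > 0L
  bias <- phantom_bias_field(d, cfg$bias_amplitude, brain)
  vol <- clean * bias
  if (cfg$noise_sigma > 0)
    vol <- vol + rnorm(length(vol), sd = cfg$noise_sigma * means[["wm"]])

  sp <- cfg$voxel_spacing
  map <- phantom_lobe_map()
  legend_regions <- structure(map$code, names = map$region)
  truth <- list(
    clean = vol3d(clean, sp),
    struct = struct,
    tissue_labels = label_volume(tissue, c(csf = 1L, ventricle = 2L,
                                           gm = 3L, wm = 4L), sp),
    lobe_labels = label_volume(lobes, lobe_atlas_legend(), sp),
    regions = label_volume(regions, legend_regions, sp),
    bias_field = vol3d(bias, sp),
    config = cfg
  )
  list(volume = vol3d(vol, sp), truth = truth)
}

#' Apply surgery, sagging, bias, noise and misalignment to a phantom
#'
#' Carves the ellipsoidal cavity out of the clean pre-operative anatomy
#' (intensities set to the CSF mean), applies a smooth inward sagging
#' displacement decaying with distance from the cavity wall, the rigid
#' pre/post misalignment, an independently drawn bias field, and additive
#' noise. The ground-truth resection mask is defined on the pre-operative grid
#' *before* sagging and misalignment.
#'
#' @param pre Output `volume` of [generate_pre()] (unused except for its grid;
#'   the carving starts from the stored clean anatomy so the post-operative
#'   scan carries its own independent noise and bias).
#' @param truth Output `truth` of [generate_pre()]; returned augmented.
#' @param config The same [phantom_config()].
#' @param carve If `FALSE`, skip the resection (misalignment-only phantom for
#'   registration benchmarks); the returned mask is empty.
#' @return A list: `volume` (post-operative [vol3d()]), `resection_mask`
#'   ([binary_mask()] in pre-operative space), `truth` (augmented with
#'   `resection_mask`, `rigid_transform`, `sagging_field`, `labels_post`,
#'   `tissue_labels_post`, `bias_field_post`).
#' @export
apply_surgery <- function(pre, truth, config, carve = TRUE) {
  cfg <- config
  d <- cfg$grid_shape
  sp <- cfg$voxel_spacing
  idx <- index_arrays(d)
  means <- cfg$tissue_means

  struct <- truth$struct
  carved <- truth$clean$data
  regions_post <- truth$regions$data
  tissue_post <- truth$tissue_labels$data
  rho_cav <- ellipsoid_rho(idx$x, idx$y, idx$z, cfg$cavity_center, cfg$cavity_radii)
  if (carve) {
    cav <- rho_cav <= 1 & array(struct %in% c(3L, 4L, 5L, 6L), d)
    if (!any(cav)) stop("configuration error: cavity carves no tissue")
    carved[cav] <- means[["csf"]]
    regions_post[cav] <- 24L      # post-op segmenter sees extracerebral CSF
    tissue_post[cav] <- 1L
  } else {
    cav <- array(FALSE, d)
  }
  resection_mask <- binary_mask(cav, sp)

  set.seed(cfg$seed + 1L)

  # sagging: backward warp sampling outward from the cavity centroid, so
  # tissue appears displaced inward; magnitude m * exp(-dist_to_wall / 3)
  post <- carved
  sag <- NULL
  if (cfg$sagging_magnitude > 0) {
    rbar <- mean(cfg$cavity_radii)
    dwall <- abs(rho_cav - 1) * rbar  # unsigned distance to the cavity wall
    mag <- cfg$sagging_magnitude * exp(-dwall / 3)
    dx <- idx$x - cfg$cavity_center[1]
    dy <- idx$y - cfg$cavity_center[2]
    dz <- idx$z - cfg$cavity_center[3]
    nrm <- pmax(sqrt(dx^2 + dy^2 + dz^2), 1e-6)
    sag <- list(ux = mag * dx / nrm, uy = mag * dy / nrm, uz = mag * dz / nrm)
    xi <- (idx$x - 1) + sag$ux; yi <- (idx$y - 1) + sag$uy; zi <- (idx$z - 1) + sag$uz
    post <- array(cpp_sample(as.numeric(post), d, xi, yi, zi, 1L, 0), d)
    regions_post <- array(as.integer(
      cpp_sample(as.numeric(regions_post), d, xi, yi, zi, 0L, 0)), d)
    tissue_post <- array(as.integer(
      cpp_sample(as.numeric(tissue_post), d, xi, yi, zi, 0L, 0)), d)
  }

  # rigid misalignment (world mm, about the grid centre)
  ro <- cfg$rigid_offset
  rigid <- rigid_transform(rot_deg = ro[c("rx", "ry", "rz")],
                           trans_mm = ro[c("tx", "ty", "tz")],
                           center = (d - 1) / 2 * sp)
  if (any(abs(ro) > 0)) {
    wx <- (idx$x - 1) * sp[1]; wy <- (idx$y - 1) * sp[2]; wz <- (idx$z - 1) * sp[3]
    mapped <- rigid_map_world(rigid, wx, wy, wz)
    xi <- mapped$x / sp[1]; yi <- mapped$y / sp[2]; zi <- mapped$z / sp[3]
    post <- array(cpp_sample(as.numeric(post), d, xi, yi, zi, 1L, 0), d)
    regions_post <- array(as.integer(
      cpp_sample(as.numeric(regions_post), d, xi, yi, zi, 0L, 0)), d)
    tissue_post <- array(as.integer(
      cpp_sample(as.numeric(tissue_post), d, xi, yi, zi, 0L, 0)), d)
  }

  bias_post <- phantom_bias_field(d, cfg$bias_amplitude, regions_post > 0L)
  post <- post * bias_post
  if (cfg$noise_sigma > 0)
    post <- post + rnorm(length(post), sd = cfg$noise_sigma * means[["wm"]])

  truth$resection_mask <- resection_mask
  truth$rigid_transform <- rigid
  truth$sagging_field <- sag
  truth$labels_post <- label_volume(regions_post, truth$regions$legend, sp)
  truth$tissue_labels_post <- label_volume(
    tissue_post, c(csf = 1L, ventricle = 2L, gm = 3L, wm = 4L), sp)
  truth$bias_field_post <- vol3d(bias_post, sp)
  list(volume = vol3d(post, sp), resection_mask = resection_mask, truth = truth)
}

#' Graded phantom fixture battery
#'
#' Emits six pre/post cases of increasing difficulty: (a) aligned and
#' noiseless, (b) noise + bias, (c) sagging only, (d) rigid misalignment only,
#' (e) sagging + misalignment + bias + noise, (f) a small lesionectomy-sized
#' cavity (with noise + bias). Sagging magnitude and the default cavity scale
#' with the grid so the anatomy is resolution-independent.
#'
#' @param seed Base RNG seed; each case derives its own.
#' @param grid_shape Voxel counts per axis (default 96^3).
#' @return Named list of cases, each `list(name, config, spec, pre, post,
#'   truth)` with `spec` the matching left-temporal [resection_spec()].
#' @export
make_fixture_suite <- function(seed = 1L, grid_shape = c(96, 96, 96)) {
  d <- if (length(grid_shape) == 1L) rep(grid_shape, 3L) else grid_shape
  scale <- d[1] / 96
  off <- c(tx = 4, ty = -2.5, tz = 1.5, rx = 3, ry = -1.5, rz = 1)
  zero <- c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0)
  sag <- 2.5 * scale
  conds <- list(
    a = list(noise = 0, bias = 0, sag = 0, rigid = zero, small = FALSE),
    b = list(noise = 0.03, bias = 0.10, sag = 0, rigid = zero, small = FALSE),
    c = list(noise = 0, bias = 0, sag = sag, rigid = zero, small = FALSE),
    d = list(noise = 0, bias = 0, sag = 0, rigid = off, small = FALSE),
    e = list(noise = 0.03, bias = 0.10, sag = sag, rigid = off, small = FALSE),
    f = list(noise = 0.03, bias = 0.10, sag = 0, rigid = zero, small = TRUE)
  )
  out <- list()
  for (i in seq_along(conds)) {
    cn <- conds[[i]]
    radii <- c(0.115, 0.104, 0.094) * d
    if (cn$small) radii <- radii * 0.36
    cfg <- phantom_config(grid_shape = d, noise_sigma = cn$noise,
                          bias_amplitude = cn$bias, sagging_magnitude = cn$sag,
                          rigid_offset = cn$rigid, cavity_radii = radii,
                          seed = seed + 37L * i)
    g <- generate_pre(cfg)
    s <- apply_surgery(g$volume, g$truth, cfg)
    out[[names(conds)[i]]] <- list(name = names(conds)[i], config = cfg,
                                   spec = resection_spec("L", "T"),
                                   pre = g$volume, post = s$volume,
                                   truth = s$truth)
  }
  out
}

#' Misalignment-only phantom pair for registration benchmarks
#'
#' No surgery is applied: the post volume is the same anatomy under a rigid
#' offset (plus optional noise and bias).
#'
#' @param seed RNG seed.
#' @param trans_mm,rot_deg Rigid offset applied to the post volume.
#' @param grid_shape Voxel counts per axis.
#' @param noise_sigma,bias_amplitude Acquisition confounds (defaults mild).
#' @return `list(pre, post, truth)`; `truth$rigid_transform` holds the applied
#'   transform.
#' @export
make_misalignment_pair <- function(seed = 1L, trans_mm = c(4, -2.5, 1.5),
                                   rot_deg = c(3, -1.5, 1),
                                   grid_shape = c(96, 96, 96),
                                   noise_sigma = 0.02, bias_amplitude = 0.05) {
  cfg <- phantom_config(grid_shape = grid_shape, noise_sigma = noise_sigma,
                        bias_amplitude = bias_amplitude, sagging_magnitude = 0,
                        rigid_offset = c(tx = trans_mm[1], ty = trans_mm[2],
                                         tz = trans_mm[3], rx = rot_deg[1],
                                         ry = rot_deg[2], rz = rot_deg[3]),
                        seed = seed)
  g <- generate_pre(cfg)
  s <- apply_surgery(g$volume, g$truth, cfg, carve = FALSE)
  list(pre = g$volume, post = s$volume, truth = s$truth)
}
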