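# Part A: grid standardisation, bias correction, intensity clamping,
# lobe-atlas assembly and hemisphere/lobe filter masks.

#' Resample a volume to a standard isotropic grid
#'
#' Resamples onto a `target_spacing` isotropic grid of `target_fov` mm per
#' axis, centred on the input field of view, keeping the image in its original
#' world space. Intensities are interpolated linearly, labels and masks with
#' nearest-neighbour (masks via linear + 0.5 threshold).
#'
#' @param vol A [vol3d()], [label_volume()] or [binary_mask()].
#' @param target_spacing Target voxel size in mm (scalar, isotropic).
#' @param target_fov Target field of view in mm per axis (default 256).
#' @return The resampled volume, same class as the input. If the input already
#'   lies on the target grid it is returned unchanged.
#' @export
normalize_resolution <- function(vol, target_spacing = 1, target_fov = 256) {
  d_in <- dim(vol$data)
  n_out <- rep(as.integer(round(target_fov / target_spacing)), 3L)
  if (all(abs(vol$spacing - target_spacing) < 1e-9) && all(d_in == n_out))
    return(vol)
  fov_in <- d_in * vol$spacing
  if (any(fov_in > target_fov + 1e-6))
    warning("input field of view exceeds ", target_fov,
            " mm; the image is centre-cropped")
  center <- grid_center(vol)
  origin_out <- center - (n_out - 1) / 2 * target_spacing
  base <- index_arrays(n_out)
  wx <- origin_out[1] + (base$x - 1) * target_spacing
  wy <- origin_out[2] + (base$y - 1) * target_spacing
  wz <- origin_out[3] + (base$z - 1) * target_spacing
  interp <- if (inherits(vol, "labelvol")) 0L else 1L
  vals <- cpp_sample(as.numeric(vol$data), d_in,
                     (wx - vol$origin[1]) / vol$spacing[1],
                     (wy - vol$origin[2]) / vol$spacing[2],
                     (wz - vol$origin[3]) / vol$spacing[3], interp, 0)
  arr <- array(vals, n_out)
  sp <- rep(target_spacing, 3L)
  if (inherits(vol, "mask3d")) {
    binary_mask(arr >= 0.5, sp, origin_out)
  } else if (inherits(vol, "labelvol")) {
    label_volume(array(as.integer(arr), n_out), vol$legend, sp, origin_out)
  } else {
    vol3d(arr, sp, origin_out)
  }
}

# Degree-3 polynomial design matrix on normalised coordinates of `idx` voxels.
poly3_terms <- function() {
  terms <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  terms[terms$i + terms$j + terms$k <= 3, ]
}

poly3_design <- function(d, idx) {
  terms <- poly3_terms()
  ai <- arrayInd(idx, d)
  u <- 2 * (ai[, 1] - 1) / max(d[1] - 1, 1) - 1
  v <- 2 * (ai[, 2] - 1) / max(d[2] - 1, 1) - 1
  w <- 2 * (ai[, 3] - 1) / max(d[3] - 1, 1) - 1
  X <- matrix(0, length(idx), nrow(terms))
  for (t in seq_len(nrow(terms)))
    X[, t] <- u^terms$i[t] * v^terms$j[t] * w^terms$k[t]
  X
}

# Evaluate the fitted polynomial over the full grid without a dense basis.
poly3_eval_grid <- function(coef, d) {
  terms <- poly3_terms()
  u <- 2 * (seq_len(d[1]) - 1) / max(d[1] - 1, 1) - 1
  v <- 2 * (seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 1
  w <- 2 * (seq_len(d[3]) - 1) / max(d[3] - 1, 1) - 1
  out <- array(0, d)
  for (t in seq_len(nrow(terms))) {
    if (coef[t] == 0) next
    term <- outer(outer(u^terms$i[t], v^terms$j[t]), w^terms$k[t])
    out <- out + coef[t] * term
  }
  out
}

# Deterministic 1D k-means on a numeric vector (quantile-seeded Lloyd).
kmeans1d <- function(x, k, iter = 25L) {
  centers <- quantile(x, probs = seq(0.1, 0.9, length.out = k), names = FALSE)
  for (i in seq_len(iter)) {
    assign <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
    new_centers <- vapply(seq_len(k), function(j) {
      if (any(assign == j)) mean(x[assign == j]) else centers[j]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
    centers <- new_centers
  }
  list(centers = centers, assign = assign)
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Fits a low-order (degree-3) polynomial to the log-intensities within the
#' brain, iterating against a piecewise-constant three-class tissue estimate
#' (CSF / grey / white, deterministic quantile-seeded k-means): at each round
#' the field is the polynomial fit to the residual of the log-intensity about
#' its class mean. The estimated field has mean 1 over the brain, and the
#' corrected volume is exactly `vol / field`.
#'
#' @param vol A [vol3d()] (typically brain-masked).
#' @param brain Nonempty [binary_mask()] on the same grid.
#' @param rounds Field/classification alternations (default 5).
#' @param max_fit_voxels Deterministic stride subsample cap for the fit.
#' @return `list(corrected = vol3d, field = vol3d)`.
#' @export
correct_bias <- function(vol, brain, rounds = 5L, max_fit_voxels = 100000L) {
  stopifnot_same_grid(vol, brain, "volume and brain mask")
  if (!any(brain$data)) stop("brain mask is empty")
  if (all(vol$data == 0)) stop("volume is identically zero")
  d <- dim(vol$data)
  idx_all <- which(brain$data & vol$data > 0)
  if (!length(idx_all)) stop("no positive intensities inside the brain mask")
  idx <- idx_all
  if (length(idx) > max_fit_voxels)
    idx <- idx[seq(1, length(idx), by = ceiling(length(idx) / max_fit_voxels))]
  X <- poly3_design(d, idx)
  logi <- log(vol$data[idx])
  logfield_fit <- rep(0, length(idx))
  coef <- rep(0, ncol(X))
  for (r in seq_len(rounds)) {
    corrected <- logi - logfield_fit
    km <- kmeans1d(corrected, 3L)
    resid <- logi - km$centers[km$assign]
    fit <- lm.fit(X, resid)
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0
    logfield_fit <- as.numeric(X %*% coef)
  }
  logfield <- poly3_eval_grid(coef, d)
  field <- exp(logfield)
  field <- field / mean(field[brain$data])
  corrected_vol <- like_volume(vol, vol$data / field)
  list(corrected = corrected_vol, field = vol3d(field, vol$spacing, vol$origin))
}

#' Clamp the brightest brain voxels to the median
#'
#' Voxels inside the brain at or above the `100 - pct` percentile of brain
#' intensities are replaced by the brain median; all other voxels are
#' unchanged. Applied at the end of data preparation to suppress residual
#' high-intensity outliers (vessels, remaining bias).
#'
#' @param vol A [vol3d()].
#' @param brain Nonempty [binary_mask()] on the same grid.
#' @param pct Top percentile to clamp (default 1).
#' @return The clamped [vol3d()].
#' @export
clamp_top_percentile <- function(vol, brain, pct = 1) {
  stopifnot_same_grid(vol, brain, "volume and brain mask")
  if (!any(brain$data)) stop("brain mask is empty")
  bvals <- vol$data[brain$data]
  thr <- quantile(bvals, 1 - pct / 100, names = FALSE, type = 7)
  med <- median(bvals)
  out <- vol$data
  out[brain$data & vol$data >= thr] <- med
  like_volume(vol, out)
}

#' Assemble a grey-matter lobe atlas from a region segmentation
#'
#' Merges segmenter region codes into lobe categories per hemisphere:
#' Frontal, Parietal, Temporal, Occipital, Insula, SubCortical, plus
#' `Excluded` for regions in which a resection cannot occur (ventricles,
#' extracerebral CSF, brainstem, cerebellum) and `WM` for unassigned cerebral
#' white matter, which [dilate_atlas_through_wm()] later fills.
#'
#' @param regions A [label_volume()] of segmenter codes.
#' @param mapping A data.frame with columns `code`, `lobe`, `hemisphere`
#'   (see [phantom_lobe_map()] for the format and lobe vocabulary).
#' @return A [label_volume()] lobe atlas (codes 1..8 left, 11..18 right,
#'   7 = Excluded).
#' @export
build_lobe_atlas <- function(regions, mapping = phantom_lobe_map()) {
  codes_present <- sort(unique(regions$data[regions$data > 0L]))
  unmapped <- setdiff(codes_present, mapping$code)
  if (length(unmapped))
    stop("region codes missing from the lobe mapping: ",
         paste(unmapped, collapse = ", "))
  bad <- setdiff(mapping$lobe, names(LOBE_CODE))
  if (length(bad)) stop("unknown lobe categories in mapping: ",
                        paste(unique(bad), collapse = ", "))
  lut <- integer(max(codes_present) + 1L)
  for (i in seq_len(nrow(mapping))) {
    code <- mapping$code[i]
    if (!(code %in% codes_present)) next
    lc <- LOBE_CODE[[mapping$lobe[i]]]
    if (mapping$lobe[i] != "Excluded" && identical(mapping$hemisphere[i], "R"))
      lc <- lc + HEMI_OFFSET[["R"]]
    lut[code + 1L] <- lc
  }
  atlas <- array(lut[regions$data + 1L], dim(regions$data))
  out <- label_volume(atlas, lobe_atlas_legend(), regions$spacing, regions$origin)
  class(out) <- c("lobe_atlas", class(out))
  out
}

#' Ventricle mask from a region segmentation
#'
#' @inheritParams build_lobe_atlas
#' @return A [binary_mask()] of voxels whose region name contains "ventricle".
#' @export
ventricle_mask <- function(regions, mapping = phantom_lobe_map()) {
  vcodes <- mapping$code[grepl("ventricle", mapping$region, ignore.case = TRUE)]
  binary_mask(array(regions$data %in% vcodes, dim(regions$data)),
              regions$spacing, regions$origin)
}

#' Mask a volume to the binarized atlas
#'
#' Sets intensities outside the atlas to zero; the binarized atlas is the
#' brain mask (it includes Excluded regions such as ventricles, which belong
#' to the brain even though a resection cannot occur there).
#'
#' @param vol A [vol3d()].
#' @param atlas A lobe atlas from [build_lobe_atlas()] (or any
#'   [label_volume()]).
#' @return `list(masked = vol3d, brain = binary_mask)`.
#' @export
mask_brain <- function(vol, atlas) {
  stopifnot_same_grid(vol, atlas, "volume and atlas")
  if (!any(atlas$data > 0L)) stop("atlas is empty")
  brain <- binary_mask(atlas$data > 0L, vol$spacing, vol$origin)
  masked <- like_volume(vol, vol$data * brain$data)
  list(masked = masked, brain = brain)
}

#' Dilate the grey-matter lobe atlas through the white matter
#'
#' Every brain voxel not labelled by a grey-matter lobe (i.e. carrying the
#' `WM` placeholder code or no code) receives the lobe of its nearest labelled
#' voxel, by iterative 6-connected nearest-label propagation restricted to the
#' brain and to the voxel's own hemisphere half-space (propagation does not
#' cross the mid-sagittal plane). `Excluded` regions keep their code and do
#' not absorb neighbours. Ties within a propagation round are broken by the
#' lowest lobe code, processed in increasing linear voxel index, so the result
#' is deterministic.
#'
#' @param atlas Lobe atlas from [build_lobe_atlas()].
#' @param brain [binary_mask()] of the brain on the same grid.
#' @return The full lobe atlas (no brain voxel left unassigned).
#' @export
dilate_atlas_through_wm <- function(atlas, brain) {
  stopifnot_same_grid(atlas, brain, "atlas and brain mask")
  gm_codes <- c(1:6, 11:16)
  if (!any(atlas$data %in% gm_codes)) stop("atlas has no grey-matter lobe labels")
  d <- dim(atlas$data)
  midx <- (d[1] + 1) / 2
  hemi <- array(as.integer(array(seq_len(d[1]), d) >= midx), d)
  fill_codes <- c(LOBE_CODE[["WM"]], LOBE_CODE[["WM"]] + HEMI_OFFSET[["R"]])
  frozen <- LOBE_CODE[["Excluded"]]
  filled <- cpp_label_fill(array(as.integer(atlas$data), d),
                           array(as.integer(brain$data), d),
                           hemi, d, as.integer(fill_codes), as.integer(frozen))
  left_unfilled <- brain$data & array(filled == 0L | filled %in% fill_codes, d)
  if (any(left_unfilled)) {
    filled[left_unfilled] <- LOBE_CODE[["Excluded"]]
    warning(sum(left_unfilled), " brain voxels unreachable by lobe propagation",
            "; marked Excluded")
  }
  out <- label_volume(array(filled, d), lobe_atlas_legend(),
                      atlas$spacing, atlas$origin)
  class(out) <- c("lobe_atlas", class(out))
  out
}

#' Split the full lobe atlas by the user's resection specification
#'
#' @param full_atlas Output of [dilate_atlas_through_wm()].
#' @param spec A [resection_spec()].
#' @return `list(resected = binary_mask, other = binary_mask)`: the selected
#'   hemisphere-specific lobes, and all other non-Excluded labelled voxels.
#'   The two are disjoint and together cover the non-Excluded brain.
#' @export
split_resection_lobes <- function(full_atlas, spec) {
  sel_codes <- resection_spec_codes(spec)
  tissue_codes <- c(1:6, 11:16)
  d <- dim(full_atlas$data)
  resected <- array(full_atlas$data %in% sel_codes, d)
  other <- array(full_atlas$data %in% setdiff(tissue_codes, sel_codes), d)
  if (!any(resected))
    stop("resection specification selects an empty region")
  list(resected = binary_mask(resected, full_atlas$spacing, full_atlas$origin),
       other = binary_mask(other, full_atlas$spacing, full_atlas$origin))
}
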