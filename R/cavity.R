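# Part C: cavity classification in registered post-operative space and
# expansion to the pre-operative tissue boundary (steps 7-14).

#' Robust unit rescale of a volume within the brain
#'
#' Maps the 1st percentile of brain intensities to 0 and the 99th to 1,
#' clipping outside, so CSF / grey / white matter take comparable values
#' across images; background stays 0.
#'
#' @param vol A [vol3d()].
#' @param brain Nonempty [binary_mask()] on the same grid.
#' @return The rescaled [vol3d()] (intensities in `[0, 1]` within brain).
#' @export
rescale_unit <- function(vol, brain) {
  stopifnot_same_grid(vol, brain, "volume and brain mask")
  if (!any(brain$data)) stop("brain mask is empty")
  arr <- robust_unit(vol$data, brain$data)
  arr[!brain$data] <- 0
  like_volume(vol, arr)
}

# Two-class Gaussian-mixture EM with optional fixed-membership prior voxels.
# x: intensities; fixed: integer vector (0 free, 1 class-1, 2 class-2).
# Returns posterior probability of class 1 per element.
em2_gauss <- function(x, fixed, init1, init2, max_iter = 100L, tol = 1e-5,
                      sd1_floor_ratio = 0) {
  mu <- c(mean(init1), mean(init2))
  sd2 <- c(stats::sd(init1), stats::sd(init2))
  sd2[!is.finite(sd2) | sd2 < 1e-3] <- 1e-3
  if (sd1_floor_ratio > 0) sd2[1] <- max(sd2[1], sd1_floor_ratio * sd2[2])
  pooled <- sqrt(mean(sd2^2))
  if (abs(mu[1] - mu[2]) < 0.5 * pooled)
    warning("prior intensity distributions overlap strongly; ",
            "classes may not be separable")
  pi1 <- 0.5
  r1 <- numeric(length(x))
  r1[fixed == 1L] <- 1
  r1[fixed == 2L] <- 0
  free <- fixed == 0L
  # initial E-step for free voxels from the prior-derived Gaussians
  for (it in seq_len(max_iter)) {
    d1 <- stats::dnorm(x[free], mu[1], sd2[1]) * pi1
    d2 <- stats::dnorm(x[free], mu[2], sd2[2]) * (1 - pi1)
    tot <- d1 + d2
    r1f <- ifelse(tot > 0, d1 / tot,
                  as.numeric(abs(x[free] - mu[1]) <= abs(x[free] - mu[2])))
    r1[free] <- r1f
    w1 <- sum(r1); w2 <- sum(1 - r1)
    mu_new <- c(sum(r1 * x) / max(w1, 1e-12),
                sum((1 - r1) * x) / max(w2, 1e-12))
    v1 <- sum(r1 * (x - mu_new[1])^2) / max(w1, 1e-12)
    v2 <- sum((1 - r1) * (x - mu_new[2])^2) / max(w2, 1e-12)
    sd_new <- sqrt(pmax(c(v1, v2), 1e-6))
    if (sd1_floor_ratio > 0)
      sd_new[1] <- max(sd_new[1], sd1_floor_ratio * sd_new[2])
    pi_new <- w1 / length(x)
    delta <- max(abs(c(mu_new - mu, sd_new - sd2, pi_new - pi1)))
    mu <- mu_new; sd2 <- sd_new; pi1 <- pi_new
    if (delta < tol) break
  }
  r1
}

#' Prior-guided finite-mixture segmentation of the resection cavity
#'
#' Two-class Gaussian-mixture EM over the voxels of the search region and the
#' two prior masks. Class 1 (cavity/CSF) is initialised from intensities under
#' the ventricle prior, class 2 (tissue) from the non-resected-lobe tissue
#' prior; prior voxels keep fixed memberships throughout EM. Returns the
#' search-region voxels assigned to the cavity class.
#'
#' @param vol A rescaled volume from [rescale_unit()].
#' @param priors `list(csf_prior, tissue_prior, search_region)` of disjoint
#'   (priors vs search) nonempty [binary_mask()]s.
#' @return A [binary_mask()]: the post-operative resection cavity estimate
#'   within the search region.
#' @export
prior_mixture_segment <- function(vol, priors) {
  csf <- priors$csf_prior; tis <- priors$tissue_prior; sr <- priors$search_region
  for (m in list(csf, tis, sr)) stopifnot_same_grid(vol, m, "volume and priors")
  if (!any(csf$data) || !any(tis$data)) stop("prior masks must be nonempty")
  if (!any(sr$data)) stop("search region is empty")
  if (any(sr$data & tis$data))
    stop("search region and tissue prior must be disjoint")
  sel <- sr$data | csf$data | tis$data
  idx <- which(sel)
  x <- vol$data[idx]
  fixed <- integer(length(idx))
  fixed[csf$data[idx]] <- 1L
  fixed[tis$data[idx]] <- 2L
  r1 <- em2_gauss(x, fixed, vol$data[csf$data], vol$data[tis$data])
  out <- array(FALSE, dim(vol$data))
  out[idx] <- r1 > 0.5 & sr$data[idx]
  binary_mask(out, vol$spacing, vol$origin)
}

#' Two-means CSF split within the cavity
#'
#' Deterministic two-cluster k-means (Lloyd, centres initialised at the 25th
#' and 75th percentile intensities) on the voxels of the step-8 cavity; the
#' cluster with the lower median intensity is returned as CSF, separating
#' fluid from damaged tissue at the cavity rim. Ties go to the lower-mean
#' cluster, then to the cluster containing the minimum intensity.
#'
#' @param vol A rescaled volume.
#' @param cavity [binary_mask()] with at least 2 voxels.
#' @return A [binary_mask()] subset of `cavity`.
#' @export
kmeans2_csf <- function(vol, cavity) {
  stopifnot_same_grid(vol, cavity, "volume and cavity")
  idx <- which(cavity$data)
  if (length(idx) < 2L) stop("cavity must contain at least 2 voxels")
  x <- vol$data[idx]
  if (diff(range(x)) < 1e-12) {
    warning("cavity has a single distinct intensity; returning it all as CSF")
    return(cavity)
  }
  centers <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  if (diff(centers) < 1e-12) centers <- range(x)
  for (i in 1:100) {
    assign <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    nc <- c(if (any(assign == 1L)) mean(x[assign == 1L]) else centers[1],
            if (any(assign == 2L)) mean(x[assign == 2L]) else centers[2])
    if (max(abs(nc - centers)) < 1e-12) { centers <- nc; break }
    centers <- nc
  }
  med <- c(median(x[assign == 1L]), median(x[assign == 2L]))
  med[!is.finite(med)] <- Inf
  if (med[1] != med[2]) {
    keep <- which.min(med)
  } else {
    mn <- c(mean(x[assign == 1L]), mean(x[assign == 2L]))
    keep <- if (mn[1] != mn[2]) which.min(mn) else assign[which.min(x)]
  }
  out <- array(FALSE, dim(vol$data))
  out[idx[assign == keep]] <- TRUE
  binary_mask(out, vol$spacing, vol$origin)
}

#' Pre-minus-post difference image
#'
#' Subtracts the registered post-operative rescaled image from the
#' pre-operative rescaled image and masks by the pre-operative brain; positive
#' values mark pre-operative tissue overlying post-operative CSF (resected or
#' sagged tissue).
#'
#' @param pre,post_aligned Rescaled volumes on the same (pre-operative) grid.
#' @param pre_brain [binary_mask()] of the pre-operative brain.
#' @return The difference [vol3d()].
#' @export
subtract_images <- function(pre, post_aligned, pre_brain) {
  stopifnot_same_grid(pre, post_aligned, "pre and registered post volumes")
  stopifnot_same_grid(pre, pre_brain, "volumes and brain mask")
  like_volume(pre, (pre$data - post_aligned$data) * pre_brain$data)
}

#' Expand the cavity seed through the difference image
#'
#' Two-class mixture EM on difference values within the resected lobe;
#' class 1 (cavity) is pinned to the seed voxels and initialised from their
#' values (its standard deviation floored at half of class 2's, so a
#' degenerate seed-difference distribution cannot collapse the cavity
#' class), class 2 initialised from the lobe outside the seed dilated by 2
#' voxels.
#' The class-1 assignment (union the seed) is intersected with the lobe and
#' its largest 26-connected component is returned.
#'
#' @param diff Difference image from [subtract_images()].
#' @param cavity_seed Nonempty [binary_mask()] (the step-9 cavity CSF, mapped
#'   to pre-operative space).
#' @param resected_lobe [binary_mask()] search territory.
#' @return A [binary_mask()].
#' @export
expand_cavity <- function(diff, cavity_seed, resected_lobe) {
  stopifnot_same_grid(diff, cavity_seed, "difference image and seed")
  stopifnot_same_grid(diff, resected_lobe, "difference image and lobe")
  if (!any(cavity_seed$data)) stop("no cavity found (empty seed)")
  ring_excl <- mask_dilate(cavity_seed, rounds = 2L, conn = 26L)
  bg_region <- resected_lobe$data & !ring_excl$data
  sel <- resected_lobe$data | cavity_seed$data
  idx <- which(sel)
  x <- diff$data[idx]
  fixed <- integer(length(idx))
  fixed[cavity_seed$data[idx]] <- 1L
  init1 <- diff$data[cavity_seed$data]
  init2 <- if (any(bg_region)) diff$data[bg_region] else x[fixed == 0L]
  # on piecewise-constant difference images the seed class can collapse to a
  # near-zero variance and reject partial-volume boundary voxels with
  # unambiguous positive difference; floor its spread at half the background
  # class's so the cavity class stays open without reaching into the
  # background's own range
  r1 <- em2_gauss(x, fixed, init1, init2, sd1_floor_ratio = 0.5)
  out <- array(FALSE, dim(diff$data))
  out[idx] <- r1 > 0.5
  out <- (out | cavity_seed$data) & resected_lobe$data
  if (!any(out)) stop("no cavity found (empty class assignment)")
  largest_component(binary_mask(out, diff$spacing, diff$origin), conn = 26L)
}

#' Remove misalignment spurs by constrained erosion-dilation
#'
#' Poor registration leaves difference blobs attached to the cavity through
#' narrow necks. The mask is eroded (unit Chebyshev ball, i.e. the full
#' 26-neighbourhood, so voxels held up only by a thin bridge erode away too),
#' reduced to its largest
#' component, then re-grown by a fixed number of one-voxel dilations
#' constrained inside the original mask; after each round, newly reached
#' voxels are clustered (26-connectivity) and clusters smaller than
#' `cluster_threshold` are removed and barred from later rounds, so the main
#' cavity is restored while thin bridges and their attachments are dropped.
#'
#' @param mask Nonempty [binary_mask()].
#' @param erosion_radius Erosion rounds (default 1).
#' @param n_dilations Constrained dilation rounds (default 3).
#' @param cluster_threshold Minimum viable cluster size in voxels; default
#'   `max(10, 1%` of the mask volume`)`.
#' @return The cleaned [binary_mask()] (always a subset of the input). If the
#'   erosion would empty the mask (small lesionectomies), the input is
#'   returned unchanged with a warning.
#' @export
remove_misalignment_spurs <- function(mask, erosion_radius = 1L,
                                      n_dilations = 3L,
                                      cluster_threshold = NULL) {
  if (!any(mask$data)) stop("mask is empty")
  if (is.null(cluster_threshold))
    cluster_threshold <- max(10, ceiling(0.01 * sum(mask$data)))
  core <- mask_erode(mask, rounds = erosion_radius, conn = 26L)
  if (!any(core$data)) {
    warning("erosion empties the mask; skipping spur removal")
    return(mask)
  }
  core <- largest_component(core, conn = 26L)
  acc <- core$data
  forbidden <- array(FALSE, dim(acc))
  for (k in seq_len(n_dilations)) {
    grown <- mask_dilate(binary_mask(acc, mask$spacing, mask$origin),
                         rounds = 1L, conn = 26L)$data
    new_vox <- grown & mask$data & !acc & !forbidden
    if (!any(new_vox)) break
    lab <- label_components(new_vox, conn = 26L)
    sizes <- tabulate(lab)
    small <- which(sizes < cluster_threshold)
    if (length(small)) {
      bad <- array(lab %in% small, dim(acc))
      forbidden <- forbidden | bad
      new_vox <- new_vox & !bad
    }
    acc <- acc | new_vox
  }
  binary_mask(acc, mask$spacing, mask$origin)
}

#' Directional dilation of the mask boundary toward nearby CSF
#'
#' For every boundary voxel of the mask, if a CSF voxel lies within `max_dist`
#' voxels (Chebyshev metric by default), the voxels on the discrete line
#' segment to the nearest such CSF voxel are added. The mask thus extends to
#' the fluid boundary while dilation into tissue that was not resected is
#' blocked (tissue has no nearby CSF).
#'
#' @param mask A [binary_mask()].
#' @param csf A [binary_mask()] of CSF in the same space.
#' @param max_dist Search radius in voxels (default 3).
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @param max_passes The operator is applied repeatedly until no boundary
#'   voxel can advance (a single pass only adds the voxels strictly between
#'   the current boundary and the fluid, so a boundary starting more than two
#'   voxels away would otherwise stop short of the tissue boundary);
#'   `max_passes = 1` gives the single-pass operator.
#' @return The dilated [binary_mask()] (a superset of the input).
#' @export
directional_boundary_dilation <- function(mask, csf, max_dist = 3L,
                                          metric = c("chebyshev", "euclidean"),
                                          max_passes = 10L) {
  metric <- match.arg(metric)
  stopifnot_same_grid(mask, csf, "mask and CSF mask")
  m <- as_int_mask(mask)
  cheb <- as.integer(metric == "chebyshev")
  for (i in seq_len(max_passes)) {
    out <- cpp_boundary_dilation(m, as_int_mask(csf), dim(m),
                                 as.integer(max_dist), cheb)
    if (sum(out) == sum(m)) break
    m <- array(out, dim(m))
  }
  binary_mask(array(m > 0L, dim(m)), mask$spacing, mask$origin)
}

#' Finalise the resection mask
#'
#' Morphological closing plus internal hole filling (background components not
#' connected to the volume border are filled), multiplication by the
#' pre-operative resected-lobe mask, reduction to the largest connected
#' component, and resampling back to the original pre-operative grid.
#'
#' @param mask Nonempty [binary_mask()] on the working grid.
#' @param resected_lobe_pre [binary_mask()] of the resected lobe in
#'   pre-operative space (working grid).
#' @param original_grid A [vol3d()] defining the output grid, or `NULL` to
#'   stay on the working grid.
#' @return The final [binary_mask()].
#' @export
finalize_mask <- function(mask, resected_lobe_pre, original_grid = NULL) {
  if (!any(mask$data)) stop("mask is empty")
  stopifnot_same_grid(mask, resected_lobe_pre, "mask and lobe mask")
  out <- mask_close(mask, rounds = 1L, conn = 26L)
  out <- fill_holes(out)
  out <- binary_mask(out$data & resected_lobe_pre$data, mask$spacing, mask$origin)
  if (!any(out$data)) stop("cavity outside specified lobe")
  out <- largest_component(out, conn = 26L)
  if (!is.null(original_grid) && !same_grid(out, original_grid)) {
    base <- index_arrays(dim(original_grid$data))
    sp <- original_grid$spacing; or <- original_grid$origin
    wx <- or[1] + (base$x - 1) * sp[1]
    wy <- or[2] + (base$y - 1) * sp[2]
    wz <- or[3] + (base$z - 1) * sp[3]
    vals <- cpp_sample(as.numeric(out$data), dim(out$data),
                       (wx - out$origin[1]) / out$spacing[1],
                       (wy - out$origin[2]) / out$spacing[2],
                       (wz - out$origin[3]) / out$spacing[3], 1L, 0)
    out <- binary_mask(array(vals, dim(original_grid$data)) >= 0.5, sp, or)
    if (!any(out$data)) stop("cavity outside specified lobe")
    out <- largest_component(out, conn = 26L)
  }
  out
}
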