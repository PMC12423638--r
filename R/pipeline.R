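# End-to-end orchestration: Part A (per image), Part B (registration),
# Part C (steps 7-14), intermediates and a machine-readable report.

collectify <- function(report_env, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) {
      report_env$warnings <- c(report_env$warnings,
                               paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  report_env$timing[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  res
}

#' Run the full resection-mask pipeline
#'
#' Orchestrates data preparation (resolution normalisation, lobe-atlas
#' assembly, brain masking, bias correction, top-percentile clamping, atlas
#' dilation, lobe splitting), rigid + deformable registration of the
#' post-operative volume into pre-operative space, and cavity classification
#' (rescale, prior-guided mixture segmentation, CSF split, image subtraction,
#' seed expansion, spur removal, boundary dilation, finalisation). All
#' intermediates are retained for audit.
#'
#' @param pre,post Pre- and post-operative [vol3d()] volumes.
#' @param labels_pre,labels_post Region [label_volume()]s for each image
#'   (from an external whole-brain segmenter, or the phantom's ground truth).
#' @param spec A [resection_spec()]; the default searches both hemispheres and
#'   all lobes.
#' @param lobe_map Region-to-lobe mapping table (see [phantom_lobe_map()]).
#' @param target_fov Working field of view in mm; `NULL` (default) keeps the
#'   native grid when the input is already 1 mm isotropic, otherwise 256.
#' @param registration_iterations,deformable_iterations Per-level iteration
#'   schedules for the two registration stages.
#' @param spur_params `list(erosion_radius, n_dilations, cluster_threshold)`
#'   forwarded to [remove_misalignment_spurs()].
#' @param csf_low Rescaled-intensity threshold under which pre-operative
#'   voxels count as CSF for the boundary dilation (default 0.2).
#' @return `list(final_mask, state, report)`: the final [binary_mask()] in
#'   pre-operative space, every intermediate (named by step), and a report
#'   list (per-step voxel counts, warnings, timings).
#' @export
run_cavity_pipeline <- function(pre, post, labels_pre, labels_post,
                                spec = resection_spec(),
                                lobe_map = phantom_lobe_map(),
                                target_fov = NULL,
                                registration_iterations = c(100, 50, 25),
                                deformable_iterations = c(100, 50, 25),
                                spur_params = list(),
                                csf_low = 0.2) {
  rep_env <- new.env()
  rep_env$warnings <- character(0)
  rep_env$timing <- list()
  state <- list()
  original_pre <- pre

  ## ---- Part A: data preparation --------------------------------------
  needs_norm <- !(all(abs(pre$spacing - 1) < 1e-9) && is.null(target_fov))
  if (needs_norm) {
    fov <- target_fov %||% 256
    pre <- collectify(rep_env, "normalize_pre",
                      normalize_resolution(pre, 1, fov))
    labels_pre <- collectify(rep_env, "normalize_labels_pre",
                             normalize_resolution(labels_pre, 1, fov))
  }
  needs_norm_post <- !(all(abs(post$spacing - 1) < 1e-9) && is.null(target_fov))
  if (needs_norm_post) {
    fov <- target_fov %||% 256
    post <- collectify(rep_env, "normalize_post",
                       normalize_resolution(post, 1, fov))
    labels_post <- collectify(rep_env, "normalize_labels_post",
                              normalize_resolution(labels_post, 1, fov))
  }

  prep <- function(vol, labels, tag) {
    atlas <- collectify(rep_env, paste0("atlas_", tag),
                        build_lobe_atlas(labels, lobe_map))
    mb <- collectify(rep_env, paste0("mask_brain_", tag),
                     mask_brain(vol, atlas))
    bc <- collectify(rep_env, paste0("bias_", tag),
                     correct_bias(mb$masked, mb$brain))
    cl <- collectify(rep_env, paste0("clamp_", tag),
                     clamp_top_percentile(bc$corrected, mb$brain))
    list(vol = cl, brain = mb$brain, atlas = atlas, bias = bc$field)
  }
  A_pre <- prep(pre, labels_pre, "pre")
  A_post <- prep(post, labels_post, "post")

  full_atlas_pre <- collectify(rep_env, "dilate_atlas_pre",
                               dilate_atlas_through_wm(A_pre$atlas, A_pre$brain))
  lobes_pre <- collectify(rep_env, "split_lobes_pre",
                          split_resection_lobes(full_atlas_pre, spec))
  state$atlas_pre <- full_atlas_pre
  state$resected_lobe <- lobes_pre$resected
  state$other_lobes <- lobes_pre$other

  ## ---- Part B: registration ------------------------------------------
  rigid <- collectify(rep_env, "register_rigid",
                      register_rigid(A_pre$vol, A_post$vol, A_pre$brain,
                                     iterations = registration_iterations))
  chain_rigid <- transform_chain(rigid = rigid, fixed_grid = A_pre$vol)
  post_rigid <- collectify(rep_env, "apply_rigid",
                           apply_chain(A_post$vol, chain_rigid))
  dfield <- collectify(rep_env, "register_deformable",
                       register_deformable(A_pre$vol, post_rigid, A_pre$brain,
                                           iterations = deformable_iterations))
  chain <- transform_chain(rigid = rigid, field = dfield, fixed_grid = A_pre$vol)
  post_in_pre <- collectify(rep_env, "apply_chain",
                            apply_chain(A_post$vol, chain))
  brain_post_in_pre <- collectify(rep_env, "apply_chain_brain",
                                  apply_chain(A_post$brain, chain))
  state$rigid <- rigid
  state$field <- dfield
  state$post_in_pre <- post_in_pre

  ## ---- Part C: cavity classification ---------------------------------
  brain_pre <- A_pre$brain
  pre_r <- collectify(rep_env, "step07_rescale_pre",
                      rescale_unit(A_pre$vol, brain_pre))
  post_r <- collectify(rep_env, "step07_rescale_post",
                       rescale_unit(post_in_pre, brain_pre))
  state$pre_rescaled <- pre_r
  state$post_rescaled <- post_r

  vents <- collectify(rep_env, "priors_ventricles",
                      ventricle_mask(labels_pre, lobe_map))
  if (!any(vents$data))
    stop("stage 'priors_ventricles': no ventricle voxels in the region labels")

  if (spec_is_default(spec)) {
    # no lobe prior: provisional cavity from a ventricle-seeded run over the
    # whole brain, then 'tissue in the non-resected lobes' becomes brain
    # tissue away from that provisional estimate
    prov_priors <- list(
      csf_prior = vents,
      tissue_prior = binary_mask(
        lobes_pre$resected$data &
          !mask_dilate(vents, rounds = 4L, conn = 26L)$data &
          post_r$data > 0.35,
        post_r$spacing, post_r$origin),
      search_region = lobes_pre$resected)
    prov_priors$search_region <- binary_mask(
      lobes_pre$resected$data & !prov_priors$tissue_prior$data,
      post_r$spacing, post_r$origin)
    prov <- collectify(rep_env, "step08_provisional",
                       prior_mixture_segment(post_r, prov_priors))
    tissue_prior <- binary_mask(
      lobes_pre$resected$data & !mask_dilate(prov, rounds = 2L, conn = 26L)$data,
      post_r$spacing, post_r$origin)
    search_region <- lobes_pre$resected
    search_region <- binary_mask(search_region$data & !tissue_prior$data,
                                 post_r$spacing, post_r$origin)
  } else {
    tissue_prior <- lobes_pre$other
    search_region <- lobes_pre$resected
  }
  priors <- list(csf_prior = vents, tissue_prior = tissue_prior,
                 search_region = search_region)
  state$priors <- priors

  postop_cavity <- collectify(rep_env, "step08_postop_cavity",
                              prior_mixture_segment(post_r, priors))
  if (!any(postop_cavity$data))
    stop("stage 'step08_postop_cavity': no cavity found")
  state$postop_cavity <- postop_cavity

  cavity_csf <- collectify(rep_env, "step09_cavity_csf",
                           kmeans2_csf(post_r, postop_cavity))
  state$cavity_csf <- cavity_csf

  diff <- collectify(rep_env, "step10_diff_image",
                     subtract_images(pre_r, post_r, brain_pre))
  state$diff_image <- diff

  # the step-8 cavity (CSF + damaged tissue) seeds the expansion; the step-9
  # CSF subset is kept for the boundary dilation's fluid map
  expanded <- collectify(rep_env, "step11_expanded",
                         expand_cavity(diff, postop_cavity, lobes_pre$resected))
  state$expanded_mask <- expanded

  cleaned <- collectify(rep_env, "step12_cleaned", do.call(
    remove_misalignment_spurs,
    c(list(mask = expanded), spur_params)))
  state$cleaned_mask <- cleaned

  # fluid map for the boundary dilation: the step-9 cavity CSF, the whole
  # low-intensity class of the registered post image (post-operative CSF in
  # pre space), and pre-operative CSF outside the resection territory
  csf_union <- binary_mask(
    cavity_csf$data |
      (brain_pre$data & post_r$data < csf_low) |
      (brain_pre$data & pre_r$data < csf_low & !state$resected_lobe$data),
    pre_r$spacing, pre_r$origin)
  dilated <- collectify(rep_env, "step13_dilated",
                        directional_boundary_dilation(cleaned, csf_union))
  state$dilated_mask <- dilated

  final <- collectify(rep_env, "step14_final",
                      finalize_mask(dilated, lobes_pre$resected, original_pre))
  state$final_mask <- final

  counts <- list(
    brain_pre = sum(brain_pre$data),
    brain_post = sum(A_post$brain$data),
    resected_lobe = sum(state$resected_lobe$data),
    step08_postop_cavity = sum(postop_cavity$data),
    step09_cavity_csf = sum(cavity_csf$data),
    step11_expanded = sum(expanded$data),
    step12_cleaned = sum(cleaned$data),
    step13_dilated = sum(dilated$data),
    step14_final = sum(final$data)
  )
  ncomp <- max(label_components(final$data))
  report <- list(voxel_counts = counts,
                 final_components = ncomp,
                 rigid = list(rot_deg = rigid$rot_deg, trans_mm = rigid$trans_mm),
                 warnings = rep_env$warnings,
                 timing_s = rep_env$timing)
  list(final_mask = final, state = state, report = report)
}

#' Write pipeline intermediates and report to a folder
#'
#' Intermediates are written as NIfTI with step-numbered names and the report
#' as `report.json`.
#'
#' @param result Output of [run_cavity_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- result$state
  files <- list(step08_postop_cavity = st$postop_cavity,
                step09_cavity_csf = st$cavity_csf,
                step10_diff_image = st$diff_image,
                step11_expanded_mask = st$expanded_mask,
                step12_cleaned_mask = st$cleaned_mask,
                step13_dilated_mask = st$dilated_mask,
                step14_final_mask = result$final_mask)
  for (nm in names(files))
    write_volume(files[[nm]], file.path(out_dir, paste0(nm, ".nii.gz")))
  write_rigid(st$rigid, file.path(out_dir, "rigid_transform.json"))
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
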