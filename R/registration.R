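# Rigid + deformable alignment of the post-operative volume into
# pre-operative space. Same-modality T1-T1 alignment, so the similarity is
# masked mean-squared difference on unit-rescaled intensities; both stages are
# multi-resolution with a fixed iteration schedule and contain no stochastic
# sampling, so repeated runs are bit-identical.

#' Rigid transform (6 parameters)
#'
#' Maps fixed-space world coordinates to moving-space world coordinates:
#' `y = R (x - center) + center + t`, with `R = Rz Ry Rx` built from the three
#' rotation angles.
#'
#' @param rot_deg Rotations about x, y, z in degrees.
#' @param trans_mm Translations in mm.
#' @param center Centre of rotation (world mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rot_deg = c(0, 0, 0), trans_mm = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rot_deg <- as.numeric(rot_deg); trans_mm <- as.numeric(trans_mm)
  th <- rot_deg * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  structure(list(rot_deg = rot_deg, trans_mm = trans_mm,
                 center = as.numeric(center), R = Rz %*% Ry %*% Rx),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s; trans (mm): %s\n",
              paste(format(x$rot_deg, digits = 4), collapse = ", "),
              paste(format(x$trans_mm, digits = 4), collapse = ", ")))
  invisible(x)
}

# Apply the world-coordinate mapping to coordinate vectors.
rigid_map_world <- function(tr, wx, wy, wz) {
  c0 <- tr$center; t0 <- tr$trans_mm; R <- tr$R
  xc <- wx - c0[1]; yc <- wy - c0[2]; zc <- wz - c0[3]
  list(x = R[1, 1] * xc + R[1, 2] * yc + R[1, 3] * zc + c0[1] + t0[1],
       y = R[2, 1] * xc + R[2, 2] * yc + R[2, 3] * zc + c0[2] + t0[2],
       z = R[3, 1] * xc + R[3, 2] * yc + R[3, 3] * zc + c0[3] + t0[3])
}

#' Invert a rigid transform
#'
#' @param tr A [rigid_transform()].
#' @return A `rigid_transform`-like object (matrix form) mapping the other way.
#' @export
invert_rigid <- function(tr) {
  out <- tr
  out$R <- t(tr$R)
  out$trans_mm <- as.numeric(-t(tr$R) %*% tr$trans_mm)
  out$rot_deg <- -rev(rev(tr$rot_deg))  # matrix form is authoritative
  out
}

#' Compose two rigid transforms (apply `a`, then `b`)
#'
#' @param a,b [rigid_transform()] objects sharing a centre of rotation.
#' @return Composite transform `b(a(x))` in matrix form.
#' @export
compose_rigid <- function(a, b) {
  out <- a
  out$R <- b$R %*% a$R
  out$trans_mm <- as.numeric(b$R %*% a$trans_mm) + b$trans_mm
  out$rot_deg <- c(NA_real_, NA_real_, NA_real_)
  out
}

#' Deviation of an estimated rigid transform from the truth's inverse
#'
#' Registration of a moving image displaced by transform `applied` should
#' recover `applied^{-1}`; this composes the two and reports the residual
#' rotation angle and translation magnitude of the (near-identity) result.
#'
#' @param estimated,applied [rigid_transform()] objects.
#' @return Named numeric: `trans_mm` (residual displacement at the centre of
#'   rotation) and `rot_deg` (residual rotation angle).
#' @export
rigid_deviation <- function(estimated, applied) {
  comp <- compose_rigid(estimated, applied)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(comp$R)) - 1) / 2))) * 180 / pi
  c(trans_mm = sqrt(sum(comp$trans_mm^2)), rot_deg = ang)
}

# Robust [0, 1] rescale of an array using quantiles of `subset` voxels.
robust_unit <- function(arr, subset, probs = c(0.01, 0.99)) {
  q <- quantile(arr[subset], probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("cannot rescale: degenerate intensity range")
  out <- pmin(1, pmax(0, (arr - q[1]) / (q[2] - q[1])))
  array(out, dim(arr))
}

# Downsample a volume by integer factor f (Gaussian presmoothing sigma = f/2).
downsample_volume <- function(vol, f, smooth = TRUE) {
  if (f == 1) return(vol)
  d <- dim(vol$data)
  arr <- vol$data
  if (smooth) arr <- array(cpp_gauss_smooth(as.numeric(arr), d, rep(f / 2, 3)), d)
  ix <- seq(1, d[1], by = f); iy <- seq(1, d[2], by = f); iz <- seq(1, d[3], by = f)
  vol3d(arr[ix, iy, iz], vol$spacing * f, vol$origin)
}

downsample_mask <- function(mask, f) {
  if (f == 1) return(mask)
  d <- dim(mask$data)
  ix <- seq(1, d[1], by = f); iy <- seq(1, d[2], by = f); iz <- seq(1, d[3], by = f)
  binary_mask(mask$data[ix, iy, iz], mask$spacing * f, mask$origin)
}

#' Rigid registration (multi-resolution, masked MSD)
#'
#' Gradient-based (BFGS with finite-difference gradients) minimisation of the
#' masked mean-squared intensity difference between the unit-rescaled fixed
#' and moving volumes, over 3 rotations + 3 translations, at 4x / 2x / 1x
#' resolution. Initialisation is the identity and the iteration schedule is
#' fixed, so the result is deterministic.
#'
#' @param fixed,moving [vol3d()] volumes (1 mm grids expected).
#' @param fixed_mask [binary_mask()] on the fixed grid (e.g. the brain mask).
#' @param levels Downsampling factors, coarse to fine.
#' @param iterations Optimiser iteration cap per level.
#' @return A [rigid_transform()] mapping fixed world coordinates into moving
#'   world coordinates, with attributes `cost` (final masked MSD) and
#'   `converged`.
#' @export
register_rigid <- function(fixed, moving, fixed_mask,
                           levels = c(4, 2, 1), iterations = c(100, 50, 25)) {
  stopifnot_same_grid(fixed, fixed_mask, "fixed volume and mask")
  # both images rescaled by the same foreground rule so identical inputs map
  # to identical intensities (the mask restricts the metric, not the rescale)
  fg <- function(v) v$data > 0.05 * quantile(v$data, 0.99, names = FALSE)
  fx_pos <- fg(fixed); mv_pos <- fg(moving)
  if (!any(mv_pos)) stop("moving volume has no foreground")
  f_arr <- robust_unit(fixed$data, fx_pos)
  m_arr <- robust_unit(moving$data, mv_pos)
  fixed_n <- vol3d(f_arr, fixed$spacing, fixed$origin)
  moving_n <- vol3d(m_arr, moving$spacing, moving$origin)
  center <- grid_center(fixed)
  # brain radius, used to scale the finite-difference step for rotations so a
  # probe step moves the periphery by a fixed fraction of the level's voxel
  idxm <- which(fixed_mask$data, arr.ind = TRUE)
  rbrain <- max(sqrt(rowSums(sweep(idxm, 2, colMeans(idxm))^2))) * fixed$spacing[1]
  rbrain <- max(rbrain, 1)

  par <- c(0, 0, 0, 0, 0, 0)  # rx, ry, rz (deg), tx, ty, tz (mm)
  conv <- TRUE
  for (l in seq_along(levels)) {
    f <- levels[l]
    fx <- downsample_volume(fixed_n, f)
    mk <- downsample_mask(fixed_mask, f)
    mv <- downsample_volume(moving_n, f)
    idx <- which(mk$data)
    if (!length(idx)) stop("fixed mask empty at level ", f)
    w <- grid_world_coords(fx)
    wx <- w$x[idx]; wy <- w$y[idx]; wz <- w$z[idx]
    fv <- fx$data[idx]
    mdim <- dim(mv$data); msp <- mv$spacing; mor <- mv$origin
    mdat <- as.numeric(mv$data)
    cost <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], center)
      mp <- rigid_map_world(tr, wx, wy, wz)
      sv <- cpp_sample(mdat, mdim, (mp$x - mor[1]) / msp[1],
                       (mp$y - mor[2]) / msp[2], (mp$z - mor[3]) / msp[3],
                       1L, NA_real_)
      ok <- !is.na(sv)
      frac <- mean(ok)
      if (frac < 0.25) return(10 + (0.25 - frac))
      v <- mean((fv[ok] - sv[ok])^2) + 0.25 * (1 - frac)
      if (!is.finite(v)) stop("non-finite registration loss")
      v
    }
    sp_l <- fx$spacing[1]
    nd <- c(rep(0.2 * sp_l / rbrain * 180 / pi, 3), rep(0.2 * sp_l, 3))
    res <- optim(par, cost, method = "BFGS",
                 control = list(maxit = iterations[l], reltol = 1e-10,
                                ndeps = nd))
    par <- res$par
    if (l == length(levels)) {
      # derivative-free polish: the trilinear cost is only piecewise smooth,
      # so finish with a simplex search at the finest level
      res <- optim(par, cost, method = "Nelder-Mead",
                   control = list(maxit = 8L * iterations[l], reltol = 1e-12))
      par <- res$par
      conv <- res$convergence == 0L
      final_cost <- res$value
    }
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "cost") <- final_cost
  attr(out, "converged") <- conv
  if (!conv) warning("rigid registration hit the iteration cap; returning best iterate")
  out
}

#' Dense displacement field
#'
#' Per-voxel displacements in mm on the fixed grid; sampling a moving volume
#' at `x + u(x)` aligns it to the fixed volume.
#'
#' @param ux,uy,uz 3D arrays of displacements (mm).
#' @param spacing,origin Fixed-grid description.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy, uz, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  structure(list(ux = ux, uy = uy, uz = uz, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<displacement_field> %s voxels, |u| max %.3f mm, 99%% %.3f mm\n",
              paste(dim(x$ux), collapse = "x"), max(mag),
              quantile(mag, 0.99, names = FALSE)))
  invisible(x)
}

#' Deformable registration (demons-style, multi-resolution)
#'
#' Iterative intensity-difference-driven update (Thirion force using the fixed
#' image gradient), Gaussian-regularised both in the update (sigma 1 voxel)
#' and in the accumulated field (sigma 2 voxels), on a 4x / 2x / 1x pyramid
#' with a fixed iteration schedule. The field is zero outside the fixed mask
#' plus a 3-voxel margin. If the masked MSD diverges the best iterate is
#' returned with a warning.
#'
#' @param fixed [vol3d()] fixed volume.
#' @param moving_rigid [vol3d()] moving volume already rigid-aligned onto the
#'   fixed grid.
#' @param fixed_mask [binary_mask()] on the fixed grid.
#' @param levels Downsampling factors, coarse to fine.
#' @param iterations Iterations per level.
#' @param sigma_field,sigma_update Gaussian regularisation (voxels).
#' @return A [displacement_field()] on the fixed grid.
#' @export
register_deformable <- function(fixed, moving_rigid, fixed_mask,
                                levels = c(4, 2, 1), iterations = c(100, 50, 25),
                                sigma_field = 2, sigma_update = 1) {
  stopifnot_same_grid(fixed, moving_rigid, "fixed and moving volumes")
  stopifnot_same_grid(fixed, fixed_mask, "fixed volume and mask")
  f_arr <- robust_unit(fixed$data, fixed_mask$data)
  m_arr <- robust_unit(moving_rigid$data, fixed_mask$data)
  fixed_n <- vol3d(f_arr, fixed$spacing, fixed$origin)
  moving_n <- vol3d(m_arr, moving_rigid$spacing, moving_rigid$origin)

  u <- NULL
  for (l in seq_along(levels)) {
    f <- levels[l]
    fx <- downsample_volume(fixed_n, f)
    mv <- downsample_volume(moving_n, f)
    mk <- downsample_mask(fixed_mask, f)
    d <- dim(fx$data); sp <- fx$spacing
    margin <- mask_dilate(mk, rounds = 3L, conn = 6L)$data
    inmask <- mk$data

    if (is.null(u)) {
      u <- list(x = array(0, d), y = array(0, d), z = array(0, d))
    } else {
      # resample previous (coarser) field onto this grid
      w <- grid_world_coords(fx)
      up <- function(comp, prev) {
        array(cpp_sample(as.numeric(prev), dim(prev),
                         (w$x - prev_or[1]) / prev_sp[1],
                         (w$y - prev_or[2]) / prev_sp[2],
                         (w$z - prev_or[3]) / prev_sp[3], 1L, 0), d)
      }
      u <- list(x = up(NULL, u$x), y = up(NULL, u$y), z = up(NULL, u$z))
    }
    prev_sp <- sp; prev_or <- fx$origin

    # fixed-image gradient (per mm), central differences
    grad_axis <- function(a, ax) {
      d3 <- dim(a)
      g <- array(0, d3)
      n <- d3[ax]
      idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
      if (ax == 1) g <- (a[idx_p, , ] - a[idx_m, , ]) / (2 * sp[1])
      if (ax == 2) g <- (a[, idx_p, ] - a[, idx_m, ]) / (2 * sp[2])
      if (ax == 3) g <- (a[, , idx_p] - a[, , idx_m]) / (2 * sp[3])
      g
    }
    gx <- grad_axis(fx$data, 1); gy <- grad_axis(fx$data, 2); gz <- grad_axis(fx$data, 3)
    g2 <- gx^2 + gy^2 + gz^2

    base <- index_arrays(d)
    mdat <- as.numeric(mv$data)
    best <- list(energy = Inf, u = u)
    worse <- 0L
    for (it in seq_len(iterations[l])) {
      xi <- (base$x - 1) + u$x / sp[1]
      yi <- (base$y - 1) + u$y / sp[2]
      zi <- (base$z - 1) + u$z / sp[3]
      mw <- array(cpp_sample(mdat, d, xi, yi, zi, 1L, NA_real_), d)
      diffv <- fx$data - mw
      diffv[is.na(diffv)] <- 0
      energy <- mean(diffv[inmask]^2)
      if (!is.finite(energy)) { warning("divergent field energy; stopping"); u <- best$u; break }
      if (energy < best$energy) { best <- list(energy = energy, u = u); worse <- 0L }
      else { worse <- worse + 1L; if (worse >= 10L) { u <- best$u; break } }
      denom <- g2 + diffv^2
      denom[denom < 1e-9] <- 1e-9
      w <- (diffv / denom) * margin
      dux <- w * gx; duy <- w * gy; duz <- w * gz
      # cap the raw update at one voxel (the Thirion bound 0.5/|grad| is
      # unbounded in flat regions)
      dnorm <- sqrt(dux^2 + duy^2 + duz^2)
      cap <- min(sp)
      over <- dnorm > cap
      if (any(over)) {
        scl <- cap / dnorm[over]
        dux[over] <- dux[over] * scl
        duy[over] <- duy[over] * scl
        duz[over] <- duz[over] * scl
      }
      dux <- array(cpp_gauss_smooth(dux, d, rep(sigma_update, 3)), d)
      duy <- array(cpp_gauss_smooth(duy, d, rep(sigma_update, 3)), d)
      duz <- array(cpp_gauss_smooth(duz, d, rep(sigma_update, 3)), d)
      u$x <- array(cpp_gauss_smooth(u$x + dux, d, rep(sigma_field, 3)), d) * margin
      u$y <- array(cpp_gauss_smooth(u$y + duy, d, rep(sigma_field, 3)), d) * margin
      u$z <- array(cpp_gauss_smooth(u$z + duz, d, rep(sigma_field, 3)), d) * margin
    }
  }
  displacement_field(u$x, u$y, u$z, fixed$spacing, fixed$origin)
}

#' Transform chain
#'
#' Ordered combination of an optional displacement field (applied first, in
#' fixed space) and an optional rigid transform, mapping fixed-grid positions
#' into the moving volume: `y = rigid(x + u(x))`. Applying a chain to a
#' payload produced in moving (post-operative) space resamples it onto the
#' fixed (pre-operative) grid with a single interpolation.
#'
#' @param rigid A [rigid_transform()] or `NULL`.
#' @param field A [displacement_field()] or `NULL`.
#' @param fixed_grid A [vol3d()] (or any object with the fixed grid) defining
#'   the output grid.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(rigid = NULL, field = NULL, fixed_grid) {
  structure(list(rigid = rigid, field = field,
                 dim = dim(fixed_grid$data %||% fixed_grid$ux),
                 spacing = fixed_grid$spacing, origin = fixed_grid$origin),
            class = "transform_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a transform chain to a volume, label volume or mask
#'
#' Interpolation policy per payload kind: linear for intensity volumes,
#' nearest-neighbour for label volumes, linear followed by a 0.5 threshold for
#' binary masks.
#'
#' @param payload A [vol3d()], [label_volume()] or [binary_mask()] in moving
#'   space.
#' @param chain A [transform_chain()].
#' @return The payload resampled onto the fixed grid, same class as the input.
#' @export
apply_chain <- function(payload, chain) {
  d <- chain$dim; sp <- chain$spacing; or <- chain$origin
  if (!is.null(chain$field) &&
      !identical(dim(chain$field$ux), as.integer(d)) &&
      !identical(dim(chain$field$ux), d))
    stop("displacement field grid does not match the chain's fixed grid")
  base <- index_arrays(d)
  wx <- or[1] + (base$x - 1) * sp[1]
  wy <- or[2] + (base$y - 1) * sp[2]
  wz <- or[3] + (base$z - 1) * sp[3]
  if (!is.null(chain$field)) {
    wx <- wx + chain$field$ux
    wy <- wy + chain$field$uy
    wz <- wz + chain$field$uz
  }
  if (!is.null(chain$rigid)) {
    mp <- rigid_map_world(chain$rigid, wx, wy, wz)
    wx <- mp$x; wy <- mp$y; wz <- mp$z
  }
  interp <- if (inherits(payload, "labelvol")) 0L else 1L
  vals <- cpp_sample(as.numeric(payload$data), dim(payload$data),
                     (wx - payload$origin[1]) / payload$spacing[1],
                     (wy - payload$origin[2]) / payload$spacing[2],
                     (wz - payload$origin[3]) / payload$spacing[3],
                     interp, 0)
  arr <- array(vals, d)
  if (inherits(payload, "mask3d")) {
    binary_mask(arr >= 0.5, sp, or)
  } else if (inherits(payload, "labelvol")) {
    label_volume(array(as.integer(arr), d), payload$legend, sp, or)
  } else {
    vol3d(arr, sp, or)
  }
}

#' Serialise / deserialise transforms
#'
#' Rigid transforms are written as JSON (angles, translations, centre); fields
#' as a 4D NIfTI vector image.
#'
#' @param tr A [rigid_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rigid <- function(tr, path) {
  jsonlite::write_json(list(rot_deg = tr$rot_deg, trans_mm = tr$trans_mm,
                            center = tr$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rot_deg, x$trans_mm, x$center)
}

#' @rdname write_rigid
#' @param field A [displacement_field()].
#' @export
write_field <- function(field, path) {
  d <- dim(field$ux)
  arr <- array(0, c(d, 3))
  arr[, , , 1] <- field$ux; arr[, , , 2] <- field$uy; arr[, , , 3] <- field$uz
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}
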