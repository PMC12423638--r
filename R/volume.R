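#' @useDynLib resectr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile median rnorm runif optim pnorm qbeta lm.fit
#' @importFrom utils write.csv
NULL

#' 3D scalar volume
#'
#' The universal image carrier of the package: a 3D numeric array plus a voxel
#' grid description (spacing in mm per axis and the world position of the
#' centre of voxel `[1,1,1]`). World coordinates of voxel `(i,j,k)` (1-based)
#' are `origin + (c(i,j,k) - 1) * spacing`; the corresponding NIfTI affine is
#' diagonal.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world coordinate of the first voxel centre.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' Integer-coded label volume
#'
#' A [vol3d()] whose voxels are non-negative integer region codes, with a
#' legend mapping every nonzero code in use to a region name.
#'
#' @inheritParams vol3d
#' @param legend Named integer vector (names = region names, values = codes).
#'   Every nonzero code present in `data` must appear.
#' @return An object of class `c("labelvol", "vol3d")`.
#' @export
label_volume <- function(data, legend, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- vol3d(data, spacing, origin)
  storage.mode(v$data) <- "integer"
  if (any(v$data < 0L, na.rm = TRUE)) stop("label codes must be non-negative")
  codes <- sort(unique(v$data[v$data > 0L]))
  missing <- setdiff(codes, as.integer(legend))
  if (length(missing))
    stop("codes absent from legend: ", paste(missing, collapse = ", "))
  v$legend <- legend
  class(v) <- c("labelvol", "vol3d")
  v
}

#' Binary mask volume
#'
#' @inheritParams vol3d
#' @param data 3D logical (or 0/1 numeric) array.
#' @return An object of class `c("mask3d", "vol3d")`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- vol3d(array(as.logical(data), dim = dim(as.array(data))), spacing, origin)
  class(v) <- c("mask3d", "vol3d")
  v
}

#' @export
print.vol3d <- function(x, ...) {
  kind <- class(x)[1L]
  cat(sprintf("<%s> %s voxels, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x")))
  if (kind == "mask3d") cat(sprintf("  %d voxels set\n", sum(x$data)))
  invisible(x)
}

# Rebuild a volume of the same grid/class as `like` with new data.
like_volume <- function(like, data) {
  out <- like
  out$data <- array(data, dim = dim(like$data))
  if (inherits(like, "mask3d")) out$data <- array(as.logical(out$data), dim(out$data))
  if (inherits(like, "labelvol")) storage.mode(out$data) <- "integer"
  out
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid")
}

# World coordinates (mm) of every voxel centre, as three arrays.
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  sp <- vol$spacing; o <- vol$origin
  x <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  y <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  z <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  list(
    x = array(x, d),
    y = array(rep(y, each = d[1]), d),
    z = array(rep(z, each = d[1] * d[2]), d)
  )
}

# World centre of the grid (mm).
grid_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
}

# Sample `vol` at world coordinates (vectors, mm). interp "linear"|"nearest".
sample_world <- function(vol, wx, wy, wz, interp = "linear", background = 0) {
  vx <- (wx - vol$origin[1]) / vol$spacing[1]
  vy <- (wy - vol$origin[2]) / vol$spacing[2]
  vz <- (wz - vol$origin[3]) / vol$spacing[3]
  cpp_sample(as.numeric(vol$data), dim(vol$data), vx, vy, vz,
             if (interp == "nearest") 0L else 1L, background)
}

interp_for <- function(payload) {
  if (inherits(payload, "labelvol")) "nearest" else "linear"
}

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind One of `"volume"`, `"labels"`, `"mask"`.
#' @param legend Optional legend for `kind = "labels"`; defaults to naming each
#'   code `code_<k>`.
#' @return A [vol3d()], [label_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, kind = c("volume", "labels", "mask"), legend = NULL) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- attr(img, "pixdim")[1:3]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  org[!is.finite(org)] <- 0
  switch(kind,
    volume = vol3d(arr, sp, org),
    mask = binary_mask(arr >= 0.5, sp, org),
    labels = {
      arr <- array(as.integer(round(arr)), dim(arr))
      if (is.null(legend)) {
        codes <- sort(unique(arr[arr > 0L]))
        legend <- structure(codes, names = paste0("code_", codes))
      }
      label_volume(arr, legend, sp, org)
    })
}

#' Write a volume to NIfTI
#'
#' Masks are written as 0/1 integers, labels as integers, volumes as doubles.
#'
#' @param vol A [vol3d()] (or subclass).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (inherits(vol, "mask3d")) {
    dat <- array(as.integer(dat), dim(dat))
  }
  img <- RNifti::asNifti(dat)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Plot an axial slice of a volume
#'
#' Quick-look display for audits: grey-scale slice with optional mask overlay.
#'
#' @param vol A [vol3d()].
#' @param z Slice index (default: middle slice).
#' @param mask Optional [binary_mask()] outlined in red.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_slice <- function(vol, z = NULL, mask = NULL, ...) {
  d <- dim(vol$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- vol$data[, , z]
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl,
                  col = grDevices::gray.colors(128, 0, 1),
                  asp = 1, xlab = "x", ylab = "y", useRaster = TRUE, ...)
  if (!is.null(mask)) {
    ms <- mask$data[, , z]
    if (any(ms)) {
      idx <- which(ms, arr.ind = TRUE)
      graphics::points(idx[, 1], idx[, 2], pch = ".", col = "red")
    }
  }
  invisible(NULL)
}
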