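# 3D binary morphology helpers shared by the preprocessing and cavity stages.
# Connectivity conventions (documented, fixed for reproducibility):
#   * components and dilation clusters: 26-connectivity
#   * hole filling background: 6-connectivity
#   * spur-removal erosion element: the unit Chebyshev ball (26-neighbourhood)

as_int_mask <- function(mask) {
  if (inherits(mask, "mask3d")) array(as.integer(mask$data), dim(mask$data))
  else array(as.integer(as.logical(mask)), dim(as.array(mask)))
}

mask_like <- function(template, data) {
  if (inherits(template, "vol3d")) {
    binary_mask(array(as.logical(data), dim(template$data)),
                template$spacing, template$origin)
  } else {
    array(as.logical(data), dim(as.array(template)))
  }
}

#' Binary dilation / erosion
#'
#' One or more rounds of unit-structuring-element dilation or erosion.
#'
#' @param mask A [binary_mask()] or logical array.
#' @param rounds Number of rounds (default 1).
#' @param conn Neighbourhood: 6 (face) or 26 (face+edge+corner).
#' @return Same type as `mask`.
#' @export
mask_dilate <- function(mask, rounds = 1L, conn = 26L) {
  m <- as_int_mask(mask)
  for (i in seq_len(rounds)) m <- cpp_morph(m, dim(m), as.integer(conn), 1L)
  mask_like(mask, m)
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, rounds = 1L, conn = 6L) {
  m <- as_int_mask(mask)
  for (i in seq_len(rounds)) m <- cpp_morph(m, dim(m), as.integer(conn), 0L)
  mask_like(mask, m)
}

#' Connected-component labelling
#'
#' @param mask A [binary_mask()] or logical array.
#' @param conn 26 (default) or 6.
#' @return Integer array of component ids (0 = background), components numbered
#'   in order of their lowest linear voxel index.
#' @export
label_components <- function(mask, conn = 26L) {
  m <- as_int_mask(mask)
  cpp_label_components(m, dim(m), as.integer(conn))
}

#' Largest connected component
#'
#' @inheritParams label_components
#' @return Same type as `mask`, restricted to its largest component (ties
#'   broken toward the component with the lowest id, i.e. lowest first voxel).
#' @export
largest_component <- function(mask, conn = 26L) {
  lab <- label_components(mask, conn)
  if (!any(lab > 0L)) return(mask_like(mask, lab > 0L))
  tab <- tabulate(lab)
  keep <- which.max(tab)  # first maximum = lowest component id
  mask_like(mask, lab == keep)
}

#' Fill internal holes of a mask
#'
#' Background components (6-connected) not touching the grid border are
#' considered internal cavities and are filled.
#'
#' @inheritParams label_components
#' @return Same type as `mask`.
#' @export
fill_holes <- function(mask) {
  m <- as_int_mask(mask)
  d <- dim(m)
  bg <- cpp_label_components(1L - m, d, 6L)
  border_ids <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                         bg[, , 1], bg[, , d[3]]))
  border_ids <- border_ids[border_ids > 0L]
  hole <- bg > 0L & !(bg %in% border_ids)
  mask_like(mask, m == 1L | hole)
}

#' Morphological closing
#'
#' @inheritParams mask_dilate
#' @export
mask_close <- function(mask, rounds = 1L, conn = 26L) {
  mask_erode(mask_dilate(mask, rounds, conn), rounds, conn)
}

mask_count <- function(mask) {
  if (inherits(mask, "vol3d")) sum(mask$data) else sum(as.logical(mask))
}
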