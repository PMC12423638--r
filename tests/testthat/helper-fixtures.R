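# Shared fixtures and independent oracles. Phantom suites and pipeline runs
# are cached for the session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

suite48 <- function() cached("suite48", make_fixture_suite(seed = 101, grid_shape = 48))

# misalignment-only 96^3 pairs shared by the registration unit and
# acceptance tests (keyed by the leading translation component)
reg_pair96 <- function(trans_mm = c(4, -2.5, 1.5), rot_deg = c(3, -1.5, 1)) {
  cached(paste0("reg96_", trans_mm[1]), {
    pair <- make_misalignment_pair(seed = 19, grid_shape = 96,
                                   trans_mm = trans_mm, rot_deg = rot_deg)
    atlas <- build_lobe_atlas(pair$truth$regions)
    mb <- mask_brain(pair$pre, atlas)
    est <- suppressWarnings(register_rigid(pair$pre, pair$post, mb$brain))
    c(pair, list(brain = mb$brain, est = est))
  })
}
suite96 <- function() cached("suite96", make_fixture_suite(seed = 7, grid_shape = 96))

run_case <- function(cs, spec = cs$spec, ...) {
  t0 <- proc.time()[["elapsed"]]
  res <- run_cavity_pipeline(cs$pre, cs$post, cs$truth$regions,
                             cs$truth$labels_post, spec = spec, ...)
  res$elapsed_s <- proc.time()[["elapsed"]] - t0
  res
}

pipeline96 <- function(case) {
  cached(paste0("pipe96_", case), run_case(suite96()[[case]]))
}

pipeline48 <- function(case) {
  cached(paste0("pipe48_", case), run_case(suite48()[[case]]))
}

# --- independent oracles -------------------------------------------------

# logical-array shift with FALSE padding
arr_shift <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  sx <- xs + dx; sy <- ys + dy; sz <- zs + dz
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]; okz <- sz >= 1 & sz <= d[3]
  out[xs[okx], ys[oky], zs[okz]] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

neighbour_shifts <- function(conn) {
  if (conn == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    out <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      if (dx || dy || dz) out[[length(out) + 1L]] <- c(dx, dy, dz)
    out
  }
}

# brute-force connected components by iterated min-label propagation
brute_components <- function(mask, conn = 26) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  sh <- neighbour_shifts(conn)
  repeat {
    new_lab <- lab
    for (s in sh) {
      cand <- array(0, d)
      xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
      sx <- xs + s[1]; sy <- ys + s[2]; sz <- zs + s[3]
      okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]; okz <- sz >= 1 & sz <= d[3]
      cand[xs[okx], ys[oky], zs[okz]] <- lab[sx[okx], sy[oky], sz[okz]]
      take <- mask & cand > 0 & (new_lab == 0 | cand < new_lab)
      new_lab[take] <- cand[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# border-connected 6-neighbour flood fill of the background; returns the
# array of internal holes of `mask`
flood_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  flood <- array(FALSE, d)
  flood[1, , ] <- bg[1, , ]; flood[d[1], , ] <- bg[d[1], , ]
  flood[, 1, ] <- flood[, 1, ] | bg[, 1, ]; flood[, d[2], ] <- flood[, d[2], ] | bg[, d[2], ]
  flood[, , 1] <- flood[, , 1] | bg[, , 1]; flood[, , d[3]] <- flood[, , d[3]] | bg[, , d[3]]
  sh <- neighbour_shifts(6)
  repeat {
    grown <- flood
    for (s in sh) grown <- grown | arr_shift(flood, s[1], s[2], s[3])
    grown <- grown & bg
    if (identical(grown, flood)) break
    flood <- grown
  }
  bg & !flood
}

# full sign-pattern enumeration of the Wilcoxon signed-rank distribution
enum_wilcoxon <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  if (alternative == "greater") mean(W_all >= W - 1e-9) else mean(W_all <= W + 1e-9)
}

# random blobby mask: a few dilated seed points
random_blob_mask <- function(d, n_seeds = 4, grow = 3) {
  m <- array(FALSE, d)
  idx <- cbind(sample(2:(d[1] - 1), n_seeds, TRUE),
               sample(2:(d[2] - 1), n_seeds, TRUE),
               sample(2:(d[3] - 1), n_seeds, TRUE))
  m[idx] <- TRUE
  for (i in seq_len(grow)) {
    g <- m
    for (s in neighbour_shifts(6)) g <- g | arr_shift(m, s[1], s[2], s[3])
    m <- g
  }
  m
}

# legend for hand-built lobe-atlas label volumes in tests
lobe_atlas_legend_codes <- function() resectr:::lobe_atlas_legend()

grid_center_of <- function(v) resectr:::grid_center(v)
resectr_index_arrays <- function(d) resectr:::index_arrays(d)
map_rigid <- function(tr, wx, wy, wz) resectr:::rigid_map_world(tr, wx, wy, wz)
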