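# --- free-form deformation via a cubic B-spline control grid -----------------

#' Create a B-spline control grid
#'
#' Control points are laid out with `spacing_vox` voxels between them along
#' each axis, covering the full volume domain plus one boundary ring (cubic
#' B-spline support requires controls one cell beyond each end). Control k
#' (0-based) sits at voxel coordinate `(k - 1) * spacing`.
#'
#' @param shape volume dimensions (voxels).
#' @param spacing_vox control-point spacing per axis in voxels (scalar or
#'   length-3).
#' @return object of class `control_grid` with fields `shape`, `spacing_vox`,
#'   `displacements` (ncx x ncy x ncz x 3 array, voxel units).
#' @export
control_grid <- function(shape, spacing_vox = 8) {
  shape <- as.integer(shape)
  spacing_vox <- rep(as.numeric(spacing_vox), length.out = 3L)
  if (any(spacing_vox <= 0)) stop("control_grid: spacing must be positive")
  nc <- floor((shape - 1) / spacing_vox) + 4L
  structure(list(shape = shape, spacing_vox = spacing_vox,
                 displacements = array(0, dim = c(nc, 3L))),
            class = "control_grid")
}

#' Expand a control grid into a dense deformation field
#'
#' Evaluates the free-form deformation T(x) = x + sum_k B(||x - k|| / s) * d_k
#' with tensor-product cubic B-spline weights, giving a per-voxel displacement
#' vector (voxel units).
#'
#' @param grid a [control_grid()].
#' @param shape target volume shape; must be covered by the grid.
#' @return object of class `deformation_field` with fields `disp`
#'   (nx x ny x nz x 3 array) and `grid` (provenance).
#' @export
bspline_expand <- function(grid, shape = grid$shape) {
  stopifnot(inherits(grid, "control_grid"))
  shape <- as.integer(shape)
  if (any(shape > grid$shape))
    stop("bspline_expand: grid does not cover the requested shape")
  nc <- dim(grid$displacements)[1:3]
  dense <- ffd_expand_cpp(as.vector(grid$displacements), nc, shape,
                          grid$spacing_vox)
  structure(list(disp = array(dense, dim = c(shape, 3L)), grid = grid),
            class = "deformation_field")
}

identity_field <- function(shape) {
  bspline_expand(control_grid(shape))
}

field_disp <- function(field, shape) {
  if (is.null(field)) array(0, dim = c(shape, 3L)) else field$disp
}

#' Warp a gray volume along a deformation field
#'
#' Pull-back warp with trilinear interpolation: `out(x) = v(x + d(x))`.
#' Out-of-domain samples take `fill` (default: the volume minimum, i.e.
#' background).
#'
#' @param v a [gray_volume()].
#' @param field a `deformation_field` on the same grid.
#' @param fill out-of-domain value.
#' @return the warped [gray_volume()].
#' @export
warp_volume <- function(v, field, fill = min(v$data)) {
  stopifnot(inherits(v, "gray_volume"), inherits(field, "deformation_field"))
  d <- dim(v$data)
  out <- warp_trilinear_cpp(as.vector(v$data), d, as.vector(field$disp), fill)
  gray_volume(array(out, dim = d), spacing = v$spacing, origin = v$origin)
}

#' Warp a label map along a deformation field
#'
#' Nearest-neighbour transport: `out(x) = m(round(x + d(x)))`; out-of-domain
#' samples take `fill` (default 0, background). The label set is preserved.
#'
#' @param m a [label_map()].
#' @param field a `deformation_field` on the same grid.
#' @param fill out-of-domain label.
#' @return the warped [label_map()].
#' @export
warp_labels <- function(m, field, fill = 0L) {
  stopifnot(inherits(m, "label_map"), inherits(field, "deformation_field"))
  d <- dim(m$labels)
  out <- warp_nearest_cpp(as.vector(m$labels), d, as.vector(field$disp),
                          as.integer(fill))
  label_map(array(out, dim = d), label_set = m$label_set, spacing = m$spacing)
}

#' Sum-of-absolute-differences registration energy
#'
#' Mean over the domain of `|target(x) - source(x + d(x))|` with trilinear
#' interpolation of the warped source. With `field = NULL` the identity
#' transform is scored.
#'
#' @param target,source [gray_volume()]s on the same grid.
#' @param field optional `deformation_field`.
#' @return non-negative scalar.
#' @export
sad_energy <- function(target, source, field = NULL) {
  check_same_grid(target, source, "sad_energy: volumes")
  warped <- if (is.null(field)) source$data else warp_volume(source, field)$data
  mean(abs(target$data - warped))
}

#' Registration settings
#'
#' @param grid_spacing control-point spacing in voxels.
#' @param steps candidate displacement step sizes (voxels), coarse to fine.
#' @param passes_per_step maximum ICM passes at each step size.
#' @param lambda first-order smoothness weight on neighbouring control-point
#'   displacement differences.
#' @param stride voxel subsampling stride(s) for local energy evaluation,
#'   one per step size (recycled); coarser steps tolerate coarser sampling.
#' @param max_disp per-component displacement bound (voxels).
#' @param pre_align centre-of-mass pre-alignment on / off.
#' @param support_half half-width (in control-grid cells) of the region used
#'   to score candidate moves; the full 2-cell B-spline support is always
#'   used when applying an accepted move to the dense field.
#' @return a list of settings for [register_ffd()].
#' @export
register_config <- function(grid_spacing = 8, steps = c(4, 2, 1),
                            passes_per_step = 2L, lambda = 0.1,
                            stride = c(4L, 3L, 2L), max_disp = 10,
                            pre_align = TRUE, support_half = 1.5) {
  list(grid_spacing = grid_spacing, steps = steps,
       passes_per_step = as.integer(passes_per_step), lambda = lambda,
       stride = rep(as.integer(stride), length.out = length(steps)),
       max_disp = max_disp, pre_align = isTRUE(pre_align),
       support_half = support_half)
}

com_shift <- function(target, source) {
  com <- function(a) {
    w <- pmax(a - min(a), 0)
    s <- sum(w)
    if (s == 0) return(c(0, 0, 0))
    d <- dim(a)
    ix <- slice.index(a, 1) - 1; iy <- slice.index(a, 2) - 1; iz <- slice.index(a, 3) - 1
    c(sum(w * ix), sum(w * iy), sum(w * iz)) / s
  }
  com(source) - com(target)
}

#' Nonrigid B-spline registration of a source volume to a target
#'
#' Estimates a free-form deformation minimising the sum of absolute
#' differences between the target and the warped source. The control-point
#' displacements are optimised by deterministic discrete ICM: candidate moves
#' `current + step * {-1, 0, 1}^3` are scored by the B-spline-support-weighted
#' local SAD plus a first-order smoothness penalty, coarse-to-fine over the
#' step sizes in `cfg$steps`, with strict-improvement acceptance in fixed
#' raster order. An optional centre-of-mass pre-alignment (a uniform control
#' shift) is applied first, and only kept if it lowers the global energy.
#' The returned field's energy never exceeds the identity field's energy.
#'
#' @param target,source [gray_volume()]s on the same grid.
#' @param cfg a [register_config()].
#' @return a `deformation_field`; attribute `energy` holds
#'   `c(identity = ..., final = ...)`, attribute `flagged` is set if the
#'   optimiser could not improve on the identity.
#' @export
register_ffd <- function(target, source, cfg = register_config()) {
  check_same_grid(target, source, "register_ffd: volumes")
  d <- dim(target$data)
  grid <- control_grid(d, cfg$grid_spacing)
  e_id <- sad_energy(target, source)

  if (cfg$pre_align) {
    shift <- com_shift(target$data, source$data)
    shift <- pmax(pmin(shift, cfg$max_disp), -cfg$max_disp)
    g2 <- grid
    for (k in 1:3) g2$displacements[, , , k] <- shift[k]
    if (sad_energy(target, source, bspline_expand(g2)) < e_id) grid <- g2
  }

  nc <- dim(grid$displacements)[1:3]
  disp <- as.vector(grid$displacements)
  tg <- as.vector(target$data)
  sr <- as.vector(source$data)
  fill <- min(source$data)
  for (si in seq_along(cfg$steps)) {
    for (pass in seq_len(cfg$passes_per_step)) {
      res <- ffd_icm_pass_cpp(tg, sr, d, disp, nc, grid$spacing_vox,
                              cfg$steps[si], cfg$lambda, cfg$stride[si],
                              cfg$max_disp, fill, cfg$support_half)
      disp <- res$disp
      if (res$changes == 0L) break
    }
  }
  grid$displacements <- array(disp, dim = c(nc, 3L))
  field <- bspline_expand(grid)
  e_final <- sad_energy(target, source, field)
  flagged <- FALSE
  if (e_final > e_id) {       # fall back to the identity transform
    grid$displacements[] <- 0
    field <- bspline_expand(grid)
    e_final <- e_id
    flagged <- TRUE
  }
  attr(field, "energy") <- c(identity = e_id, final = e_final)
  if (flagged) attr(field, "flagged") <- TRUE
  field
}

#' Atlas selection by slice-wise 2-D correlation
#'
#' Averages the Pearson correlation of intensities over corresponding axial
#' slices of the target and a candidate atlas volume; the candidate is
#' selected when the mean correlation is at least `gate` (default 0.5). A
#' slice with zero variance on either side contributes r = 0.
#'
#' @param target,candidate [gray_volume()]s with equal slice counts.
#' @param gate selection threshold on the mean correlation.
#' @param mask optional logical array or [label_map()]; correlations are
#'   computed over mask voxels of each slice.
#' @return list `(mean_r, selected)`.
#' @export
atlas_gate <- function(target, candidate, gate = 0.5, mask = NULL) {
  dt <- dim(target$data); dc <- dim(candidate$data)
  if (dt[3] != dc[3])
    stop("atlas_gate: target and candidate have different slice counts")
  if (!identical(dt, dc))
    stop("atlas_gate: target and candidate have different in-plane extents")
  marr <- if (is.null(mask)) NULL else as_mask_array(mask)
  rs <- vapply(seq_len(dt[3]), function(z) {
    a <- target$data[, , z]; b <- candidate$data[, , z]
    if (!is.null(marr)) {
      keep <- marr[, , z]
      if (sum(keep) < 2L) return(0)
      a <- a[keep]; b <- b[keep]
    }
    if (sd(a) == 0 || sd(b) == 0) return(0)
    stats::cor(as.vector(a), as.vector(b))
  }, numeric(1))
  mean_r <- mean(rs)
  list(mean_r = mean_r, selected = mean_r >= gate)
}
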