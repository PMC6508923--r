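#' Specification of a synthetic dual-contrast thigh phantom
#'
#' The phantom emulates an axial thigh slab: a circular thigh cross-section
#' with a subcutaneous fat ring, a muscle body carrying thin radial
#' intermuscular fat streaks, a cortical bone ring with a bright marrow
#' core, and three angular muscle compartments (knee extensors, knee
#' flexors, medial compartment) with known labels. Geometry is constant
#' along z (a cylinder), sized to a 50-slice central slab at 1.5 mm
#' isotropic voxels. FS intensities: muscle bright, fat dark; WS swaps
#' muscle and fat; marrow (fatty) is bright on both.
#'
#' @param shape grid dimensions (voxels), default `c(96, 96, 50)`.
#' @param spacing voxel size mm, default 1.5 isotropic.
#' @param thigh_radius outer thigh radius (mm).
#' @param sat_thickness subcutaneous fat ring thickness (mm).
#' @param bone_radius outer cortical bone radius (mm); must be smaller than
#'   `thigh_radius - sat_thickness`.
#' @param marrow_radius marrow core radius (mm), inside the cortical ring.
#' @param bone_center in-plane offset (mm) of the bone axis from the thigh
#'   axis.
#' @param group_angles three angular sector boundaries (degrees) partitioning
#'   the muscle annulus into extensor / flexor / medial compartments.
#' @param imat_streaks number of radial intermuscular fat streaks.
#' @param streak_width streak width (mm).
#' @param jitter_mm atlas boundary perturbation scale (mm) used by
#'   [make_atlas_family()].
#' @param noise_sigma Gaussian noise SD as a fraction of the 0-255 dynamic
#'   range, added independently to FS and WS.
#' @param intensities per-tissue mean levels for each contrast.
#' @param seed RNG seed controlling streak placement and noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 50L), spacing = c(1.5, 1.5, 1.5),
                         thigh_radius = 60, sat_thickness = 9,
                         bone_radius = 12, marrow_radius = 7.5,
                         bone_center = c(-7.5, -4.5),
                         group_angles = c(0, 130, 240),
                         imat_streaks = 3L, streak_width = 2.25,
                         jitter_mm = 0, noise_sigma = 0.05,
                         intensities = list(
                           fs = c(background = 5, fat = 60, muscle = 190,
                                  cortical = 20, marrow = 180),
                           ws = c(background = 5, fat = 190, muscle = 60,
                                  cortical = 20, marrow = 180)),
                         seed = 1L) {
  if (!(bone_radius < thigh_radius - sat_thickness))
    stop("phantom_spec: bone_radius must be smaller than thigh_radius - sat_thickness")
  if (marrow_radius >= bone_radius)
    stop("phantom_spec: marrow_radius must be smaller than bone_radius")
  if (length(group_angles) != 3L || is.unsorted(group_angles) ||
      any(group_angles < 0) || any(group_angles >= 360))
    stop("phantom_spec: group_angles must be three increasing angles in [0, 360)")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 thigh_radius = thigh_radius, sat_thickness = sat_thickness,
                 bone_radius = bone_radius, marrow_radius = marrow_radius,
                 bone_center = bone_center, group_angles = group_angles,
                 imat_streaks = as.integer(imat_streaks),
                 streak_width = streak_width, jitter_mm = jitter_mm,
                 noise_sigma = noise_sigma, intensities = intensities,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# tissue codes used internally for warping the ground truth as one map
PH_BG <- 0L; PH_SAT <- 1L; PH_MUSCLE <- 2L; PH_IMAT <- 3L; PH_CORT <- 4L; PH_MARROW <- 5L

# clean (noise-free) phantom: tissue code volume + group label volume
phantom_geometry <- function(spec, streak_angles) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dx <- spec$spacing[1]; dy <- spec$spacing[2]
  xm <- (seq_len(nx) - 1 - (nx - 1) / 2) * dx
  ym <- (seq_len(ny) - 1 - (ny - 1) / 2) * dy
  X <- matrix(xm, nx, ny); Y <- matrix(ym, nx, ny, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  rb <- sqrt((X - spec$bone_center[1])^2 + (Y - spec$bone_center[2])^2)

  tis <- matrix(PH_BG, nx, ny)
  inner <- spec$thigh_radius - spec$sat_thickness
  tis[r <= spec$thigh_radius] <- PH_SAT
  tis[r <= inner] <- PH_MUSCLE
  # radial IMAT streaks through the muscle body
  if (spec$imat_streaks > 0L) {
    r0 <- spec$bone_radius + 3; r1 <- inner - 1.5
    for (th in streak_angles) {
      u <- c(cos(th), sin(th))
      along <- X * u[1] + Y * u[2]
      perp <- abs(X * u[2] - Y * u[1])
      hit <- tis == PH_MUSCLE & along > 0 & r >= r0 & r <= r1 &
        perp <= spec$streak_width / 2
      tis[hit] <- PH_IMAT
    }
  }
  tis[rb <= spec$bone_radius & r <= inner] <- PH_CORT
  tis[rb <= spec$marrow_radius & r <= inner] <- PH_MARROW

  theta <- (atan2(Y, X) * 180 / pi) %% 360
  ga <- spec$group_angles
  grp <- matrix(0L, nx, ny)
  grp[theta >= ga[1] & theta < ga[2]] <- 1L
  grp[theta >= ga[2] & theta < ga[3]] <- 2L
  grp[theta >= ga[3] | theta < ga[1]] <- 3L
  grp[tis != PH_MUSCLE] <- 0L

  list(tissue = array(rep(tis, nz), dim = c(nx, ny, nz)),
       groups = array(rep(grp, nz), dim = c(nx, ny, nz)))
}

phantom_intensity <- function(tissue, levels) {
  lut <- c(levels[["background"]], levels[["fat"]], levels[["muscle"]],
           levels[["fat"]], levels[["cortical"]], levels[["marrow"]])
  array(lut[tissue + 1L], dim = dim(tissue))
}

phantom_case_from_codes <- function(tissue, groups, spec, noise_seed = NULL) {
  fs <- phantom_intensity(tissue, spec$intensities$fs)
  ws <- phantom_intensity(tissue, spec$intensities$ws)
  if (spec$noise_sigma > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    sdv <- spec$noise_sigma * 255
    fs <- fs + array(rnorm(length(fs), sd = sdv), dim = dim(fs))
    ws <- ws + array(rnorm(length(ws), sd = sdv), dim = dim(ws))
  }
  sp <- spec$spacing
  masks <- list(
    thigh = mask_to_map(tissue != PH_BG, sp),
    bone = mask_to_map(tissue == PH_CORT | tissue == PH_MARROW, sp),
    muscle = mask_to_map(tissue == PH_MUSCLE, sp),
    sat = mask_to_map(tissue == PH_SAT, sp),
    imat = mask_to_map(tissue == PH_IMAT, sp))
  counts <- vapply(masks, function(m) sum(m$labels), numeric(1))
  structure(list(
    fs = gray_volume(fs, spacing = sp),
    ws = gray_volume(ws, spacing = sp),
    truth_tissues = structure(c(masks, list(counts = counts)),
                              class = "tissue_masks"),
    truth_groups = label_map(groups, label_set = 0:3, spacing = sp),
    tissue_codes = tissue,
    spec = spec), class = "phantom_case")
}

#' Generate a synthetic dual-contrast thigh phantom
#'
#' Deterministic given `spec$seed`: streak placement and the Gaussian noise
#' are drawn from a seeded stream, so the same spec always yields
#' bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_case` with fields `fs`, `ws`
#'   ([gray_volume()]s), `truth_tissues` (`tissue_masks`), `truth_groups`
#'   ([label_map()] with labels background/extensor/flexor/medial = 0:3),
#'   and the generating `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  streak_angles <- if (spec$imat_streaks > 0L)
    sort(stats::runif(spec$imat_streaks, 0, 2 * pi)) else numeric(0)
  geo <- phantom_geometry(spec, streak_angles)
  phantom_case_from_codes(geo$tissue, geo$groups, spec, noise_seed = NULL)
}

# random smooth B-spline warp used for atlas jitter
random_jitter_grid <- function(shape, jitter_vox, grid_spacing = 16) {
  grid <- control_grid(shape, grid_spacing)
  nc <- dim(grid$displacements)
  disp <- rnorm(prod(nc), sd = jitter_vox)
  disp <- pmax(pmin(disp, 2.5 * jitter_vox), -2.5 * jitter_vox)
  grid$displacements <- array(disp, dim = nc)
  grid
}

#' Generate a family of jittered atlas phantoms
#'
#' `n` phantoms sharing the base topology, each deformed by an independent
#' random smooth B-spline warp of scale `spec$jitter_mm` applied jointly to
#' both contrast volumes and the ground-truth labels (so truth stays
#' consistent with the images), with noise added after warping. Seeds are
#' derived from `spec$seed`; with `jitter_mm = 0` every member equals the
#' base phantom.
#'
#' @param spec a [phantom_spec()].
#' @param n number of family members (>= 1).
#' @return list of `phantom_case` objects.
#' @export
make_atlas_family <- function(spec = phantom_spec(), n = 6L) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1L)
  set.seed(spec$seed)
  streak_angles <- if (spec$imat_streaks > 0L)
    sort(stats::runif(spec$imat_streaks, 0, 2 * pi)) else numeric(0)
  geo <- phantom_geometry(spec, streak_angles)
  jitter_vox <- spec$jitter_mm / mean(spec$spacing[1:2])
  lapply(seq_len(n), function(i) {
    member_seed <- (spec$seed * 131L + i * 977L) %% 2147483647L
    if (jitter_vox > 0) {
      set.seed(member_seed)
      grid <- random_jitter_grid(spec$shape, jitter_vox)
      field <- bspline_expand(grid)
      d <- spec$shape
      # edge-clamped sampling: the phantom is a cylinder, so slab ends
      # continue their boundary slice instead of filling with background
      tis <- array(warp_nearest_cpp(as.vector(geo$tissue), d,
                                    as.vector(field$disp), PH_BG, clamp = TRUE),
                   dim = d)
      grp <- array(warp_nearest_cpp(as.vector(geo$groups), d,
                                    as.vector(field$disp), 0L, clamp = TRUE),
                   dim = d)
      grp[tis != PH_MUSCLE] <- 0L
    } else {
      tis <- geo$tissue; grp <- geo$groups
    }
    phantom_case_from_codes(tis, grp, spec, noise_seed = member_seed + 1L)
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", paste(dim(x$fs$data), collapse = " x "),
      " voxels; tissue voxel counts:\n", sep = "")
  print(x$truth_tissues$counts)
  invisible(x)
}
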