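#' @useDynLib thighseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm dnorm pnorm quantile sd
NULL

#' Construct a gray-scale volume
#'
#' A `gray_volume` is the package's container for a 3-D scalar image: a numeric
#' array plus voxel spacing (mm) and a physical origin (mm). All geometric
#' computations (Hausdorff distances, volumes) use the spacing; voxel indices
#' are treated as 0-based (x, y, z) with z the slice axis.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, physical offset in mm.
#' @return an object of class `gray_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
gray_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("gray_volume: 'data' must be a 3-D array with each axis of length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("gray_volume: 'spacing' must be 3 strictly positive values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "gray_volume")
}

#' Construct a label map
#'
#' A `label_map` holds a 3-D array of small non-negative integer labels over
#' the same grid as a paired [gray_volume()], plus the ordered set of allowed
#' label ids (optionally named).
#'
#' @param labels 3-D integer array.
#' @param label_set integer vector of allowed label ids, optionally named
#'   (e.g. `c(background = 0, extensor = 1, flexor = 2, medial = 3)`).
#' @param spacing voxel size in mm.
#' @return object of class `label_map`.
#' @export
label_map <- function(labels, label_set = sort(unique(as.integer(labels))),
                      spacing = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("label_map: 'labels' must be a 3-D array")
  storage.mode(labels) <- "integer"
  label_set <- as.integer(label_set)
  if (!all(unique(as.vector(labels)) %in% label_set))
    stop("label_map: voxel values outside 'label_set'")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("label_map: 'spacing' must be 3 strictly positive values (mm)")
  structure(list(labels = labels, label_set = label_set, spacing = spacing),
            class = "label_map")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat("<gray_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "), " mm\n",
      "  intensity range [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(x$label_set, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

check_same_grid <- function(a, b, what = "volumes") {
  da <- if (inherits(a, "gray_volume")) dim(a$data) else dim(a$labels)
  db <- if (inherits(b, "gray_volume")) dim(b$data) else dim(b$labels)
  if (!identical(da, db))
    stop(sprintf("%s have mismatched shapes (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  sa <- a$spacing; sb <- b$spacing
  if (max(abs(sa - sb)) > 1e-9)
    stop(sprintf("%s have mismatched voxel spacing", what))
  invisible(TRUE)
}

#' Read a volume from a NIfTI file
#'
#' Spacing is taken from the file header (`pixdim`); intensities are returned
#' unmodified. Gzip-compressed files are accepted.
#'
#' @param path path to a 3-D NIfTI file (`.nii` or `.nii.gz`).
#' @return a [gray_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_volume: file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("read_volume: cannot read '%s': %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop(sprintf("read_volume: '%s' is not a 3-D volume (found %d axes)",
                 path, length(dim(arr))))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop(sprintf("read_volume: '%s' lacks valid voxel spacing metadata", path))
  org <- tryCatch(-RNifti::origin(img), error = function(e) c(0, 0, 0))
  gray_volume(arr, spacing = sp, origin = as.numeric(org)[1:3])
}

#' Write a volume to a NIfTI file
#'
#' @param v a [gray_volume()] or [label_map()]; label maps are written as
#'   integer-typed volumes.
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "label_map")) {
    arr <- v$labels
    attr(arr, "pixdim") <- v$spacing
    img <- RNifti::asNifti(arr, datatype = "int32")
  } else if (inherits(v, "gray_volume")) {
    arr <- v$data
    attr(arr, "pixdim") <- v$spacing
    img <- RNifti::asNifti(arr)
  } else stop("write_volume: expected a gray_volume or label_map")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from a NIfTI file
#'
#' @param path NIfTI file of integer labels.
#' @param label_set optional label id vector; defaults to the values present.
#' @return a [label_map()].
#' @export
read_label_map <- function(path, label_set = NULL) {
  v <- read_volume(path)
  lab <- round(v$data)
  if (max(abs(lab - v$data)) > 1e-6)
    stop(sprintf("read_label_map: '%s' contains non-integer values", path))
  if (is.null(label_set)) label_set <- sort(unique(as.integer(lab)))
  label_map(lab, label_set = label_set, spacing = v$spacing)
}

#' Rescale intensities to integer gray levels
#'
#' Affinely maps intensities to integers in `[0, levels - 1]`: the input
#' minimum maps to 0 and the maximum to `levels - 1`, with half-up rounding.
#' A constant volume maps to all zeros. The quantised scale is the domain of
#' the LCDG density model (default Q = 256 gray levels).
#'
#' @param v a [gray_volume()].
#' @param levels number of gray levels Q (>= 2).
#' @return a [gray_volume()] with integer-valued data in `[0, levels - 1]`.
#' @export
rescale_intensities <- function(v, levels = 256L) {
  stopifnot(inherits(v, "gray_volume"))
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("rescale_intensities: 'levels' must be an integer >= 2")
  rng <- range(v$data)
  if (rng[2] - rng[1] <= 0) {
    out <- array(0, dim = dim(v$data))
  } else {
    scaled <- (v$data - rng[1]) / (rng[2] - rng[1]) * (levels - 1)
    out <- floor(scaled + 0.5)  # half-up rounding
  }
  gray_volume(out, spacing = v$spacing, origin = v$origin)
}

#' Crop an axial slab and an in-plane box
#'
#' Restricts a volume to axial slices `[lo, hi)` (0-based, half-open) and an
#' in-plane bounding box, e.g. to keep the central slab of one thigh. Spacing
#' is preserved. `side = "left"`/`"right"` is a convenience that splits the
#' in-plane field of view at the x midline.
#'
#' @param v a [gray_volume()] or [label_map()].
#' @param slice_range integer length-2 `(lo, hi)`, 0-based half-open on z.
#' @param side optional `"left"` or `"right"` half of the x axis.
#' @param crop_box optional list with 0-based inclusive in-plane bounds
#'   `x = c(x0, x1)`, `y = c(y0, y1)`; overrides `side` on x if both given.
#' @return the cropped object, same class as `v`, with attribute `offset`
#'   recording the 0-based (x, y, z) origin of the crop within the input grid.
#' @export
crop_slab_and_side <- function(v, slice_range, side = NULL, crop_box = NULL) {
  arr <- if (inherits(v, "label_map")) v$labels else v$data
  d <- dim(arr)
  lo <- as.integer(slice_range[1]); hi <- as.integer(slice_range[2])
  if (lo < 0L || hi > d[3] || lo >= hi)
    stop(sprintf("crop_slab_and_side: slice_range (%d, %d) out of range for %d slices",
                 lo, hi, d[3]))
  xr <- c(0L, d[1] - 1L); yr <- c(0L, d[2] - 1L)
  if (!is.null(side)) {
    side <- match.arg(side, c("left", "right"))
    half <- d[1] %/% 2L
    xr <- if (side == "left") c(0L, half - 1L) else c(half, d[1] - 1L)
  }
  if (!is.null(crop_box)) {
    if (!is.null(crop_box$x)) xr <- as.integer(crop_box$x)
    if (!is.null(crop_box$y)) yr <- as.integer(crop_box$y)
  }
  if (xr[1] < 0L || xr[2] >= d[1] || xr[1] > xr[2] ||
      yr[1] < 0L || yr[2] >= d[2] || yr[1] > yr[2])
    stop("crop_slab_and_side: crop box outside the in-plane extent")
  sub <- arr[(xr[1] + 1L):(xr[2] + 1L), (yr[1] + 1L):(yr[2] + 1L),
             (lo + 1L):hi, drop = FALSE]
  out <- if (inherits(v, "label_map"))
    label_map(sub, label_set = v$label_set, spacing = v$spacing)
  else gray_volume(sub, spacing = v$spacing, origin = v$origin)
  attr(out, "offset") <- c(xr[1], yr[1], lo)
  out
}

#' Voxel-wise sum of two volumes
#'
#' Used to form the FS + WS volume in which every thigh tissue is bright
#' (each tissue class is bright in exactly one of the two contrasts), so the
#' whole-thigh mask and the bone can be extracted by a single 2-class split.
#'
#' @param a,b [gray_volume()]s on the same grid with the same spacing.
#' @return their voxel-wise sum as a [gray_volume()].
#' @export
sum_volumes <- function(a, b) {
  stopifnot(inherits(a, "gray_volume"), inherits(b, "gray_volume"))
  check_same_grid(a, b, "sum_volumes: volumes")
  gray_volume(a$data + b$data, spacing = a$spacing, origin = a$origin)
}

# internal: binary mask array from label_map or logical array
as_mask_array <- function(m) {
  if (inherits(m, "label_map")) m$labels > 0L
  else if (is.logical(m)) m
  else m > 0
}
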