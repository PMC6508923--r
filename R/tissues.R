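# --- binary 3-D morphology wrappers (26-connectivity) ------------------------

mask_dim <- function(m) dim(m)

#' Connected components of a binary mask
#'
#' 26-connected component labelling.
#'
#' @param mask logical 3-D array.
#' @return integer array of component ids (0 = background).
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  array(cc_label_26_cpp(as.vector(mask), d), dim = d)
}

largest_component <- function(mask) {
  cc <- connected_components(mask)
  if (max(cc) == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(cc[cc > 0L])
  cc == which.max(sizes)
}

fill_holes_slices <- function(mask) {
  d <- dim(mask)
  array(fill_holes_slices_cpp(as.vector(mask), d), dim = d)
}

fill_holes_3d <- function(mask) {
  d <- dim(mask)
  array(fill_holes_3d_cpp(as.vector(mask), d), dim = d)
}

dilate_ball <- function(mask, radius) {
  d <- dim(mask)
  array(dilate_ball_cpp(as.vector(mask), d, radius), dim = d)
}

erode_ball <- function(mask, radius) {
  d <- dim(mask)
  array(erode_ball_cpp(as.vector(mask), d, radius), dim = d)
}

close_ball <- function(mask, radius) erode_ball(dilate_ball(mask, radius), radius)

mask_to_map <- function(mask, spacing) {
  label_map(array(as.integer(mask), dim = dim(mask)), label_set = c(0L, 1L),
            spacing = spacing)
}

# --- tissue extraction (whole thigh, bone, muscle, SAT / IMAT) ---------------

#' Segment the whole thigh and the bone from the FS + WS volume
#'
#' In the summed FS + WS volume every soft tissue is bright (each tissue class
#' is bright in exactly one contrast) while background and cortical bone stay
#' dark, so a single LCDG 2-class split extracts the thigh: the largest
#' 26-connected light component with its holes filled (slice-wise). Cortical
#' bone is then recovered as the dark component(s) fully enclosed by the thigh
#' interior, the bright marrow core as the cavity they enclose, and the bone
#' mask as their morphological closing (3-voxel ball).
#'
#' @param fs,ws fat-suppressed and water-suppressed [gray_volume()]s on the
#'   same grid.
#' @param levels gray levels Q for the LCDG fit.
#' @param min_size minimum voxel count of the thigh component.
#' @param bone_min_size minimum voxel count of a cortical-bone component.
#' @return list with binary [label_map()]s `thigh` and `bone`, plus the
#'   fitted `lcdg_model`. If no enclosed dark component exists, `bone` is
#'   empty and carries attribute `flagged = TRUE`.
#' @export
segment_thigh_and_bone <- function(fs, ws, levels = 256L, min_size = 1000L,
                                   bone_min_size = 100L) {
  check_same_grid(fs, ws, "segment_thigh_and_bone: FS and WS")
  s <- rescale_intensities(sum_volumes(fs, ws), levels)
  model <- fit_lcdg(empirical_histogram(s, levels = levels))
  light <- as_mask_array(binarize(s, model))
  thigh0 <- largest_component(light)
  if (sum(thigh0) < min_size)
    stop(sprintf("segment_thigh_and_bone: largest light component has %d voxels (< %d)",
                 sum(thigh0), min_size))
  thigh <- fill_holes_slices(thigh0)

  dark <- thigh & !light
  bone_mask <- array(FALSE, dim(dark))
  flagged <- TRUE
  cc <- connected_components(dark)
  if (max(cc) > 0L) {
    # a component is cortical bone if none of its voxels touches non-thigh
    touch <- array(touches_cpp(as.vector(dark), as.vector(!thigh), dim(dark)),
                   dim = dim(dark))
    sizes <- tabulate(cc[cc > 0L])
    touching_ids <- unique(cc[touch])
    cortical_ids <- setdiff(which(sizes >= bone_min_size), touching_ids)
    if (length(cortical_ids)) {
      cortical <- array(cc %in% cortical_ids, dim = dim(cc))
      marrow <- fill_holes_slices(cortical) & !cortical & thigh
      bone_mask <- close_ball(cortical | marrow, 3) & thigh
      flagged <- FALSE
    }
  }
  bone <- mask_to_map(bone_mask, fs$spacing)
  if (flagged) attr(bone, "flagged") <- TRUE
  list(thigh = mask_to_map(thigh, fs$spacing), bone = bone, model = model)
}

#' Segment total muscle from the FS volume
#'
#' The light LCDG class of the fat-suppressed volume within the thigh mask
#' (muscle and marrow are bright on FS, fat dark), minus the bone mask.
#'
#' @param fs fat-suppressed [gray_volume()].
#' @param thigh binary thigh [label_map()].
#' @param bone optional binary bone [label_map()] to subtract.
#' @param levels gray levels Q.
#' @return list with the binary `muscle` [label_map()] and the `lcdg_model`.
#' @export
segment_muscle <- function(fs, thigh, bone = NULL, levels = 256L) {
  fsq <- rescale_intensities(fs, levels)
  thigh_arr <- as_mask_array(thigh)
  model <- fit_lcdg(empirical_histogram(fsq, mask = thigh_arr, levels = levels))
  light <- as_mask_array(binarize(fsq, model))
  muscle <- light & thigh_arr
  if (!is.null(bone)) muscle <- muscle & !as_mask_array(bone)
  list(muscle = mask_to_map(muscle, fs$spacing), model = model)
}

#' Segment total fat from the WS volume and split SAT from IMAT
#'
#' The light LCDG class of the water-suppressed volume within the thigh mask
#' is total fat. The muscle mask is overlaid to split it: fat inside the
#' filled morphological closing of the muscle mask (the muscle envelope, a
#' proxy for the fascia lata) is intermuscular adipose tissue (IMAT); fat
#' outside it is subcutaneous adipose tissue (SAT).
#'
#' @param ws water-suppressed [gray_volume()].
#' @param thigh,muscle binary [label_map()]s.
#' @param bone optional binary bone [label_map()] to exclude (marrow is
#'   bright on WS).
#' @param levels gray levels Q.
#' @param envelope_radius closing-ball radius (voxels) of the muscle envelope.
#' @return list with binary `sat` and `imat` [label_map()]s and the
#'   `lcdg_model`. If the fat class is empty, both masks are empty and carry
#'   attribute `flagged = TRUE`.
#' @export
segment_fat_and_split <- function(ws, thigh, muscle, bone = NULL,
                                  levels = 256L, envelope_radius = 5) {
  wsq <- rescale_intensities(ws, levels)
  thigh_arr <- as_mask_array(thigh)
  muscle_arr <- as_mask_array(muscle)
  model <- fit_lcdg(empirical_histogram(wsq, mask = thigh_arr, levels = levels))
  fat <- as_mask_array(binarize(wsq, model)) & thigh_arr & !muscle_arr
  if (!is.null(bone)) fat <- fat & !as_mask_array(bone)
  flagged <- !any(fat)
  envelope <- fill_holes_slices(close_ball(muscle_arr, envelope_radius))
  sat <- mask_to_map(fat & !envelope, ws$spacing)
  imat <- mask_to_map(fat & envelope, ws$spacing)
  if (flagged) { attr(sat, "flagged") <- TRUE; attr(imat, "flagged") <- TRUE }
  list(sat = sat, imat = imat, model = model)
}

#' Extract all thigh tissue masks from an FS / WS pair
#'
#' Composes [segment_thigh_and_bone()], [segment_muscle()] and
#' [segment_fat_and_split()] into the full first-stage tissue extraction:
#' whole thigh, bone (cortical + marrow), total muscle, SAT and IMAT. The
#' returned masks are pairwise disjoint (muscle, sat, imat, bone) and
#' contained in the thigh.
#'
#' @param fs,ws the two contrast [gray_volume()]s.
#' @param levels gray levels Q.
#' @param min_size minimum thigh component size in voxels.
#' @param envelope_radius muscle-envelope closing radius in voxels.
#' @return object of class `tissue_masks`: binary [label_map()]s `thigh`,
#'   `bone`, `muscle`, `sat`, `imat` and a `counts` vector of voxel counts.
#' @export
segment_tissues <- function(fs, ws, levels = 256L, min_size = 1000L,
                            envelope_radius = 5) {
  tb <- segment_thigh_and_bone(fs, ws, levels = levels, min_size = min_size)
  mu <- segment_muscle(fs, tb$thigh, bone = tb$bone, levels = levels)
  fsp <- segment_fat_and_split(ws, tb$thigh, mu$muscle, bone = tb$bone,
                               levels = levels, envelope_radius = envelope_radius)
  masks <- list(thigh = tb$thigh, bone = tb$bone, muscle = mu$muscle,
                sat = fsp$sat, imat = fsp$imat)
  counts <- vapply(masks, function(m) sum(m$labels), numeric(1))
  structure(c(masks, list(counts = counts)), class = "tissue_masks")
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat("<tissue_masks> voxel counts:\n")
  print(x$counts)
  invisible(x)
}
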