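#' Voxel-wise confusion counts between two binary masks
#'
#' Counts true/false positives/negatives over the full grid.
#'
#' @param pred,truth binary [label_map()]s or logical arrays on the same grid.
#' @return object of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  p <- as_mask_array(pred); t <- as_mask_array(truth)
  if (!identical(dim(p), dim(t)))
    stop("confusion: prediction and truth are on different grids")
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Dice coefficient, precision and recall
#'
#' `DC = 2TP / (FP + 2TP + FN)`, `P = TP / (TP + FP)`, `R = TP / (TP + FN)`.
#' If both masks are empty all three are defined as 1 (with a warning from
#' the calling metric when relevant); if only the denominator of a ratio is
#' zero that ratio is 0.
#'
#' @param c a `confusion_counts` (or a list with tp/fp/fn fields).
#' @return list `(dice, precision, recall)`.
#' @export
dice_precision_recall <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fp + fn == 0) return(list(dice = 1, precision = 1, recall = 1))
  list(dice = 2 * tp / (fp + 2 * tp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Dice coefficient of two binary masks
#'
#' Convenience wrapper around [confusion()] and [dice_precision_recall()].
#'
#' @param pred,truth binary masks on the same grid.
#' @return scalar Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth) dice_precision_recall(confusion(pred, truth))$dice

#' Symmetric Hausdorff distance between two masks (mm)
#'
#' The boundary voxels of each mask (positive voxels with a 6-connected
#' negative neighbour or lying on the grid edge) are taken as the two point
#' sets; the Hausdorff distance is the larger of the two directed farthest
#' nearest-neighbour distances, with Euclidean distance computed in physical
#' millimetres using the voxel spacing.
#'
#' @param pred,truth binary [label_map()]s (or logical arrays, in which case
#'   `spacing` must be supplied).
#' @param spacing voxel spacing in mm; taken from `pred` when it is a
#'   [label_map()].
#' @return Hausdorff distance in mm. Both masks empty: 0 with a warning;
#'   exactly one empty: an error naming the empty side.
#' @export
hausdorff <- function(pred, truth, spacing = NULL) {
  p <- as_mask_array(pred); t <- as_mask_array(truth)
  if (!identical(dim(p), dim(t)))
    stop("hausdorff: masks are on different grids")
  if (is.null(spacing)) {
    if (inherits(pred, "label_map")) spacing <- pred$spacing
    else stop("hausdorff: spacing required when masks are plain arrays")
  }
  pe <- !any(p); te <- !any(t)
  if (pe && te) { warning("hausdorff: both masks empty; distance defined as 0"); return(0) }
  if (pe) stop("hausdorff: the prediction mask is empty")
  if (te) stop("hausdorff: the truth mask is empty")
  d <- dim(p)
  bp <- array(boundary_6_cpp(as.vector(p), d), dim = d)
  bt <- array(boundary_6_cpp(as.vector(t), d), dim = d)
  coords <- function(b) {
    w <- which(b, arr.ind = TRUE) - 1L
    sweep(w, 2L, spacing, `*`)
  }
  hausdorff_points_cpp(coords(bp), coords(bt))
}

#' Volume of a binary mask
#'
#' Voxel count times the voxel volume `dx * dy * dz` (mm^3), also reported in
#' millilitres. Additive over disjoint masks.
#'
#' @param mask a binary [label_map()] (or logical array with `spacing`).
#' @param spacing voxel spacing in mm when `mask` is a plain array.
#' @return list `(voxels, mm3, ml)`.
#' @export
volume_ml <- function(mask, spacing = NULL) {
  m <- as_mask_array(mask)
  if (is.null(spacing)) {
    if (inherits(mask, "label_map")) spacing <- mask$spacing
    else stop("volume_ml: spacing required when mask is a plain array")
  }
  n <- sum(m)
  mm3 <- n * prod(spacing)
  list(voxels = n, mm3 = mm3, ml = mm3 / 1000)
}

#' Per-label segmentation accuracy report
#'
#' Compares a predicted multi-label map against a ground-truth map label by
#' label, producing the Dice coefficient, precision, recall and Hausdorff
#' distance for each requested label.
#'
#' @param pred,truth [label_map()]s on the same grid.
#' @param labels integer label ids to evaluate (default: all non-background
#'   labels of the truth).
#' @return data.frame with columns `label`, `dice`, `precision`, `recall`,
#'   `hausdorff_mm`.
#' @export
evaluate_labels <- function(pred, truth,
                            labels = setdiff(truth$label_set, 0L)) {
  stopifnot(inherits(pred, "label_map"), inherits(truth, "label_map"))
  check_same_grid(pred, truth, "evaluate_labels: maps")
  rows <- lapply(labels, function(l) {
    p <- pred$labels == l; t <- truth$labels == l
    dpr <- dice_precision_recall(confusion(p, t))
    hd <- if (any(p) && any(t)) hausdorff(p, t, spacing = truth$spacing) else NA_real_
    data.frame(label = l, dice = dpr$dice, precision = dpr$precision,
               recall = dpr$recall, hausdorff_mm = hd)
  })
  do.call(rbind, rows)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
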