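#' Build the probabilistic shape prior from an atlas set
#'
#' For a test subject, each candidate atlas (a gray volume with its 4-label
#' ground-truth map: background + extensor + flexor + medial) is screened by
#' [atlas_gate()]; the selected atlases are registered to the target with
#' [register_ffd()] and their label maps transported by nearest-neighbour
#' warping. The prior at voxel v and label l is the Laplace-smoothed vote
#' fraction `(count_l(v) + alpha) / (n_selected + alpha * L)`. Outside the
#' optional domain mask the background label has probability 1.
#'
#' @param target [gray_volume()] of the test subject (any intensity scale;
#'   rescaled internally).
#' @param atlases list of atlases, each a list with elements `volume`
#'   ([gray_volume()]) and `labels` ([label_map()] on the 4-label set).
#' @param mask optional logical array or [label_map()] restricting the prior
#'   domain (typically the total muscle mask).
#' @param alpha Laplace smoothing count (default 0.5) so no voxel-label pair
#'   has probability exactly 0.
#' @param gate atlas-selection threshold on the mean slice correlation.
#' @param cfg [register_config()] used for the atlas registrations.
#' @param levels gray levels used for rescaling before gating/registration.
#' @return object of class `shape_prior`: `probs` (nx x ny x nz x L array,
#'   summing to 1 over labels at every voxel), `label_set`, `mask`,
#'   `n_selected`, `gate_r` (mean correlation per atlas), `spacing`.
#' @export
build_prior <- function(target, atlases, mask = NULL, alpha = 0.5, gate = 0.5,
                        cfg = register_config(), levels = 256L) {
  stopifnot(inherits(target, "gray_volume"), length(atlases) >= 1L)
  tq <- rescale_intensities(target, levels)
  d <- dim(target$data)
  label_set <- atlases[[1]]$labels$label_set
  L <- length(label_set)
  marr <- if (is.null(mask)) array(TRUE, d) else as_mask_array(mask)

  gate_r <- numeric(length(atlases))
  warped <- list()
  for (i in seq_along(atlases)) {
    a <- atlases[[i]]
    if (!identical(a$labels$label_set, label_set))
      stop("build_prior: atlases disagree on the label set")
    aq <- rescale_intensities(a$volume, levels)
    g <- atlas_gate(tq, aq, gate = gate)
    gate_r[i] <- g$mean_r
    if (!g$selected) next
    field <- register_ffd(tq, aq, cfg)
    warped[[length(warped) + 1L]] <- warp_labels(a$labels, field)
  }
  n_sel <- length(warped)
  if (n_sel == 0L)
    stop("build_prior: no atlas passed the correlation gate; lower the gate or add atlases")

  nvox <- prod(d)
  votes <- matrix(0, nrow = nvox, ncol = L)
  for (w in warped) {
    idx <- match(as.vector(w$labels), label_set)
    votes[cbind(seq_len(nvox), idx)] <- votes[cbind(seq_len(nvox), idx)] + 1
  }
  probs <- (votes + alpha) / (n_sel + alpha * L)
  # outside the domain mask: background with certainty
  out <- !as.vector(marr)
  if (any(out)) {
    bg <- which(label_set == 0L)
    if (length(bg) != 1L) bg <- 1L
    probs[out, ] <- 0
    probs[out, bg] <- 1
  }
  structure(list(probs = array(probs, dim = c(d, L)), label_set = label_set,
                 mask = marr, n_selected = n_sel, gate_r = gate_r,
                 spacing = target$spacing),
            class = "shape_prior")
}

#' Log-probability of a label map under a shape prior
#'
#' The prior factorises over voxels, so the log-probability is the sum over
#' voxels of the log prior probability of the map's label there. A
#' zero-probability assignment yields `-Inf` with attribute `flagged`.
#'
#' @param prior a `shape_prior`.
#' @param m a [label_map()] on the prior's grid and label set.
#' @return scalar log-probability.
#' @export
prior_log_prob <- function(prior, m) {
  stopifnot(inherits(prior, "shape_prior"), inherits(m, "label_map"))
  d <- dim(m$labels)
  if (!identical(as.integer(d), as.integer(dim(prior$probs)[1:3])))
    stop("prior_log_prob: map grid does not match the prior")
  idx <- match(as.vector(m$labels), prior$label_set)
  if (anyNA(idx)) stop("prior_log_prob: map contains labels outside the prior's label set")
  nvox <- prod(d)
  p <- as.vector(prior$probs)[seq_len(nvox) + (idx - 1L) * nvox]
  lp <- sum(log(p))
  if (!is.finite(lp)) attr(lp, "flagged") <- TRUE
  lp
}

#' @export
print.shape_prior <- function(x, ...) {
  cat("<shape_prior> ", paste(dim(x$probs)[1:3], collapse = " x "),
      " voxels x ", dim(x$probs)[4], " labels; built from ", x$n_selected,
      " atlas(es)\n", sep = "")
  invisible(x)
}
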