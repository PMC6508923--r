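# --- per-label intensity models ----------------------------------------------

# Fit a conditional intensity density for one label from the gray levels of
# its voxels, using a small LCDG (2 dominant + n_add additive + n_sub
# subtractive DGs; each muscle group is near-unimodal so a small model is
# stable on small classes). Degenerate inputs (single occupied level) get a
# narrow DG at that level.
fit_label_density <- function(glev, Q, n_add = 2L, n_sub = 2L) {
  if (length(glev) == 0L) return(NULL)
  counts <- tabulate(as.integer(glev) + 1L, nbins = Q)
  if (sum(counts > 0L) < 2L) {
    lvl <- which(counts > 0L)[1] - 1L
    d <- dg_probs(Q, lvl, 0.5)
    return(d / sum(d))
  }
  h <- structure(list(counts = counts, empirical = counts / sum(counts),
                      levels = Q), class = "gray_histogram")
  fit_lcdg(h, n_add = n_add, n_sub = n_sub)$density
}

# L x Q matrix of per-label intensity densities estimated from the voxels
# currently assigned to each label inside the mask. Labels with no voxels
# fall back to the previous sweep's density (or uniform), flagged.
class_intensity_models <- function(fsq, labels, mask, label_set, Q,
                                   n_add = 2L, n_sub = 2L, prev = NULL) {
  L <- length(label_set)
  dens <- matrix(1 / Q, nrow = L, ncol = Q)
  flagged <- logical(L)
  for (k in seq_len(L)) {
    g <- fsq[mask & labels == label_set[k]]
    dk <- fit_label_density(g, Q, n_add, n_sub)
    if (is.null(dk)) {
      flagged[k] <- TRUE
      if (!is.null(prev)) dens[k, ] <- prev[k, ]
    } else dens[k, ] <- dk
  }
  list(densities = dens, flagged = flagged)
}

#' Fusion (joint MGRF) settings
#'
#' @param max_sweeps maximum ICM sweeps.
#' @param tol_frac stop when the fraction of relabelled mask voxels in a
#'   sweep falls below this.
#' @param n_add,n_sub subordinate DG counts for the per-label intensity
#'   models.
#' @param levels gray levels Q.
#' @param freeze_models if TRUE the Potts potential and intensity models are
#'   estimated once from the initial map and never re-estimated (gives the
#'   strict ICM monotonicity guarantee on the objective trace).
#' @param exponents weights (log-domain multipliers) of the three fused
#'   probabilities, `c(shape, spatial, intensity)`; default all 1 (plain
#'   product).
#' @return settings list for [icm_refine()].
#' @export
fusion_config <- function(max_sweeps = 20L, tol_frac = 1e-4, n_add = 2L,
                          n_sub = 2L, levels = 256L, freeze_models = FALSE,
                          exponents = c(shape = 1, spatial = 1, intensity = 1)) {
  list(max_sweeps = as.integer(max_sweeps), tol_frac = tol_frac,
       n_add = as.integer(n_add), n_sub = as.integer(n_sub),
       levels = as.integer(levels), freeze_models = isTRUE(freeze_models),
       exponents = exponents)
}

#' Initial region map from shape prior and intensity models
#'
#' Each voxel of the prior's domain mask takes the label maximising
#' `prior(l) * intensity(l | gray level)`; voxels outside the mask are
#' background. Ties go to the lowest label id.
#'
#' @param prior a `shape_prior`.
#' @param intensity L x Q matrix of per-label intensity densities (rows in
#'   the prior's label order), or NULL for a prior-only argmax.
#' @param fs the fat-suppressed [gray_volume()] (rescaled internally to Q).
#' @return a [label_map()] on the prior's label set.
#' @export
init_map <- function(prior, intensity, fs) {
  stopifnot(inherits(prior, "shape_prior"))
  d <- dim(prior$probs)[1:3]
  L <- length(prior$label_set)
  Q <- if (is.null(intensity)) 256L else ncol(intensity)
  fsq <- rescale_intensities(fs, Q)$data
  nvox <- prod(d)
  pm <- matrix(as.vector(prior$probs), nrow = nvox, ncol = L)
  midx <- which(as.vector(prior$mask))
  score <- log(pmax(pm[midx, , drop = FALSE], 1e-12))
  if (!is.null(intensity)) {
    g <- as.integer(fsq)[midx]
    for (k in seq_len(L))
      score[, k] <- score[, k] + log(pmax(intensity[k, g + 1L], 1e-12))
  }
  pick <- max.col(score, ties.method = "first")
  lab <- array(0L, dim = d)
  lab[midx] <- prior$label_set[pick]
  label_map(lab, label_set = prior$label_set, spacing = prior$spacing)
}

#' Refine a region map by iterated conditional modes
#'
#' Repeats sweeps of: (1) re-estimate the Potts potential from the current
#' map (pairs inside the domain mask), (2) re-fit the per-label LCDG
#' intensity densities from the voxels currently assigned to each label,
#' (3) reassign every mask voxel in fixed raster order to the label
#' maximising the product of shape-prior, Potts-conditional and intensity
#' probabilities. Stops when fewer than `cfg$tol_frac` of mask voxels change
#' or `cfg$max_sweeps` is reached. With `cfg$freeze_models = TRUE` both
#' models stay fixed at their initial estimates and the recorded objective
#' is non-decreasing by the ICM guarantee.
#'
#' @param init initial [label_map()] (e.g. from [init_map()]).
#' @param prior a `shape_prior` carrying the domain mask.
#' @param fs the fat-suppressed [gray_volume()].
#' @param cfg a [fusion_config()].
#' @return object of class `segmentation_result`: `map` ([label_map()]),
#'   `iterations`, `trace` (data.frame sweep/changes/v_eq/objective),
#'   `converged`, `flagged_labels`.
#' @export
icm_refine <- function(init, prior, fs, cfg = fusion_config()) {
  stopifnot(inherits(init, "label_map"), inherits(prior, "shape_prior"))
  d <- dim(init$labels)
  L <- length(prior$label_set)
  Q <- cfg$levels
  w <- cfg$exponents
  fsq <- rescale_intensities(fs, Q)$data
  mask <- as.vector(prior$mask)
  nmask <- sum(mask)
  if (nmask == 0L) stop("icm_refine: empty domain mask")
  nvox <- prod(d)

  logprior <- w[1] * log(pmax(matrix(as.vector(prior$probs), nvox, L), 1e-12))
  g <- as.integer(fsq)
  lab0 <- match(as.vector(init$labels), prior$label_set) - 1L
  if (anyNA(lab0)) stop("icm_refine: init labels outside the prior's label set")

  map_from <- function(lab0) {
    label_map(array(prior$label_set[lab0 + 1L], dim = d),
              label_set = prior$label_set, spacing = prior$spacing)
  }

  pot <- estimate_potentials(map_from(lab0), mask = prior$mask)
  im <- class_intensity_models(as.vector(fsq), prior$label_set[lab0 + 1L],
                               mask, prior$label_set, Q,
                               cfg$n_add, cfg$n_sub)
  flagged <- im$flagged
  trace <- data.frame(sweep = integer(), changes = integer(),
                      v_eq = numeric(), objective = numeric())
  converged <- FALSE
  it <- 0L
  for (sweep in seq_len(cfg$max_sweeps)) {
    it <- sweep
    if (!cfg$freeze_models && sweep > 1L) {
      pot <- estimate_potentials(map_from(lab0), mask = prior$mask)
      im2 <- class_intensity_models(as.vector(fsq), prior$label_set[lab0 + 1L],
                                    mask, prior$label_set, Q,
                                    cfg$n_add, cfg$n_sub, prev = im$densities)
      flagged <- flagged | im2$flagged
      im <- im2
    }
    logint <- w[3] * log(pmax(im$densities, 1e-12))
    veq_eff <- w[2] * pot$v_eq
    res <- icm_sweep_cpp(lab0, d, mask, logprior, logint, g, veq_eff)
    lab0 <- res$labels
    obj <- map_objective_cpp(lab0, d, mask, logprior, logint, g, veq_eff)
    trace <- rbind(trace, data.frame(sweep = sweep, changes = res$changes,
                                     v_eq = pot$v_eq, objective = obj))
    if (res$changes <= cfg$tol_frac * nmask) { converged <- TRUE; break }
  }
  structure(list(map = map_from(lab0), iterations = it, trace = trace,
                 converged = converged, flagged_labels = flagged),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", x$iterations, "sweep(s),",
      if (x$converged) "converged" else "max sweeps reached", "\n")
  print(x$trace)
  invisible(x)
}

#' End-to-end muscle-group segmentation
#'
#' Full pipeline for one subject: tissue extraction ([segment_tissues()]),
#' atlas gating / registration and shape-prior construction
#' ([build_prior()] restricted to the muscle mask), initial map from prior
#' and intensity ([init_map()]), and ICM refinement ([icm_refine()]).
#' Deterministic given inputs and settings.
#'
#' @param fs,ws the two contrast [gray_volume()]s of the test subject.
#' @param atlases list of atlases as in [build_prior()].
#' @param alpha,gate shape-prior smoothing and atlas-gate threshold.
#' @param reg_cfg a [register_config()].
#' @param fus_cfg a [fusion_config()].
#' @param levels gray levels Q.
#' @return list with `tissues` (`tissue_masks`), `prior` (`shape_prior`),
#'   `init` ([label_map()]) and `result` (`segmentation_result`).
#' @export
segment_groups <- function(fs, ws, atlases, alpha = 0.5, gate = 0.5,
                           reg_cfg = register_config(),
                           fus_cfg = fusion_config(), levels = 256L) {
  if (length(atlases) == 0L) stop("segment_groups: atlas set is empty")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  tiss <- stage("tissues", segment_tissues(fs, ws, levels = levels))
  prior <- stage("shape_prior",
                 build_prior(fs, atlases, mask = tiss$muscle, alpha = alpha,
                             gate = gate, cfg = reg_cfg, levels = levels))
  Q <- fus_cfg$levels
  fsq <- rescale_intensities(fs, Q)$data
  mask <- as.vector(prior$mask)
  # bootstrap intensity models from the prior's argmax labelling
  nvox <- prod(dim(fsq))
  L <- length(prior$label_set)
  pm <- matrix(as.vector(prior$probs), nvox, L)
  boot_lab <- prior$label_set[max.col(pm, ties.method = "first")]
  im <- class_intensity_models(as.vector(fsq), boot_lab, mask,
                               prior$label_set, Q, fus_cfg$n_add, fus_cfg$n_sub)
  init <- stage("init_map", init_map(prior, im$densities, fs))
  result <- stage("icm", icm_refine(init, prior, fs, fus_cfg))
  list(tissues = tiss, prior = prior, init = init, result = result)
}

#' Assign IMAT voxels to the muscle group of their nearest muscle voxel
#'
#' Muscle-group labels cover muscle tissue only; for compartment volumes that
#' include the intermuscular fat, each IMAT voxel can be attached to the
#' group of its nearest labelled voxel by iterative 26-neighbour label
#' propagation (majority vote per iteration, ties to the lowest label id).
#'
#' @param map the group [label_map()] (background + 3 groups).
#' @param imat binary IMAT [label_map()].
#' @param max_iter propagation iteration cap.
#' @return a [label_map()] with IMAT voxels labelled.
#' @export
assign_imat_to_groups <- function(map, imat, max_iter = 50L) {
  stopifnot(inherits(map, "label_map"))
  lab <- map$labels
  todo <- as_mask_array(imat) & lab == 0L
  d <- dim(lab)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (iter in seq_len(max_iter)) {
    if (!any(todo)) break
    idx <- which(todo, arr.ind = TRUE)
    votes <- matrix(0L, nrow = nrow(idx), ncol = max(map$label_set))
    for (r in seq_len(nrow(offs))) {
      q <- sweep(idx, 2L, offs[r, ], `+`)
      ok <- q[, 1] >= 1 & q[, 2] >= 1 & q[, 3] >= 1 &
        q[, 1] <= d[1] & q[, 2] <= d[2] & q[, 3] <= d[3]
      lv <- integer(nrow(idx))
      lv[ok] <- lab[q[ok, , drop = FALSE]]
      pos <- lv > 0L
      if (any(pos)) {
        ii <- which(pos)
        votes[cbind(ii, lv[ii])] <- votes[cbind(ii, lv[ii])] + 1L
      }
    }
    got <- rowSums(votes) > 0L
    if (!any(got)) break
    pick <- max.col(votes[got, , drop = FALSE], ties.method = "first")
    lab[idx[got, , drop = FALSE]] <- pick
    todo[idx[got, , drop = FALSE]] <- FALSE
  }
  label_map(lab, label_set = map$label_set, spacing = map$spacing)
}
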