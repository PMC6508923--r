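#' Analytic Potts potential estimate from a region map
#'
#' For a pairwise Potts Markov-Gibbs random field on the 26-neighbourhood
#' with bi-valued potentials (v_eq for equal neighbouring labels, v_ne = -v_eq
#' otherwise), the maximum-likelihood potential estimate is analytic:
#' `v_eq = 2 * f_eq - 1`, where f_eq is the relative frequency of equal
#' labels over neighbouring voxel pairs. Unordered pairs are counted once;
#' pairs crossing the volume (or mask) boundary are excluded.
#'
#' @param m a [label_map()].
#' @param mask optional logical array or [label_map()]; only pairs with both
#'   endpoints inside the mask are counted.
#' @return object of class `potts_model`: `v_eq`, `v_ne`, `f_eq`, `n_pairs`,
#'   `neighborhood` (26 x 3 offsets), `label_set`.
#' @export
estimate_potentials <- function(m, mask = NULL) {
  stopifnot(inherits(m, "label_map"))
  d <- dim(m$labels)
  use_mask <- !is.null(mask)
  marr <- if (use_mask) as.vector(as_mask_array(mask)) else logical(0)
  st <- pair_stats_26_cpp(as.vector(m$labels), d, marr, use_mask)
  if (st[2] == 0) stop("estimate_potentials: no valid neighbour pairs in the domain")
  f_eq <- st[1] / st[2]
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  structure(list(v_eq = 2 * f_eq - 1, v_ne = -(2 * f_eq - 1), f_eq = f_eq,
                 n_pairs = st[2], neighborhood = nb, label_set = m$label_set),
            class = "potts_model")
}

#' Voxel-wise Potts label probabilities
#'
#' The Gibbs conditional of each label at each voxel given its 26-neighbour
#' labels: `p(l) propto exp(sum_nb V(l, m_nb))` with V = v_eq for equal and
#' -v_eq for unequal labels, normalised over the label set. Out-of-bounds
#' neighbours are excluded.
#'
#' @param m a [label_map()] whose labels lie in `model$label_set`.
#' @param model a `potts_model` estimated on a map with the same label set.
#' @return nx x ny x nz x L array of probabilities summing to 1 over labels.
#' @export
spatial_probs <- function(m, model) {
  stopifnot(inherits(m, "label_map"), inherits(model, "potts_model"))
  if (!all(m$labels %in% model$label_set))
    stop("spatial_probs: map labels outside the model's label set")
  d <- dim(m$labels)
  L <- length(model$label_set)
  lab0 <- match(as.vector(m$labels), model$label_set) - 1L
  pm <- spatial_probs_cpp(lab0, d, L, model$v_eq)
  array(pm, dim = c(d, L))
}

#' @export
print.potts_model <- function(x, ...) {
  cat(sprintf("<potts_model> 26-neighbourhood; f_eq = %.4f, v_eq = %.4f (= -v_ne), %d pairs\n",
              x$f_eq, x$v_eq, as.integer(x$n_pairs)))
  invisible(x)
}
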