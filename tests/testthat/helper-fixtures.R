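# Small phantom used by unit tests: same topology as the default, sized down
# so each generation + LCDG run stays well under a second.
small_spec <- function(seed = 1L, noise_sigma = 0, jitter_mm = 0, ...) {
  phantom_spec(shape = c(64L, 64L, 20L), thigh_radius = 40, sat_thickness = 7,
               bone_radius = 9, marrow_radius = 5.5, bone_center = c(-5, -3),
               noise_sigma = noise_sigma, jitter_mm = jitter_mm, seed = seed,
               ...)
}

# deterministic random binary mask
rand_mask <- function(dim, p = 0.3, seed = 1L) {
  set.seed(seed)
  array(stats::runif(prod(dim)) < p, dim = dim)
}

# histogram object from simulated draws quantised to 0..Q-1
sim_histogram <- function(x, Q = 256L) {
  x <- pmin(pmax(round(x), 0), Q - 1L)
  counts <- tabulate(x + 1L, nbins = Q)
  structure(list(counts = counts, empirical = counts / sum(counts), levels = Q),
            class = "gray_histogram")
}

# brute-force unordered 26-neighbour pair counts (oracle for the Potts
# estimator), via explicit loops over voxels and offsets
oracle_pair_stats <- function(lab, mask = NULL) {
  d <- dim(lab)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  neq <- 0; ntot <- 0
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!is.null(mask) && !mask[x, y, z]) next
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      if (!is.null(mask) && !mask[q[1], q[2], q[3]]) next
      ntot <- ntot + 1
      if (lab[x, y, z] == lab[q[1], q[2], q[3]]) neq <- neq + 1
    }
  }
  c(neq = neq / 2, ntot = ntot / 2)  # each unordered pair visited twice
}

# brute-force boundary extraction + all-pairs Hausdorff oracle (mm)
oracle_hausdorff <- function(p, t, spacing) {
  boundary <- function(m) {
    d <- dim(m)
    b <- array(FALSE, d)
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      if (!m[x, y, z]) next
      edge <- x == 1 || y == 1 || z == 1 || x == d[1] || y == d[2] || z == d[3]
      if (!edge) {
        nb <- c(m[x - 1, y, z], m[x + 1, y, z], m[x, y - 1, z],
                m[x, y + 1, z], m[x, y, z - 1], m[x, y, z + 1])
        edge <- !all(nb)
      }
      b[x, y, z] <- edge
    }
    b
  }
  coords <- function(b) sweep(which(b, arr.ind = TRUE) - 1, 2, spacing, `*`)
  A <- coords(boundary(p)); B <- coords(boundary(t))
  dmat <- sqrt(outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
                 outer(A[, 3], B[, 3], `-`)^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# dense B-spline expansion by direct summation over every control point
oracle_ffd_expand <- function(grid, shape) {
  bspl <- function(t) {
    t <- abs(t)
    ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
           ifelse(t < 2, (2 - t)^3 / 6, 0))
  }
  nc <- dim(grid$displacements)[1:3]
  s <- grid$spacing_vox
  out <- array(0, dim = c(shape, 3))
  for (z in 0:(shape[3] - 1)) for (y in 0:(shape[2] - 1)) for (x in 0:(shape[1] - 1)) {
    for (kz in 0:(nc[3] - 1)) {
      wz <- bspl(z / s[3] - (kz - 1)); if (wz == 0) next
      for (ky in 0:(nc[2] - 1)) {
        wy <- bspl(y / s[2] - (ky - 1)); if (wy == 0) next
        for (kx in 0:(nc[1] - 1)) {
          wx <- bspl(x / s[1] - (kx - 1)); if (wx == 0) next
          w <- wx * wy * wz
          out[x + 1, y + 1, z + 1, ] <- out[x + 1, y + 1, z + 1, ] +
            w * grid$displacements[kx + 1, ky + 1, kz + 1, ]
        }
      }
    }
  }
  out
}

# Brute-force Bayes-error-minimising threshold over all Q candidate levels,
# evaluated against the known generating two-Gaussian mixture (the empirical
# error curve is flat over a wide span for well-separated modes, so its
# argmin is not a usable reference).
oracle_threshold <- function(m1, m2, sd1 = 12, sd2 = sd1, w1 = 0.5, Q = 256L) {
  t <- 0:(Q - 1)
  errs <- w1 * pnorm((t - 0.5 - m1) / sd1, lower.tail = FALSE) +
    (1 - w1) * pnorm((t - 0.5 - m2) / sd2)
  t[which.min(errs)]
}

# empirical misclassification count of a threshold on labelled samples
threshold_errors <- function(t, x1, x2, Q = 256L) {
  x1 <- pmin(pmax(round(x1), 0), Q - 1); x2 <- pmin(pmax(round(x2), 0), Q - 1)
  sum(x1 >= t) + sum(x2 < t)
}

# shape_prior built directly from a known truth map (near-one-hot), for tests
# that need a controlled prior without running registration
prior_from_truth <- function(truth, mask, alpha = 0.5) {
  d <- dim(truth$labels)
  L <- length(truth$label_set)
  nvox <- prod(d)
  probs <- matrix(alpha / (1 + alpha * L), nvox, L)
  idx <- match(as.vector(truth$labels), truth$label_set)
  probs[cbind(seq_len(nvox), idx)] <- (1 + alpha) / (1 + alpha * L)
  marr <- thighseg:::as_mask_array(mask)
  out <- !as.vector(marr)
  probs[out, ] <- 0
  probs[out, which(truth$label_set == 0L)] <- 1
  structure(list(probs = array(probs, dim = c(d, L)),
                 label_set = truth$label_set, mask = marr, n_selected = 1L,
                 gate_r = 1, spacing = truth$spacing),
            class = "shape_prior")
}
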