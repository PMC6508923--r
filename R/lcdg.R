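#' Empirical gray-level histogram
#'
#' Counts voxels (optionally within a mask) at each of `levels` integer gray
#' levels. The volume must already be quantised with [rescale_intensities()].
#'
#' @param v a [gray_volume()] with integer data in `[0, levels - 1]`.
#' @param mask optional [label_map()] or logical array on the same grid;
#'   only voxels with positive / TRUE mask value are counted.
#' @param levels number of gray levels Q.
#' @return object of class `gray_histogram`: `counts` (length Q),
#'   `empirical` (normalised frequencies), `levels`.
#' @export
empirical_histogram <- function(v, mask = NULL, levels = 256L) {
  stopifnot(inherits(v, "gray_volume"))
  levels <- as.integer(levels)
  x <- as.vector(v$data)
  if (!is.null(mask)) {
    m <- as.vector(as_mask_array(mask))
    if (length(m) != length(x))
      stop("empirical_histogram: mask shape does not match the volume")
    x <- x[m]
    if (length(x) == 0L) stop("empirical_histogram: mask selects no voxels")
  }
  if (min(x) < 0 || max(x) > levels - 1L)
    stop("empirical_histogram: volume not rescaled to [0, levels - 1]")
  counts <- tabulate(as.integer(round(x)) + 1L, nbins = levels)
  structure(list(counts = counts, empirical = counts / sum(counts),
                 levels = levels),
            class = "gray_histogram")
}

# Discrete Gaussian probabilities over levels 0..Q-1: each level gets the
# Gaussian mass of its unit bin, with the two end bins absorbing the tails so
# that every component sums to exactly 1.
dg_probs <- function(levels, mean, sigma) {
  q <- seq_len(levels) - 1L
  hi <- pnorm((q + 0.5 - mean) / sigma)
  lo <- pnorm((q - 0.5 - mean) / sigma)
  p <- hi - lo
  p[1] <- hi[1]
  p[levels] <- 1 - lo[levels]
  p
}

dg_matrix <- function(levels, means, sigmas) {
  vapply(seq_along(means), function(i) dg_probs(levels, means[i], sigmas[i]),
         numeric(levels))
}

weighted_quantile <- function(levels_vec, w, probs) {
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) levels_vec[which(cw >= p)[1]], numeric(1))
}

# Deterministic EM for a K-component DG mixture fitted to a weighted histogram
# (freq over levels 0..Q-1, any positive total). Initialised from weighted
# quantiles; sigma floored at `sigma_floor` gray levels.
em_dg_mixture <- function(freq, K, levels, max_iter = 200L, tol = 1e-8,
                          sigma_floor = 0.5) {
  q <- seq_len(levels) - 1
  tot <- sum(freq)
  f <- freq / tot
  mu <- weighted_quantile(q, f, (seq_len(K) - 0.5) / K)
  m0 <- sum(f * q)
  s0 <- sqrt(max(sum(f * (q - m0)^2), sigma_floor^2))
  sg <- rep(max(s0 / K, sigma_floor), K)
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    G <- dg_matrix(levels, mu, sg)                 # Q x K
    dens <- as.vector(G %*% pi_k)
    ll <- sum(f * log(pmax(dens, 1e-300)))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    R <- sweep(G, 2L, pi_k, `*`) / pmax(dens, 1e-300)  # responsibilities
    W <- R * f                                      # Q x K, weighted resp
    nk <- colSums(W)
    nk <- pmax(nk, 1e-12)
    pi_k <- nk / sum(nk)
    mu <- colSums(W * q) / nk
    sg <- sqrt(pmax(colSums(W * outer(q, mu, `-`)^2) / nk, sigma_floor^2))
  }
  o <- order(mu)
  list(weight = pi_k[o], mean = mu[o], sigma = sg[o], loglik = ll_old)
}

#' Initial two-mode fit of a bimodal histogram
#'
#' Fits the two dominant discrete Gaussians of the LCDG model — a standard
#' non-negative 2-component mixture approximating the bimodal empirical
#' distribution (dark and light tissue) — by deterministic EM on the
#' histogram.
#'
#' @param h a `gray_histogram`.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param sigma_floor minimum component sigma in gray levels.
#' @return data.frame with columns `weight`, `mean`, `sigma` (2 rows, means
#'   ascending).
#' @export
init_dominant_modes <- function(h, max_iter = 200L, tol = 1e-8,
                                sigma_floor = 0.5) {
  stopifnot(inherits(h, "gray_histogram"))
  if (sum(h$empirical > 0) < 2L)
    stop("init_dominant_modes: histogram has fewer than 2 occupied levels; a bimodal distribution is required")
  fit <- em_dg_mixture(h$empirical, 2L, h$levels, max_iter, tol, sigma_floor)
  data.frame(weight = fit$weight, mean = fit$mean, sigma = fit$sigma)
}

# evaluate the clipped, renormalised density of a signed component table
signed_density <- function(comp, levels) {
  if (nrow(comp) == 0L) return(rep(1 / levels, levels))
  G <- dg_matrix(levels, comp$mean, comp$sigma)
  d <- pmax(as.vector(G %*% comp$weight), 0)
  s <- sum(d)
  if (s <= 0) rep(1 / levels, levels) else d / s
}

#' Fit the full LCDG model of a gray-level histogram
#'
#' Models the empirical distribution as a signed mixture: two dominant
#' discrete Gaussians (DGs) plus `n_add` additive and `n_sub` subtractive
#' subordinate DGs fitted to the positive and negative parts of the deviation
#' between the empirical distribution and the dominant fit. All signed weights
#' are then re-fitted jointly by least squares; the refined model is retained
#' only while its L1 error against the empirical histogram does not exceed the
#' previous iterate, so the final L1 error is never above the dominant-only
#' fit. The total density is clipped at zero and renormalised, and the model
#' is split into two conditional class densities (dark / light tissue) from
#' which the decision threshold is derived.
#'
#' @param h a `gray_histogram`.
#' @param n_add,n_sub number of additive / subtractive subordinate DGs
#'   (defaults 4 and 4).
#' @param max_iter,tol EM controls for the component fits.
#' @param sigma_floor minimum sigma (gray levels) preventing spike collapse.
#' @param prune components with `|weight|` below this are dropped.
#' @return an object of class `lcdg_model`: `dominant`, `additive`,
#'   `subtractive` component tables (`weight`, `mean`, `sigma`; subtractive
#'   weights negative), `density` (length-Q proper distribution),
#'   `class_densities` (Q x 2), `class_weights`, `threshold`, `levels`,
#'   `l1`, `l1_dominant`, `l1_trace`, `converged`.
#' @export
fit_lcdg <- function(h, n_add = 4L, n_sub = 4L, max_iter = 200L, tol = 1e-8,
                     sigma_floor = 0.5, prune = 1e-4) {
  stopifnot(inherits(h, "gray_histogram"))
  if (n_add < 0L || n_sub < 0L)
    stop("fit_lcdg: n_add and n_sub must be non-negative")
  Q <- h$levels
  e <- h$empirical
  dom <- init_dominant_modes(h, max_iter, tol, sigma_floor)

  dom_density <- as.vector(dg_matrix(Q, dom$mean, dom$sigma) %*% dom$weight)
  l1_dom <- sum(abs(e - dom_density))

  dev <- e - dom_density
  pos <- pmax(dev, 0); neg <- pmax(-dev, 0)
  fit_part <- function(part, K) {
    if (K == 0L || sum(part) < 1e-6) return(dom[0, , drop = FALSE])
    fit <- em_dg_mixture(part, K, Q, max_iter, tol, sigma_floor)
    data.frame(weight = fit$weight * sum(part), mean = fit$mean,
               sigma = fit$sigma)
  }
  add <- fit_part(pos, as.integer(n_add))
  sub <- fit_part(neg, as.integer(n_sub))
  if (nrow(sub)) sub$weight <- -sub$weight

  comp0 <- rbind(cbind(dom, role = "dominant"),
                 if (nrow(add)) cbind(add, role = "additive"),
                 if (nrow(sub)) cbind(sub, role = "subtractive"))
  eval_l1 <- function(comp) {
    d <- pmax(as.vector(dg_matrix(Q, comp$mean, comp$sigma) %*% comp$weight), 0)
    s <- sum(d)
    if (s <= 0) return(Inf)
    sum(abs(e - d / s))
  }
  l1_init <- eval_l1(comp0)
  l1_trace <- l1_init
  comp_best <- comp0

  # joint least-squares re-fit of all signed weights (shapes fixed)
  if (nrow(comp0) > 2L) {
    G <- dg_matrix(Q, comp0$mean, comp0$sigma)
    w_ls <- tryCatch(qr.solve(G, e), error = function(err) NULL)
    if (!is.null(w_ls) && abs(sum(w_ls)) > 1e-6) {
      w_ls <- w_ls / sum(w_ls)
      ok_sign <- all(w_ls[comp0$role == "dominant"] > 0) &&
        all(w_ls[comp0$role == "subtractive"] <= 0) &&
        all(w_ls[comp0$role == "additive"] >= -1e-9)
      if (ok_sign) {
        comp_ls <- comp0
        comp_ls$weight <- w_ls
        l1_ls <- eval_l1(comp_ls)
        l1_trace <- c(l1_trace, min(l1_ls, l1_trace))
        if (l1_ls < min(l1_trace[-length(l1_trace)])) comp_best <- comp_ls
      }
    }
  }

  converged <- TRUE
  if (min(l1_trace) > l1_dom + 1e-12) {
    # deviations fit failed to help; fall back to the dominant-only model
    comp_best <- cbind(dom, role = "dominant")
    converged <- FALSE
  }

  # prune negligible components, but never at the cost of the L1 guarantee
  pruned <- comp_best[abs(comp_best$weight) >= prune | comp_best$role == "dominant", ,
                      drop = FALSE]
  if (nrow(pruned) < nrow(comp_best) && eval_l1(pruned) <= l1_dom + 1e-12)
    comp_best <- pruned
  density <- {
    d <- pmax(as.vector(dg_matrix(Q, comp_best$mean, comp_best$sigma) %*% comp_best$weight), 0)
    d / sum(d)
  }
  l1 <- sum(abs(e - density))

  # Split the total density into the two conditional class densities via the
  # dominant-mode responsibilities r_k(q) (computed in log space so the far
  # tails never underflow): class_density_k(q) proportional to
  # density(q) * r_k(q). The per-level class posterior then equals r_k(q)
  # wherever the total density is positive, and is monotone for ordered
  # dominant modes.
  domw <- comp_best$weight[comp_best$role == "dominant"]
  domw <- pmax(domw, 1e-6); domw <- domw / sum(domw)
  post <- dominant_responsibilities(Q, dom$mean, dom$sigma, domw)
  class_dens <- matrix(0, nrow = Q, ncol = 2)
  u1 <- density * post$P1; u2 <- density * post$P2
  class_w <- pmax(c(sum(u1), sum(u2)), 1e-6)
  class_dens[, 1] <- if (sum(u1) > 0) u1 / sum(u1) else dg_probs(Q, dom$mean[1], dom$sigma[1])
  class_dens[, 2] <- if (sum(u2) > 0) u2 / sum(u2) else dg_probs(Q, dom$mean[2], dom$sigma[2])
  class_w <- class_w / sum(class_w)

  threshold <- which(post$P2 >= post$P1)[1] - 1L
  if (is.na(threshold)) threshold <- Q  # no level favours the light class

  structure(list(dominant = comp_best[comp_best$role == "dominant", 1:3],
                 additive = comp_best[comp_best$role == "additive", 1:3],
                 subtractive = comp_best[comp_best$role == "subtractive", 1:3],
                 density = density,
                 class_densities = class_dens, class_weights = class_w,
                 posteriors = post,
                 threshold = threshold, levels = Q,
                 l1 = l1, l1_dominant = l1_dom, l1_trace = l1_trace,
                 converged = converged),
            class = "lcdg_model")
}

# Per-level posteriors of the two dominant modes, computed from log
# densities so the far tails never underflow to an indeterminate 0/0.
dominant_responsibilities <- function(Q, means, sigmas, weights) {
  q <- seq_len(Q) - 1
  l1 <- log(weights[1]) + dnorm(q, means[1], sigmas[1], log = TRUE)
  l2 <- log(weights[2]) + dnorm(q, means[2], sigmas[2], log = TRUE)
  P1 <- 1 / (1 + exp(l2 - l1))
  list(P1 = P1, P2 = 1 - P1)
}

#' Per-level class posteriors of an LCDG model
#'
#' For every gray level q, the posterior probability of the dark class (P1)
#' and the light class (P2) given q, computed from the two conditional class
#' densities and their mixing weights. `P1 + P2 == 1` at every level.
#'
#' @param model an `lcdg_model`.
#' @return list with numeric vectors `P1` and `P2` of length `model$levels`.
#' @export
class_posteriors <- function(model) {
  stopifnot(inherits(model, "lcdg_model"))
  model$posteriors
}

#' Total LCDG density
#'
#' The signed mixture evaluated per level, clipped at zero and renormalised:
#' a proper distribution over the Q gray levels.
#'
#' @param model an `lcdg_model`.
#' @return numeric vector of length `model$levels` summing to 1.
#' @export
lcdg_density <- function(model) {
  stopifnot(inherits(model, "lcdg_model"))
  model$density
}

#' Binarise a volume with an LCDG model
#'
#' Labels a voxel as light tissue (1) iff its gray level is at or above the
#' model threshold (equivalently, iff P2 >= P1 at its level); dark tissue
#' gets 0.
#'
#' @param v a [gray_volume()] rescaled to `model$levels`.
#' @param model an `lcdg_model`.
#' @return a binary [label_map()] (0 = dark, 1 = light).
#' @export
binarize <- function(v, model) {
  stopifnot(inherits(v, "gray_volume"), inherits(model, "lcdg_model"))
  lab <- array(as.integer(v$data >= model$threshold), dim = dim(v$data))
  label_map(lab, label_set = c(0L, 1L), spacing = v$spacing)
}

#' @export
print.lcdg_model <- function(x, ...) {
  cat("<lcdg_model> Q =", x$levels, "levels;",
      nrow(x$dominant), "dominant +", nrow(x$additive), "additive -",
      nrow(x$subtractive), "subtractive DGs\n",
      " threshold =", x$threshold,
      sprintf(" | L1 = %.4g (dominant-only %.4g)\n", x$l1, x$l1_dominant))
  invisible(x)
}

#' Serialise / restore an LCDG model as plain text
#'
#' Writes the component table, threshold and level count to a key-value text
#' file for reproducibility, and reads it back.
#'
#' @param model an `lcdg_model`.
#' @param path destination text file.
#' @return `write_lcdg`: `path` invisibly; `read_lcdg`: an `lcdg_model`.
#' @export
write_lcdg <- function(model, path) {
  stopifnot(inherits(model, "lcdg_model"))
  comp <- rbind(cbind(model$dominant, role = "dominant"),
                if (nrow(model$additive)) cbind(model$additive, role = "additive"),
                if (nrow(model$subtractive)) cbind(model$subtractive, role = "subtractive"))
  lines <- c(sprintf("levels: %d", model$levels),
             sprintf("threshold: %d", model$threshold),
             sprintf("component: %s %.12g %.12g %.12g", comp$role,
                     comp$weight, comp$mean, comp$sigma))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lcdg
#' @export
read_lcdg <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) sub(paste0(key, ": "), "", grep(paste0("^", key, ":"), lines, value = TRUE))
  Q <- as.integer(get1("levels"))
  thr <- as.integer(get1("threshold"))
  comp_lines <- strsplit(sub("^component: ", "", grep("^component:", lines, value = TRUE)), " ")
  comp <- do.call(rbind, lapply(comp_lines, function(p)
    data.frame(role = p[1], weight = as.numeric(p[2]), mean = as.numeric(p[3]),
               sigma = as.numeric(p[4]))))
  dens <- {
    d <- pmax(as.vector(dg_matrix(Q, comp$mean, comp$sigma) %*% comp$weight), 0)
    d / sum(d)
  }
  dom <- comp[comp$role == "dominant", c("weight", "mean", "sigma")]
  domw <- pmax(dom$weight, 1e-6); domw <- domw / sum(domw)
  post <- dominant_responsibilities(Q, dom$mean, dom$sigma, domw)
  u1 <- dens * post$P1; u2 <- dens * post$P2
  class_w <- pmax(c(sum(u1), sum(u2)), 1e-6); class_w <- class_w / sum(class_w)
  class_dens <- cbind(
    if (sum(u1) > 0) u1 / sum(u1) else dg_probs(Q, dom$mean[1], dom$sigma[1]),
    if (sum(u2) > 0) u2 / sum(u2) else dg_probs(Q, dom$mean[2], dom$sigma[2]))
  structure(list(dominant = dom,
                 additive = comp[comp$role == "additive", c("weight", "mean", "sigma")],
                 subtractive = comp[comp$role == "subtractive", c("weight", "mean", "sigma")],
                 density = dens, class_densities = class_dens,
                 class_weights = class_w, posteriors = post,
                 threshold = thr, levels = Q,
                 l1 = NA_real_, l1_dominant = NA_real_, l1_trace = NA_real_,
                 converged = TRUE),
            class = "lcdg_model")
}
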