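test_that("init_map follows a one-hot prior and reduces to the intensity Bayes rule", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  mask <- array(TRUE, dim(ph$fs$data))
  truth <- ph$truth_groups
  Q <- 256L

  onehot <- prior_from_truth(truth, mask, alpha = 1e-9)
  set.seed(77)
  intensity <- matrix(runif(4 * Q), 4, Q)
  intensity <- intensity / rowSums(intensity)
  init <- init_map(onehot, intensity, ph$fs)
  expect_identical(init$labels, truth$labels)

  # uniform prior: the init is the per-voxel intensity argmax
  uni <- onehot
  uni$probs[] <- 0.25
  fsq <- rescale_intensities(ph$fs, Q)$data
  init2 <- init_map(uni, intensity, ph$fs)
  bayes <- apply(intensity, 2, which.max) - 1L  # label per level (0-based id)
  expect_identical(as.vector(init2$labels),
                   as.integer(bayes[as.integer(fsq) + 1L]))
})

test_that("a fixed point passes one ICM sweep with zero changes", {
  # two half-spaces split by an axis-aligned plane: every boundary voxel has
  # more same-label than other-label neighbours, the prior votes the
  # incumbent and the intensity term is label-neutral, so all three terms
  # already agree everywhere
  d <- c(12L, 12L, 12L)
  lab <- array(1L, d); lab[7:12, , ] <- 2L
  truth <- label_map(lab, label_set = 0:2)
  mask <- array(TRUE, d)
  prior <- prior_from_truth(truth, mask, alpha = 0.01)
  fs <- gray_volume(array(5, d))
  res <- icm_refine(truth, prior, fs,
                    fusion_config(freeze_models = TRUE, max_sweeps = 3))
  expect_equal(res$iterations, 1L)
  expect_equal(res$trace$changes[1], 0)
  expect_true(res$converged)
  expect_identical(res$map$labels, truth$labels)
})

test_that("the frozen-model ICM objective is non-decreasing and ends at a conditional fixed point", {
  set.seed(16)
  d <- c(16L, 16L, 16L)
  mask_map <- array(TRUE, d)
  lab <- array(sample(0:3, prod(d), TRUE), d)
  truth <- label_map(lab, label_set = 0:3)
  prior <- prior_from_truth(truth, mask_map, alpha = 2)  # weakly informative
  # constant volume: every label's intensity density is identical, so the
  # conditional argmax is driven by prior and Potts terms only
  fs <- gray_volume(array(5, d))
  set.seed(17)
  start <- label_map(array(sample(0:3, prod(d), TRUE), d), label_set = 0:3)
  cfg <- fusion_config(freeze_models = TRUE, max_sweeps = 10, tol_frac = 0)
  res <- icm_refine(start, prior, fs, cfg)
  expect_true(all(diff(res$trace$objective) >= -1e-6))

  # after convergence every voxel holds the argmax of its Gibbs conditional
  if (res$trace$changes[res$iterations] == 0) {
    final <- res$map
    pot <- estimate_potentials(start, mask = mask_map)  # frozen at the init
    pr <- spatial_probs(final, pot)
    nvox <- prod(d)
    pm <- matrix(as.vector(prior$probs), nvox, 4)
    set.seed(18)
    for (i in sample(nvox, 200)) {
      xyz <- arrayInd(i, d)
      sc <- log(pmax(pm[i, ], 1e-12)) + log(pr[xyz[1], xyz[2], xyz[3], ])
      best <- which.max(sc) - 1L
      cur <- final$labels[i]
      expect_gte(sc[cur + 1L], sc[best + 1L] - 1e-9)
    }
  }
})

test_that("refinement with a strong prior recovers corrupted voxels", {
  ph <- make_phantom(small_spec(noise_sigma = 0.03))
  truth <- ph$truth_groups
  mask_arr <- truth$labels > 0L
  midx <- which(mask_arr)
  set.seed(13)
  flip <- sample(midx, round(0.02 * length(midx)))
  start <- truth
  start$labels[flip] <- ((start$labels[flip] + sample(0:2, length(flip), TRUE)) %% 3L) + 1L
  flipped <- which(start$labels != truth$labels)

  prior <- prior_from_truth(truth, mask_arr, alpha = 0.5)
  res <- icm_refine(start, prior, ph$fs, fusion_config(max_sweeps = 10))
  recovered <- sum(res$map$labels[flipped] == truth$labels[flipped])
  expect_gte(recovered / length(flipped), 0.95)
})

test_that("icm_refine is deterministic", {
  ph <- make_phantom(small_spec(seed = 8, noise_sigma = 0.05))
  truth <- ph$truth_groups
  mask_arr <- truth$labels > 0L
  set.seed(99)
  start <- truth
  midx <- which(mask_arr)
  flip <- sample(midx, 500)
  start$labels[flip] <- (start$labels[flip] %% 3L) + 1L
  prior <- prior_from_truth(truth, mask_arr)
  r1 <- icm_refine(start, prior, ph$fs, fusion_config())
  r2 <- icm_refine(start, prior, ph$fs, fusion_config())
  expect_identical(r1$map$labels, r2$map$labels)
  expect_identical(r1$trace, r2$trace)
})

test_that("permuting the labels permutes the refined map identically", {
  ph <- make_phantom(small_spec(seed = 14, noise_sigma = 0.05))
  truth <- ph$truth_groups
  mask_arr <- truth$labels > 0L
  prior <- prior_from_truth(truth, mask_arr)
  set.seed(15)
  start <- truth
  flip <- sample(which(mask_arr), 400)
  start$labels[flip] <- (start$labels[flip] %% 3L) + 1L
  cfg <- fusion_config(max_sweeps = 5)
  r <- icm_refine(start, prior, ph$fs, cfg)

  perm <- c(0L, 3L, 1L, 2L)  # background fixed, groups cycled
  permute_map <- function(m) {
    label_map(array(perm[m$labels + 1L], dim(m$labels)), label_set = 0:3,
              spacing = m$spacing)
  }
  truth_p <- permute_map(truth)
  start_p <- permute_map(start)
  prior_p <- prior_from_truth(truth_p, mask_arr)
  r_p <- icm_refine(start_p, prior_p, ph$fs, cfg)
  expect_identical(r_p$map$labels, permute_map(r$map)$labels)
})

test_that("segment_groups propagates stage errors and confines labels to the muscle mask", {
  ph <- make_phantom(small_spec(seed = 2, noise_sigma = 0.05))
  neg <- gray_volume(max(ph$fs$data) - ph$fs$data, spacing = ph$fs$spacing)
  expect_error(
    segment_groups(ph$fs, ph$ws,
                   list(list(volume = neg, labels = ph$truth_groups))),
    "shape_prior")
  expect_error(segment_groups(ph$fs, ph$ws, list()), "empty")
})

test_that("IMAT voxels inherit the group of their nearest muscle voxel", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  truth <- ph$truth_groups
  imat <- ph$truth_tissues$imat
  filled <- assign_imat_to_groups(truth, imat)
  im <- as.logical(imat$labels)
  expect_true(all(filled$labels[im] > 0L))
  expect_identical(filled$labels[!im], truth$labels[!im])
})
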