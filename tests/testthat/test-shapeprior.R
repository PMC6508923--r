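test_that("a single identical atlas yields the one-hot prior smoothed by alpha", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  atlas <- list(volume = ph$fs, labels = ph$truth_groups)
  prior <- build_prior(ph$fs, list(atlas), alpha = 0.5)
  expect_equal(prior$n_selected, 1L)
  L <- 4
  d <- dim(ph$fs$data)
  nvox <- prod(d)
  idx <- match(as.vector(ph$truth_groups$labels), prior$label_set)
  pm <- matrix(as.vector(prior$probs), nvox, L)
  expect_equal(pm[cbind(seq_len(nvox), idx)],
               rep((1 + 0.5) / (1 + 0.5 * L), nvox), tolerance = 1e-12)
})

test_that("two disagreeing atlases split the vote 50/50 with alpha = 0", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  lab2 <- ph$truth_groups
  v <- which(lab2$labels == 1L)[1]
  lab2$labels[v] <- 2L
  atlases <- list(list(volume = ph$fs, labels = ph$truth_groups),
                  list(volume = ph$fs, labels = lab2))
  prior <- build_prior(ph$fs, atlases, alpha = 0)
  nvox <- prod(dim(ph$fs$data))
  pm <- matrix(as.vector(prior$probs), nvox, 4)
  expect_equal(pm[v, 2], 0.5)   # label 1 (column 2 of 0:3)
  expect_equal(pm[v, 3], 0.5)
})

test_that("the prior normalises at every voxel and zero selected atlases is an error", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  atlas <- list(volume = ph$fs, labels = ph$truth_groups)
  prior <- build_prior(ph$fs, list(atlas),
                       mask = ph$truth_tissues$muscle)
  pm <- matrix(as.vector(prior$probs), prod(dim(ph$fs$data)), 4)
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-9)

  neg <- gray_volume(max(ph$fs$data) - ph$fs$data, spacing = ph$fs$spacing)
  expect_error(build_prior(ph$fs, list(list(volume = neg, labels = ph$truth_groups))),
               "gate")
})

test_that("adding an atlas that votes a label never decreases its probability", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  atlas <- list(volume = ph$fs, labels = ph$truth_groups)
  p1 <- build_prior(ph$fs, list(atlas))
  p2 <- build_prior(ph$fs, list(atlas, atlas))
  nvox <- prod(dim(ph$fs$data))
  idx <- match(as.vector(ph$truth_groups$labels), p1$label_set)
  m1 <- matrix(as.vector(p1$probs), nvox, 4)
  m2 <- matrix(as.vector(p2$probs), nvox, 4)
  voted1 <- m1[cbind(seq_len(nvox), idx)]
  voted2 <- m2[cbind(seq_len(nvox), idx)]
  expect_true(all(voted2 >= voted1 - 1e-12))
})

test_that("prior_log_prob matches the exhaustive per-voxel product", {
  # 2 x 2 x 1 grid, 2 labels: enumerate the product directly
  probs <- array(0, c(2, 2, 1, 2))
  pvals <- matrix(c(0.9, 0.3, 0.6, 0.2), 2, 2)
  probs[, , 1, 1] <- pvals
  probs[, , 1, 2] <- 1 - pvals
  prior <- structure(list(probs = probs, label_set = c(0L, 1L),
                          mask = array(TRUE, c(2, 2, 1)), n_selected = 1L,
                          gate_r = 1, spacing = c(1, 1, 1)),
                     class = "shape_prior")
  for (code in 0:15) {
    bits <- as.integer(intToBits(code)[1:4])
    m <- label_map(array(bits, c(2, 2, 1)), label_set = c(0L, 1L))
    direct <- prod(vapply(1:4, function(i) {
      xy <- arrayInd(i, c(2, 2))
      probs[xy[1], xy[2], 1, bits[i] + 1L]
    }, numeric(1)))
    expect_equal(prior_log_prob(prior, m), log(direct), tolerance = 1e-12)
  }
})

test_that("one-hot priors rank their own argmax highest; uniform priors are indifferent", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  truth <- ph$truth_groups
  prior <- prior_from_truth(truth, mask = array(TRUE, dim(truth$labels)),
                            alpha = 1e-6)
  lp_truth <- prior_log_prob(prior, truth)
  other <- truth
  sel <- which(other$labels == 1L)[1:50]
  other$labels[sel] <- 3L
  expect_gt(lp_truth, prior_log_prob(prior, other))

  uni <- prior
  uni$probs[] <- 0.25
  expect_equal(prior_log_prob(uni, truth), prior_log_prob(uni, other),
               tolerance = 1e-9)
})
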