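test_that("empirical_histogram counts levels and respects masks", {
  v <- gray_volume(array(7, c(5, 5, 4)))
  h <- empirical_histogram(v, levels = 256)
  expect_equal(h$counts[8], 100)
  expect_equal(h$empirical[8], 1)
  expect_equal(sum(h$empirical), 1, tolerance = 1e-9)

  x <- array(50, c(10, 10, 2)); x[, , 2] <- 200
  h2 <- empirical_histogram(gray_volume(x))
  expect_equal(h2$empirical[51], 0.5)
  expect_equal(h2$empirical[201], 0.5)

  m <- array(FALSE, c(5, 5, 4))
  expect_error(empirical_histogram(v, mask = m), "no voxels")

  # the phantom FS histogram inside the thigh is bimodal: fat and muscle peaks
  ph <- make_phantom(small_spec(noise_sigma = 0.05))
  fsq <- rescale_intensities(ph$fs)
  hp <- empirical_histogram(fsq, mask = ph$truth_tissues$thigh)
  e <- stats::filter(hp$empirical, rep(1 / 5, 5))  # light smoothing
  e[is.na(e)] <- 0
  peaks <- which(diff(sign(diff(e))) == -2) + 1
  peaks <- peaks[e[peaks] > max(e) / 10]
  expect_gte(length(peaks), 2)
  expect_gt(max(peaks) - min(peaks), 60)
})

test_that("init_dominant_modes recovers a two-Gaussian mixture", {
  set.seed(21)
  x <- c(rnorm(5e4, 64, 10), rnorm(5e4, 192, 10))
  fit <- init_dominant_modes(sim_histogram(x))
  expect_lt(abs(fit$mean[1] - 64), 3)
  expect_lt(abs(fit$mean[2] - 192), 3)
  expect_lt(abs(fit$weight[1] - 0.5), 0.05)
  expect_lt(abs(fit$weight[2] - 0.5), 0.05)
})

test_that("init_dominant_modes handles spikes and rejects degenerate input", {
  counts <- integer(256); counts[41] <- 500; counts[201] <- 500
  h <- structure(list(counts = counts, empirical = counts / sum(counts),
                      levels = 256L), class = "gray_histogram")
  fit <- init_dominant_modes(h)
  expect_equal(fit$mean, c(40, 200), tolerance = 0.5)
  expect_equal(fit$sigma, c(0.5, 0.5), tolerance = 1e-6)  # at the floor

  counts1 <- integer(256); counts1[11] <- 100
  h1 <- structure(list(counts = counts1, empirical = counts1 / 100,
                       levels = 256L), class = "gray_histogram")
  expect_error(init_dominant_modes(h1), "bimodal")
})

test_that("fit_lcdg yields a proper density and never does worse than the dominant fit", {
  # histogram exactly equal to a 2-DG mixture: deviations vanish
  dexact <- 0.4 * thighseg:::dg_probs(256, 80, 12) +
    0.6 * thighseg:::dg_probs(256, 180, 15)
  h <- structure(list(counts = round(dexact * 1e6), empirical = dexact,
                      levels = 256L), class = "gray_histogram")
  m <- fit_lcdg(h)
  if (nrow(m$additive)) expect_lt(max(abs(m$additive$weight)), 0.02)
  if (nrow(m$subtractive)) expect_lt(max(abs(m$subtractive$weight)), 0.02)
  expect_lte(m$l1, m$l1_dominant + 1e-12)

  # reduction: no subordinate components allowed
  m0 <- fit_lcdg(h, n_add = 0, n_sub = 0)
  expect_equal(nrow(m0$additive), 0)
  expect_equal(nrow(m0$subtractive), 0)

  # skewed bimodal mixture: the full model strictly beats the dominant-only fit
  set.seed(31)
  x <- c(rnorm(4e4, 60, 8), rnorm(2e4, 85, 18), rnorm(3e4, 180, 10),
         rnorm(1e4, 155, 20))
  ms <- fit_lcdg(sim_histogram(x))
  expect_lt(ms$l1, ms$l1_dominant)

  for (mod in list(m, m0, ms)) {
    expect_true(all(mod$density >= 0))
    expect_equal(sum(mod$density), 1, tolerance = 1e-6)
    expect_true(all(mod$class_densities >= 0))
    expect_equal(colSums(mod$class_densities), c(1, 1), tolerance = 1e-6)
    expect_true(mod$threshold >= 0 && mod$threshold <= mod$levels)
    # the recorded L1 trace never increases across refinement
    expect_true(all(diff(mod$l1_trace) <= 1e-12))
  }
})

test_that("class posteriors sum to one, favour the near class, and cross at the threshold", {
  set.seed(41)
  x <- c(rnorm(5e4, 64, 10), rnorm(5e4, 192, 10))
  m <- fit_lcdg(sim_histogram(x))
  post <- class_posteriors(m)
  expect_equal(post$P1 + post$P2, rep(1, 256), tolerance = 1e-9)
  expect_gt(post$P1[65], 0.99)      # at the dark-class mean
  expect_gt(post$P2[193], 0.99)     # at the light-class mean
  expect_true(all(diff(post$P2) >= -1e-9))  # monotone towards the light class
  # the decision boundary is where the posteriors cross
  gap <- abs(post$P1 - post$P2)
  expect_lte(min(gap[(m$threshold):(m$threshold + 2)]), min(gap) + 1e-9)
})

test_that("binarize thresholds at the model threshold and approaches the Bayes rule", {
  set.seed(51)
  x1 <- rnorm(5e4, 64, 10); x2 <- rnorm(5e4, 192, 10)
  m <- fit_lcdg(sim_histogram(c(x1, x2)))
  expect_lt(abs(m$threshold - 128), 3)

  # equivalence with direct thresholding on random volumes
  for (s in 1:3) {
    set.seed(s)
    v <- gray_volume(array(sample(0:255, 4000, TRUE), c(20, 20, 10)))
    lab <- binarize(v, m)
    expect_identical(lab$labels, array(as.integer(v$data >= m$threshold), dim(v$data)))
  }

  dark <- gray_volume(array(sample(0:40, 1000, TRUE), c(10, 10, 10)))
  expect_true(all(binarize(dark, m)$labels == 0))

  # misclassification within 1.2x of the brute-force optimal threshold
  topt <- oracle_threshold(64, 192, 10)
  expect_lte(threshold_errors(m$threshold, x1, x2),
             1.2 * threshold_errors(topt, x1, x2))
})

test_that("LCDG threshold tracks the brute-force optimum across separations", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    m1 <- 60 + (s - 1) * 50 / 19
    m2 <- 196 - (s - 1) * 50 / 19
    x1 <- rnorm(5e4, m1, 12); x2 <- rnorm(5e4, m2, 12)
    mod <- fit_lcdg(sim_histogram(c(x1, x2)))
    expect_true(all(mod$density >= 0))
    expect_equal(sum(mod$density), 1, tolerance = 1e-6)
    expect_lte(mod$l1, mod$l1_dominant + 1e-12)
    if (abs(mod$threshold - oracle_threshold(m1, m2)) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("LCDG models serialise to text and back", {
  set.seed(61)
  x <- c(rnorm(3e4, 70, 11), rnorm(3e4, 185, 14))
  m <- fit_lcdg(sim_histogram(x))
  f <- tempfile(fileext = ".txt")
  write_lcdg(m, f)
  m2 <- read_lcdg(f)
  expect_equal(m2$threshold, m$threshold)
  expect_equal(m2$levels, m$levels)
  expect_equal(m2$density, m$density, tolerance = 1e-9)
  expect_equal(m2$dominant$mean, m$dominant$mean, tolerance = 1e-9)
})
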