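test_that("bspline_expand matches brute-force tensor-product evaluation", {
  set.seed(9)
  g <- control_grid(c(9L, 9L, 9L), 4)
  nc <- dim(g$displacements)
  g$displacements <- array(rnorm(prod(nc)), dim = nc)
  dense <- bspline_expand(g)$disp
  expect_equal(dense, oracle_ffd_expand(g, c(9, 9, 9)), tolerance = 1e-9)
})

test_that("bspline_expand is the identity on zero displacements and is linear", {
  g0 <- control_grid(c(12L, 10L, 8L), 4)
  expect_true(all(bspline_expand(g0)$disp == 0))

  set.seed(10)
  g <- g0
  g$displacements <- array(rnorm(prod(dim(g$displacements))),
                           dim = dim(g$displacements))
  ga <- g; ga$displacements <- 2.5 * g$displacements
  expect_equal(bspline_expand(ga)$disp, 2.5 * bspline_expand(g)$disp,
               tolerance = 1e-12)
})

test_that("a single displaced control point produces a local bump of known height", {
  g <- control_grid(c(17L, 17L, 17L), 4)
  # control at voxel (8,8,8): k = 8/4 + 1 = 3 (0-based), R index 4
  g$displacements[4, 4, 4, 1] <- 6
  dense <- bspline_expand(g)$disp
  # peak at the control position equals d * B(0)^3 = d * (2/3)^3
  expect_equal(dense[9, 9, 9, 1], 6 * (2 / 3)^3, tolerance = 1e-12)
  # support limited to 2 cells (8 voxels) per axis around the control
  expect_equal(dense[1, 9, 9, 1], 0)
  expect_true(all(dense[, , , 2:3] == 0))
  far <- dense[abs(seq_len(17) - 9) >= 8, , , 1]
  expect_true(all(far == 0))
})

test_that("sad_energy is zero on identity self-match, non-negative, and improved by the true shift", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  fsq <- rescale_intensities(ph$fs)
  expect_equal(sad_energy(fsq, fsq), 0)

  d <- dim(fsq$data)
  g <- control_grid(d, 8)
  g$displacements[, , , 1] <- 3   # uniform +3 voxel shift in x
  field <- bspline_expand(g)
  shifted <- warp_volume(fsq, field)        # shifted(x) = fs(x + 3)
  e_corr <- sad_energy(shifted, fsq, field) # sampling fs at x+3 again
  e_id <- sad_energy(shifted, fsq)
  expect_lte(e_corr, e_id)
  expect_gte(e_corr, 0)
})

test_that("warp_labels transports labels along the field and preserves the label set", {
  lab <- array(0L, c(12, 12, 6)); lab[6, 6, 3] <- 2L
  m <- label_map(lab, label_set = c(0L, 2L), spacing = c(1, 1, 1))
  g <- control_grid(c(12L, 12L, 6L), 4)
  expect_identical(warp_labels(m, bspline_expand(g))$labels, lab)

  g$displacements[, , , 1] <- 2   # pull-back: out(x) = m(x + 2)
  w <- warp_labels(m, bspline_expand(g))
  expect_equal(which(w$labels == 2L, arr.ind = TRUE)[1, ], c(4, 6, 3),
               ignore_attr = TRUE)
  expect_true(all(unique(as.vector(w$labels)) %in% m$label_set))
})

test_that("registering a volume to itself recovers the identity", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  fsq <- rescale_intensities(ph$fs)
  field <- register_ffd(fsq, fsq)
  expect_lt(max(abs(field$disp)), 0.5)
  e <- attr(field, "energy")
  expect_lte(e["final"], e["identity"])
})

test_that("the recovered field never scores worse than the identity", {
  ph <- make_phantom(small_spec(noise_sigma = 0.05, seed = 2))
  fsq <- rescale_intensities(ph$fs)
  set.seed(17)
  g <- control_grid(dim(fsq$data), 12)
  nc <- dim(g$displacements)
  g$displacements <- array(rnorm(prod(nc), sd = 1.5), dim = nc)
  warped <- warp_volume(fsq, bspline_expand(g))
  field <- register_ffd(gray_volume(warped$data, spacing = fsq$spacing), fsq)
  e <- attr(field, "energy")
  expect_lte(e["final"], e["identity"])
})

test_that("atlas_gate selects by mean slice correlation with the 0.5 gate", {
  ph <- make_phantom(small_spec(noise_sigma = 0.05))
  fsq <- rescale_intensities(ph$fs)
  same <- atlas_gate(fsq, fsq)
  expect_equal(same$mean_r, 1, tolerance = 1e-12)
  expect_true(same$selected)

  neg <- gray_volume(max(fsq$data) - fsq$data, spacing = fsq$spacing)
  opp <- atlas_gate(fsq, neg)
  expect_equal(opp$mean_r, -1, tolerance = 1e-12)
  expect_false(opp$selected)

  set.seed(3)
  n1 <- gray_volume(array(runif(40 * 40 * 20), c(40, 40, 20)))
  n2 <- gray_volume(array(runif(40 * 40 * 20), c(40, 40, 20)))
  ind <- atlas_gate(n1, n2)
  expect_lt(abs(ind$mean_r), 0.1)
  expect_false(ind$selected)

  # a constant slice contributes r = 0
  c1 <- gray_volume(array(1, c(8, 8, 4)))
  c2 <- gray_volume(array(runif(8 * 8 * 4), c(8, 8, 4)))
  expect_equal(atlas_gate(c1, c2)$mean_r, 0)
})
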