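test_that("confusion counts match direct enumeration", {
  d <- c(10, 10, 10)
  p <- rand_mask(d, 0.4, seed = 2)
  t <- rand_mask(d, 0.4, seed = 20)
  cc <- confusion(p, t)
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (p[x, y, z] && t[x, y, z]) tp <- tp + 1
    else if (p[x, y, z]) fp <- fp + 1
    else if (t[x, y, z]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(cc$tp, tp); expect_equal(cc$fp, fp)
  expect_equal(cc$fn, fn); expect_equal(cc$tn, tn)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, prod(d))

  k <- sum(t)
  same <- confusion(t, t)
  expect_equal(same$tp, k); expect_equal(same$tn, prod(d) - k)
  expect_equal(same$fp + same$fn, 0)

  allp <- confusion(array(TRUE, d), array(FALSE, d))
  expect_equal(allp$fp, prod(d))
  expect_equal(allp$tp + allp$fn + allp$tn, 0)

  expect_error(confusion(p, rand_mask(c(5, 5, 5))), "grids")
})

test_that("Dice, precision and recall follow their closed forms", {
  r <- dice_precision_recall(list(tp = 8, fp = 2, fn = 2))
  expect_equal(r$dice, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)

  perfect <- dice_precision_recall(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(dice = 1, precision = 1, recall = 1))

  none <- dice_precision_recall(list(tp = 0, fp = 3, fn = 4))
  expect_equal(none$dice, 0)

  both_empty <- dice_precision_recall(list(tp = 0, fp = 0, fn = 0))
  expect_equal(both_empty$dice, 1)
})

test_that("Dice is symmetric and precision/recall swap with the masks", {
  d <- c(12, 12, 6)
  p <- rand_mask(d, 0.3, seed = 7)
  t <- rand_mask(d, 0.3, seed = 70)
  expect_equal(dice(p, t), dice(t, p))
  a <- dice_precision_recall(confusion(p, t))
  b <- dice_precision_recall(confusion(t, p))
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
})

test_that("Hausdorff distance handles worked cases, symmetry and degenerate masks", {
  d <- c(10, 10, 10)
  m <- rand_mask(d, 0.2, seed = 11)
  m_map <- label_map(array(as.integer(m), d), label_set = 0:1,
                     spacing = c(1.5, 1.5, 1.5))
  expect_equal(hausdorff(m_map, m_map), 0)

  a <- array(FALSE, d); b <- array(FALSE, d)
  a[3, 5, 5] <- TRUE; b[5, 5, 5] <- TRUE   # 2 voxels apart in x
  expect_equal(hausdorff(a, b, spacing = c(1.5, 1.5, 1.5)), 3.0)

  p <- rand_mask(d, 0.15, seed = 4)
  t <- rand_mask(d, 0.15, seed = 40)
  expect_equal(hausdorff(p, t, spacing = c(1.5, 1.5, 1.5)),
               hausdorff(t, p, spacing = c(1.5, 1.5, 1.5)))

  empty <- array(FALSE, d)
  expect_warning(h0 <- hausdorff(empty, empty, spacing = c(1, 1, 1)), "both")
  expect_equal(h0, 0)
  expect_error(hausdorff(empty, t, spacing = c(1, 1, 1)), "prediction")
  expect_error(hausdorff(p, empty, spacing = c(1, 1, 1)), "truth")
})

test_that("Hausdorff matches the brute-force boundary oracle", {
  for (s in 1:5) {
    d <- c(12, 12, 8)
    p <- rand_mask(d, 0.2, seed = s)
    t <- rand_mask(d, 0.2, seed = s + 100)
    sp <- c(1.5, 1.5, 1.5)
    expect_equal(hausdorff(p, t, spacing = sp), oracle_hausdorff(p, t, sp),
                 tolerance = 1e-9)
  }
})

test_that("volumes are voxel count times voxel volume and additive", {
  d <- c(10, 10, 10)
  m <- array(FALSE, d); m[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels
  v <- volume_ml(m, spacing = c(1.5, 1.5, 1.5))
  expect_equal(v$mm3, 3375)
  expect_equal(v$ml, 3.375)

  expect_equal(volume_ml(array(FALSE, d), spacing = c(1.5, 1.5, 1.5))$mm3, 0)

  a <- rand_mask(d, 0.3, seed = 31)
  b <- rand_mask(d, 0.3, seed = 32) & !a
  va <- volume_ml(a, spacing = c(1, 2, 3))$mm3
  vb <- volume_ml(b, spacing = c(1, 2, 3))$mm3
  expect_equal(volume_ml(a | b, spacing = c(1, 2, 3))$mm3, va + vb)
})

test_that("evaluate_labels reports one accuracy row per label", {
  ph <- make_phantom(small_spec(noise_sigma = 0))
  rep <- evaluate_labels(ph$truth_groups, ph$truth_groups)
  expect_equal(rep$label, 1:3)
  expect_equal(rep$dice, rep(1, 3))
  expect_equal(rep$hausdorff_mm, rep(0, 3))
})
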