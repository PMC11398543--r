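test_that("peak extraction finds generator orientations and rejects flats", {
  p1 <- extract_peaks(gt_fod_from_fibers(rbind(c(0, 0, 1)), 1))
  expect_equal(p1$n, 1L)
  expect_lt(angular_sep(p1$directions[1L, ], c(0, 0, 1)), 1)
  p2 <- extract_peaks(gt_fod_from_fibers(rbind(c(0, 0, 1), c(1, 0, 0)),
                                         c(0.5, 0.5)))
  expect_equal(p2$n, 2L)
  errs <- vapply(1:2, function(i)
    min(angular_sep(p2$directions[i, ], c(0, 0, 1)),
        angular_sep(p2$directions[i, ], c(1, 0, 0))), numeric(1))
  expect_lt(max(errs), 1)
  # constant (isotropic) FOD and zero FOD yield no peaks
  expect_equal(extract_peaks(c(2, rep(0, 44)))$n, 0L)
  expect_equal(extract_peaks(rep(0, 45))$n, 0L)
})

test_that("peak extraction is rotation-equivariant and scale-invariant", {
  fod <- gt_fod_from_fibers(rbind(uvec(10), uvec(75)), c(0.55, 0.45))
  R <- rot_about(c(0, 1, 1), 28)
  dense <- fibonacci_directions(600)
  fod_rot <- fit_sh(evaluate_sh(fod, dense %*% R), dense, 8L)
  pk <- extract_peaks(fod)
  pk_rot <- extract_peaks(fod_rot)
  expect_equal(pk$n, pk_rot$n)
  for (i in seq_len(pk$n)) {
    rotated <- as.numeric(R %*% pk$directions[i, ])
    expect_lt(min(fodlab:::angular_sep_many(pk_rot$directions, rotated)), 2)
  }
  pk_scaled <- extract_peaks(7.3 * fod)
  expect_equal(pk_scaled$n, pk$n)
  expect_equal(pk_scaled$directions, pk$directions, tolerance = 1e-9)
})

test_that("angular separation is antipodally symmetric", {
  expect_equal(angular_sep(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(angular_sep(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(angular_sep(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(angular_sep(uvec(30), uvec(75)), 45, tolerance = 1e-9)
})

test_that("peak matching uses the optimal assignment, not greedy pairing", {
  a <- peak_set(rbind(c(0, 0, 1), uvec(20)), c(1, 0.9))
  expect_equal(match_and_ae(a, a), 0)
  # joint rotation preserves the mean angle
  R <- rot_about(c(0, 0, 1), 10)
  b <- peak_set(rbind(as.numeric(R %*% uvec(90)), as.numeric(R %*% c(1, 1, 0)
                                                             / sqrt(2))),
                c(1, 0.9))
  a2 <- peak_set(rbind(uvec(90), c(1, 1, 0) / sqrt(2)), c(1, 0.9))
  expect_equal(match_and_ae(b, a2), 10, tolerance = 1e-6)
  # adversarial ordering: greedy nearest-first would pair (10deg, 18deg)
  # wrongly; the optimal assignment gives mean 10.5 degrees
  ref <- peak_set(rbind(uvec(0), uvec(18)), c(1, 1))
  pred <- peak_set(rbind(uvec(10), uvec(29)), c(1, 1))
  # independent exhaustive oracle
  ang <- outer(1:2, 1:2, Vectorize(function(i, j)
    angular_sep(pred$directions[i, ], ref$directions[j, ])))
  oracle <- min(ang[1, 1] + ang[2, 2], ang[1, 2] + ang[2, 1]) / 2
  expect_equal(match_and_ae(pred, ref), oracle, tolerance = 1e-9)
  expect_equal(oracle, 10.5, tolerance = 1e-6)
  # count mismatch is NA, not an error
  expect_true(is.na(match_and_ae(peak_set(rbind(c(0, 0, 1)), 1), ref)))
  expect_true(is.na(match_and_ae(ref, peak_set())))
})

test_that("agreement rate matches hand enumeration", {
  ref <- c(1, 1, 1, 1, 2, 2)
  pred <- c(1, 1, 1, 2, 2, 2)
  ar <- agreement_rate(pred, ref)
  expect_equal(unname(ar["1"]), 75)
  expect_equal(unname(ar["2"]), 100)
  expect_true(is.na(ar["3"]))
  expect_equal(unname(agreement_rate(ref, ref)[c("1", "2")]), c(100, 100))
  expect_equal(unname(agreement_rate(c(2, 2, 3), c(1, 1, 2))[c("1", "2")]),
               c(0, 0))
})

test_that("fiber-count confusion is normalized and trace-consistent", {
  ref <- c(1, 1, 1, 2, 2, 3)
  pred <- c(1, 1, 2, 2, 2, 3)
  M <- fiber_count_confusion(pred, ref)
  expect_equal(sum(M), 1, tolerance = 1e-9)
  expect_equal(sum(diag(M)), mean(pred == ref), tolerance = 1e-9)
  expect_equal(M["1", "2"], 1 / 6, tolerance = 1e-9)
  # hand-computed toy
  expect_equal(unname(M["1", "1"]), 2 / 6, tolerance = 1e-12)
  # perfect agreement, uniform counts
  Mu <- fiber_count_confusion(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(diag(Mu)), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(fiber_count_confusion(1, 1, mask = FALSE), "empty mask")
  # zero-count voxels are excluded
  M0 <- fiber_count_confusion(c(0, 1), c(1, 1))
  expect_equal(unname(M0["1", "1"]), 1)
})

test_that("AFD and its MAPE follow the total-integral definition", {
  fod <- gt_fod_from_fibers(rbind(c(0, 0, 1)), 1)
  expect_equal(afd(fod), sqrt(4 * pi) * fod[1L], tolerance = 1e-12)
  ref <- rbind(fod, fod)
  expect_equal(afd_mape(ref, ref), 0)
  expect_equal(afd_mape(ref, 1.1 * ref), 10, tolerance = 1e-9)
  # hand case: afd (1, 2) vs (1.2, 1.8) -> mean(20%, 10%) = 15%
  r2 <- rbind(c(1, rep(0, 44)), c(2, rep(0, 44)))
  o2 <- rbind(c(1.2, rep(0, 44)), c(1.8, rep(0, 44)))
  expect_equal(afd_mape(r2, o2), 15, tolerance = 1e-9)
  expect_error(afd_mape(matrix(0, 2, 45), matrix(1, 2, 45)), "positive")
})

test_that("self-comparison of a volume is perfect on every metric", {
  vol <- fix_noiseless_phantom(shape = c(8, 8, 4))
  img <- sh_image(vol$gt_fod, 8L, "fod")
  mask <- array(as.vector(vol$tissue_label) %in%
                  c("wm_single", "wm_cross2", "wm_cross3"),
                dim = dim(vol$gt_count))
  rep <- compare_fod_volumes(img, img, mask)
  expect_equal(unname(rep$ar), rep(100, 3))
  expect_equal(unname(rep$ae), rep(0, 3), tolerance = 1e-5)
  expect_equal(rep$afd_mape, 0)
  expect_equal(sum(diag(rep$confusion)), 1, tolerance = 1e-9)
  expect_equal(sum(rep$confusion), 1, tolerance = 1e-9)
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0))
})

test_that("metric invariants hold for a perturbed comparison", {
  vol <- fix_noiseless_phantom(shape = c(8, 8, 4))
  img <- sh_image(vol$gt_fod, 8L, "fod")
  M <- fodlab:::sh_image_matrix(img)
  set.seed(31)
  other <- sh_image(M * 1.07 + matrix(rnorm(length(M), 0, 0.01), nrow(M)),
                    8L, "fod", grid_shape = img$grid_shape)
  mask <- array(as.vector(vol$tissue_label) %in%
                  c("wm_single", "wm_cross2", "wm_cross3"),
                dim = dim(vol$gt_count))
  rep <- compare_fod_volumes(img, other, mask)
  expect_true(all(is.na(rep$ar) | (rep$ar >= 0 & rep$ar <= 100)))
  expect_true(all(is.na(rep$ae) | rep$ae >= 0))
  expect_equal(sum(rep$confusion), 1, tolerance = 1e-9)
  expect_true(all(rep$confusion >= 0))
  expect_gte(rep$afd_mape, 0)
})
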