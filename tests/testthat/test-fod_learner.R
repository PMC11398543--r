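test_that("direction subsampling is deterministic and well spread", {
  sch <- fix_scheme()
  full <- subsample_directions(sch, 88L)
  expect_equal(length(full$bvals), 89L)
  expect_equal(sum(full$bvals == 1000), 88L)
  s6 <- subsample_directions(sch, 6L)
  expect_identical(s6, subsample_directions(sch, 6L))
  # minimum pairwise antipodal angle beats the best of 200 random subsets
  min_angle <- function(dirs) {
    ad <- acos(pmin(abs(tcrossprod(dirs)), 1))
    min(ad[upper.tri(ad)]) * 180 / pi
  }
  chosen <- min_angle(s6$directions[s6$bvals > 0, ])
  shell <- sch$directions[sch$bvals == 1000, ]
  set.seed(99)
  rand_best <- max(vapply(1:200, function(i)
    min_angle(shell[sample(88, 6), ]), numeric(1)))
  expect_gte(chosen, rand_best)
  expect_error(subsample_directions(sch, 89L), "exceeds")
})

test_that("direction counts pair with the documented SH orders", {
  expect_equal(lmax_for_nsig(6L), 2L)
  expect_equal(lmax_for_nsig(15L), 4L)
  expect_equal(lmax_for_nsig(28L), 6L)
  expect_equal(lmax_for_nsig(45L), 8L)
  expect_equal(lmax_for_nsig(88L), 8L)
})

test_that("prepare_input normalizes by b0 and projects at the paired order", {
  vol <- fix_noiseless_phantom(shape = c(6, 6, 4))
  inp <- prepare_input(vol$dwi, vol$scheme, 15L)
  expect_equal(inp$lmax, 4L)
  expect_equal(dim(inp$coeffs)[4L], 15L)
  expect_equal(inp$provenance, "signal")
  # constant dwi equal to b0 -> only the l = 0 coefficient, sqrt(4 pi)
  const <- array(3, dim = c(4, 4, 4, 300))
  ci <- prepare_input(const, vol$scheme, 15L)
  flat <- matrix(ci$coeffs, 64, 15)
  expect_equal(unname(flat[, 1L]), rep(sqrt(4 * pi), 64), tolerance = 1e-9)
  expect_lt(max(abs(flat[, -1L])), 1e-9)
  # zero b0 voxels are masked, not NaN
  z <- const; z[1, 1, 1, vol$scheme$bvals == 0] <- 0
  cz <- prepare_input(z, vol$scheme, 15L)
  expect_false(cz$mask[1, 1, 1])
  expect_true(all(is.finite(cz$coeffs)))
  # round trip: the fitted SH reproduces the normalized signal
  sub <- subsample_directions(vol$scheme, 28L)
  v <- which(as.vector(vol$tissue_label) == "wm_single")[1L]
  flat_dwi <- matrix(vol$dwi, prod(dim(vol$gt_count)), 300)
  normalized <- flat_dwi[v, sub$parent_idx[-1L]] /
    flat_dwi[v, sub$parent_idx[1L]]
  inp28 <- prepare_input(vol$dwi, vol$scheme, 28L)
  cf <- matrix(inp28$coeffs, prod(dim(vol$gt_count)), 28)[v, ]
  recon <- evaluate_sh(cf, sub$directions[-1L, ])
  expect_lt(max(abs(recon - normalized)), 0.05)
})

test_that("patch sampling is seeded, masked and degenerates correctly", {
  set.seed(5)
  gs <- c(20, 20, 20)
  img_in <- sh_image(matrix(rnorm(prod(gs) * 6), prod(gs), 6), 2L,
                     "signal", grid_shape = gs)
  img_out <- sh_image(matrix(rnorm(prod(gs) * 45), prod(gs), 45), 8L,
                      "fod", grid_shape = gs)
  p1 <- sample_patches(img_in, img_out, n = 10L, size = 16L, seed = 3L)
  p2 <- sample_patches(img_in, img_out, n = 10L, size = 16L, seed = 3L)
  expect_identical(p1, p2)
  expect_true(all(vapply(p1, function(p) any(p$mask), logical(1))))
  # on a 16^3 volume every patch is the full volume
  gs2 <- c(16, 16, 16)
  i2 <- sh_image(matrix(rnorm(prod(gs2) * 6), prod(gs2), 6), 2L, "signal",
                 grid_shape = gs2)
  o2 <- sh_image(matrix(rnorm(prod(gs2) * 45), prod(gs2), 45), 8L, "fod",
                 grid_shape = gs2)
  ps <- sample_patches(i2, o2, n = 3L, size = 16L, seed = 1L)
  expect_equal(ps[[1L]]$x, ps[[2L]]$x)
  expect_equal(ps[[1L]]$origin, c(1L, 1L, 1L), ignore_attr = TRUE)
  # empty mask is an error
  i3 <- i2; i3$mask[] <- FALSE
  expect_error(sample_patches(i3, o2, n = 1L, size = 16L, seed = 1L),
               "no patch origin")
})

test_that("training descends, is reproducible, and predicts 45 channels", {
  vol <- fix_noiseless_phantom(shape = c(8, 8, 8))
  gt <- sh_image(vol$gt_fod, 8L, "fod")
  inp <- prepare_input(vol$dwi, vol$scheme, 6L)
  subj <- list(input = inp, target = gt)
  cfg <- train_config(learning_rate = 1e-3, patches_per_subject = 6L,
                      patch_size = 8L, max_epochs = 5L, patience = 5L,
                      seed = 11L)
  spec <- model_spec(in_channels = 6L, base = 4L)
  m1 <- train_fod_net(spec, list(subj), list(subj), cfg)
  h1 <- attr(m1, "history")
  expect_lt(h1$train_loss[nrow(h1)], h1$train_loss[1L])
  # bitwise reproducibility of the loss history
  m2 <- train_fod_net(spec, list(subj), list(subj), cfg)
  expect_identical(h1, attr(m2, "history"))
  expect_identical(m1$params, m2$params)
  # prediction shape and masking
  pred <- predict_fod(m1, inp, patch_size = 8L)
  expect_equal(dim(pred$coeffs)[4L], 45L)
  expect_equal(pred$lmax, 8L)
  # reported loss equals an independent mean-squared-error pass
  pt <- sample_patches(inp, gt, n = 1L, size = 8L, seed = 2L)[[1L]]
  fw <- fodlab:::net_forward(m1, pt$x, pt$dims)
  expect_equal(fodlab:::l2_loss(fw$out, pt$y)$loss,
               mean((fw$out - pt$y)^2), tolerance = 1e-7)
})

test_that("sliding-window prediction averages to the direct output", {
  set.seed(8)
  spec <- model_spec(in_channels = 6L, base = 4L)
  m <- fodlab:::init_model(spec, seed = 3L)
  gs <- c(8, 8, 8)
  img <- sh_image(matrix(rnorm(prod(gs) * 6), prod(gs), 6), 2L, "signal",
                  grid_shape = gs)
  # volume equal to the window: single window, direct application
  pred <- predict_fod(m, img, patch_size = 8L)
  direct <- fodlab:::net_forward(m, t(fodlab:::sh_image_matrix(img)), gs)
  expect_equal(fodlab:::sh_image_matrix(pred), t(direct$out),
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant input, non-overlapping tiling: identical windows make the
  # output periodic with the window size
  gs2 <- c(16, 16, 16)
  cimg <- sh_image(matrix(1, prod(gs2), 6), 2L, "signal", grid_shape = gs2)
  p2 <- predict_fod(m, cimg, patch_size = 8L, stride = 8L)
  arr <- p2$coeffs
  expect_equal(arr[2:8, 2:8, 2:8, ], arr[10:16, 10:16, 10:16, ],
               tolerance = 1e-12)
  # channel mismatch errors
  bad <- sh_image(matrix(1, prod(gs2), 15), 4L, "signal", grid_shape = gs2)
  expect_error(predict_fod(m, bad, patch_size = 8L), "channels")
})
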