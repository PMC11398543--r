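test_that("canonical scheme has the right shells, counts and unit vectors", {
  sch <- fix_scheme()
  expect_equal(length(sch$bvals), 300L)
  expect_equal(sch$shell_bvals, c(0, 400, 1000, 2600))
  expect_equal(sum(sch$bvals == 1000), 88L)
  expect_equal(as.integer(table(sch$shell_id)), c(20L, 64L, 88L, 128L))
  expect_lt(max(abs(sqrt(rowSums(sch$directions^2)) - 1)), 1e-9)
  expect_identical(make_dhcp_scheme(), make_dhcp_scheme())
})

test_that("multi-tensor voxel signals match closed forms", {
  sch <- fix_scheme()
  # any mixture at b = 0 gives s0
  p <- fix_params()
  mix <- list(fiber_compartment(c(0, 0, 1), 0.5, p$wm_axial, p$wm_radial),
              iso_compartment("gm", p$gm_d, 0.3),
              iso_compartment("csf", p$csf_d, 0.2))
  sig <- simulate_voxel(mix, sch, s0 = 2)
  expect_equal(sig[sch$bvals == 0], rep(2, 20), tolerance = 1e-12)
  # pure CSF at b = 1000: s0 exp(-3)
  csf <- simulate_voxel(list(iso_compartment("csf", 3.0e-3, 1)), sch)
  expect_equal(unique(round(csf[sch$bvals == 1000], 12)), exp(-3),
               tolerance = 1e-9)
  # fiber along z measured along z at b = 1000: s0 exp(-1.7)
  one <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 1), c(0, 0, 1)))
  fib <- simulate_voxel(list(fiber_compartment(c(0, 0, 1), 1, 1.7e-3,
                                               0.3e-3)), one)
  expect_equal(fib[2L], exp(-1.7), tolerance = 1e-12)
  # fractions must sum to one; negatives rejected
  expect_error(simulate_voxel(list(iso_compartment("gm", 1e-3, 0.7)), sch),
               "sum")
  expect_error(fiber_compartment(c(0, 0, 1), -0.1), "negative")
  expect_error(iso_compartment("gm", -1e-3, 1), "positive")
})

test_that("noiseless signals are bounded, shell-monotone and antipodal", {
  sch <- fix_scheme()
  sig <- crossing_signal(sch)
  expect_true(all(sig >= 0 & sig <= 1 + 1e-12))
  shell_means <- tapply(sig, sch$shell_id, mean)
  expect_true(all(diff(shell_means) <= 1e-12))
  # antipodal symmetry
  flip <- gradient_scheme(sch$bvals, -sch$directions)
  expect_equal(crossing_signal(flip), sig, tolerance = 1e-14)
})

test_that("Rician noise is seeded, bounded below and has the Rayleigh floor", {
  s <- runif(200)
  expect_identical(add_rician_noise(s, Inf, 1L), s)
  n1 <- add_rician_noise(s, 20, 42L)
  expect_identical(n1, add_rician_noise(s, 20, 42L))
  expect_false(identical(n1, add_rician_noise(s, 20, 43L)))
  # mean of noised zero signal: sigma sqrt(pi / 2)
  z <- add_rician_noise(numeric(1e5), 20, 7L, s0 = 1)
  expect_equal(mean(z), (1 / 20) * sqrt(pi / 2), tolerance = 0.01)
})

test_that("ground-truth FODs are non-negative with maxima at the fibers", {
  f1 <- gt_fod_from_fibers(rbind(c(0, 0, 1)), 1)
  idx <- sh_index_table(8L)
  expect_lt(max(abs(f1[idx$m != 0])), 1e-10)
  grid <- fibonacci_directions(10000, hemisphere = TRUE)
  amp <- evaluate_sh(f1, grid)
  expect_gt(min(amp), -1e-3 * max(amp))
  best <- grid[which.max(amp), ]
  expect_lt(angular_sep(best, c(0, 0, 1)), 1)
  # FOD integral equals the fraction sum
  expect_equal(sqrt(4 * pi) * f1[1L], 1, tolerance = 1e-9)
  # two equal fibers at 90 degrees: symmetric, maxima on both axes
  f2 <- gt_fod_from_fibers(rbind(c(0, 0, 1), c(1, 0, 0)), c(0.5, 0.5))
  amp2 <- evaluate_sh(f2, grid)
  top <- grid[order(amp2, decreasing = TRUE)[1:2], ]
  seps <- c(min(angular_sep(top[1L, ], c(0, 0, 1)),
                angular_sep(top[1L, ], c(1, 0, 0))),
            min(angular_sep(top[2L, ], c(0, 0, 1)),
                angular_sep(top[2L, ], c(1, 0, 0))))
  expect_lt(max(seps), 1)
  # swap symmetry of the two axes
  swapped <- grid[, c(3, 2, 1)]
  expect_equal(evaluate_sh(f2, swapped), amp2, tolerance = 1e-9)
  expect_error(gt_fod_from_fibers(diag(4)[, 1:3], rep(0.25, 4)), "at most 3")
})

test_that("phantom volumes honor geometry, noise seeding and contrast", {
  vol <- fix_noiseless_phantom()
  lab <- as.vector(vol$tissue_label)
  sch <- vol$scheme
  # noiseless CSF voxels equal the closed-form signal
  v <- which(lab == "csf")[1L]
  flat <- matrix(vol$dwi, prod(dim(vol$gt_count)), 300)
  expect_equal(flat[v, ], simulate_voxel(list(iso_compartment(
    "csf", 3.0e-3, 1)), sch), tolerance = 1e-12)
  # count histogram equals region sizes
  expect_equal(sum(vol$gt_count == 2), sum(lab == "wm_cross2"))
  expect_equal(sum(vol$gt_count == 3), sum(lab == "wm_cross3"))
  # gt peaks separated by at least the crossing angle
  v2 <- which(lab == "wm_cross2")[1L]
  pk <- vol$gt_peaks[[v2]]
  expect_gte(angular_sep(pk[1L, ], pk[2L, ]),
             vol$spec$crossing_angles[["cross2"]] - 1e-6)
  # neonatal contrast: mean GM signal within WM voxel-mean range at low
  # maturation, on every non-zero shell
  low <- build_phantom(phantom_spec(grid_shape = c(10, 10, 4),
                                    maturation = 0.1, snr = Inf), sch)
  lab2 <- as.vector(low$tissue_label)
  fl <- matrix(low$dwi, prod(dim(low$gt_count)), 300)
  for (b in c(400, 1000, 2600)) {
    cols <- which(sch$bvals == b)
    gm_mean <- mean(fl[lab2 == "gm", cols])
    wm_means <- vapply(c("wm_single", "wm_cross2", "wm_cross3"),
                       function(r) mean(fl[lab2 == r, cols]), numeric(1))
    expect_gte(gm_mean, min(wm_means))
    expect_lte(gm_mean, max(wm_means))
  }
  # overlapping regions rejected
  bad <- list(csf = rbind(c(1, 4), c(1, 4), c(1, 4)),
              gm = rbind(c(3, 6), c(1, 4), c(1, 4)))
  expect_error(phantom_spec(grid_shape = c(6, 4, 4), region_layout = bad),
               "overlap")
  # seeded reproducibility with noise
  spn <- phantom_spec(grid_shape = c(6, 6, 4), snr = 25, seed = 9L)
  expect_identical(build_phantom(spn, sch)$dwi, build_phantom(spn, sch)$dwi)
})

test_that("cohorts are seeded and maturation drives anisotropy", {
  base <- phantom_spec(grid_shape = c(5, 5, 4), snr = Inf)
  c1 <- make_cohort(base, 3, c(0.5, 0.5), seed = 4L)
  expect_equal(vapply(c1, function(v) v$spec$maturation, numeric(1)),
               rep(0.5, 3))
  expect_identical(make_cohort(base, 2, c(0.1, 0.3), seed = 5L),
                   make_cohort(base, 2, c(0.1, 0.3), seed = 5L))
  expect_error(make_cohort(base, 2, c(0.4, 0.2), seed = 1L), "interval")
  # mean single-fiber FA increases from an immature to a mature cohort
  fa_of <- function(vol) {
    lab <- as.vector(vol$tissue_label)
    v <- which(lab == "wm_single")[1L]
    flat <- matrix(vol$dwi, prod(dim(vol$gt_count)), 300)
    fa(fit_tensor(flat[v, ], vol$scheme))
  }
  young <- make_cohort(base, 2, c(0.1, 0.3), seed = 6L)
  old <- make_cohort(base, 2, c(0.7, 0.9), seed = 6L)
  expect_lt(mean(vapply(young, fa_of, numeric(1))),
            mean(vapply(old, fa_of, numeric(1))))
})
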