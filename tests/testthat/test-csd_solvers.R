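test_that("forward matrix composes convolution and evaluation", {
  sch <- fix_scheme()
  resp <- fix_responses()
  A <- build_forward_matrix(sch, resp, 8L)
  expect_equal(dim(A), c(300L, 47L))
  # applying the WM block to a delta FOD equals convolution + evaluation
  delta <- as.numeric(basis_matrix(c(0, 0, 1), 8L))
  pred <- as.numeric(A[, 1:45] %*% delta)
  rows <- which(sch$bvals == 1000)
  conv <- spherical_convolution(delta, resp$wm, 1000)
  expect_equal(pred[rows], evaluate_sh(conv, sch$directions[rows, ]),
               tolerance = 1e-10)
  # b0 rows of the WM block touch only the l = 0 column
  b0rows <- which(sch$bvals == 0)
  expect_lt(max(abs(A[b0rows, 2:45])), 1e-12)
  expect_gt(min(abs(A[b0rows, 1L])), 0)
  # missing shell is an error
  expect_error(build_forward_matrix(sch, fix_responses_b1000(), 8L),
               "missing shell")
})

test_that("MSMT-CSD recovers fibers and compartments on noiseless voxels", {
  sch <- fix_scheme()
  resp <- fix_responses()
  r <- msmt_csd(fiber_signal(c(0, 0, 1), sch), sch, resp)
  pk <- extract_peaks(r$wm_sh)
  expect_equal(pk$n, 1L)
  expect_lt(angular_sep(pk$directions[1L, ], c(0, 0, 1)), 2)
  total <- sqrt(4 * pi) * r$wm_sh[1L] + sqrt(4 * pi) * (r$gm + r$csf)
  expect_lt(sqrt(4 * pi) * (r$gm + r$csf), 0.05 * total)
  # pure CSF: compartment explains the signal, WM FOD negligible
  csf_sig <- simulate_voxel(list(iso_compartment("csf", 3.0e-3, 1)), sch)
  rc <- msmt_csd(csf_sig, sch, resp)
  A <- build_forward_matrix(sch, resp, 8L)
  pred_csf <- A[, 47L] * rc$csf
  expect_gt(sum(pred_csf^2) / sum(csf_sig^2), 0.99)
  grid <- fibonacci_directions(800, hemisphere = TRUE)
  amp_csf <- max(abs(evaluate_sh(rc$wm_sh, grid)))
  amp_fib <- max(evaluate_sh(r$wm_sh, grid))
  expect_lt(amp_csf, 0.01 * amp_fib)
  expect_error(msmt_csd(csf_sig[sch$bvals <= 400],
                        scheme_subset(sch, which(sch$bvals <= 400)),
                        resp), "3 distinct b-values")
})

test_that("unconstrained MSMT equals the pseudo-inverse solution", {
  sch <- fix_scheme()
  resp <- fix_responses()
  sig <- add_rician_noise(crossing_signal(sch), 30, 11L)
  r <- msmt_csd(sig, sch, resp, constrained = FALSE)
  A <- build_forward_matrix(sch, resp, 8L)
  x <- qr.solve(A, sig)
  expect_equal(c(r$wm_sh, r$gm, r$csf), as.numeric(x), tolerance = 1e-8)
})

test_that("SS3T-CSD alternation recovers fibers from b0 + b1000", {
  sub <- fix_b1000_scheme()
  resp <- fix_responses_b1000()
  sig <- fiber_signal(c(0, 0, 1), sub)
  r <- ss3t_csd(sig, sub, resp)
  expect_true(r$converged)
  pk <- extract_peaks(r$wm_sh)
  expect_equal(pk$n, 1L)
  expect_lt(angular_sep(pk$directions[1L, ], c(0, 0, 1)), 2)
  # 90-degree crossing with a GM admixture: both fibers within 5 degrees
  r2 <- ss3t_csd(crossing_signal(sub), sub, resp)
  pk2 <- extract_peaks(r2$wm_sh)
  expect_equal(pk2$n, 2L)
  errs <- vapply(1:2, function(i)
    min(angular_sep(pk2$directions[i, ], uvec(45)),
        angular_sep(pk2$directions[i, ], uvec(-45))), numeric(1))
  expect_lt(max(errs), 5)
  # degenerate tolerance: one iteration, flagged converged
  r3 <- ss3t_csd(sig, sub, resp, tol = Inf)
  expect_identical(r3$n_iter, 1L)
  expect_true(r3$converged)
  # multi-shell input is redirected to msmt
  expect_error(ss3t_csd(rep(1, 300), fix_scheme(), fix_responses()),
               "msmt_csd")
})

test_that("SS3T residual is non-increasing across iterations", {
  sub <- fix_b1000_scheme()
  resp <- fix_responses_b1000()
  sig <- add_rician_noise(crossing_signal(sub), 20, 5L)
  res <- vapply(1:8, function(k)
    ss3t_csd(sig, sub, resp, max_iter = k, tol = 0)$residual_norm,
    numeric(1))
  expect_true(all(diff(res) <= 1e-9))
})

test_that("solver outputs satisfy constraints and scale equivariantly", {
  sub <- fix_b1000_scheme()
  sch <- fix_scheme()
  grid <- fodlab:::default_constraint_grid()
  B <- basis_matrix(grid$directions, 8L)
  for (noisy in c(FALSE, TRUE)) {
    sig <- crossing_signal(sch)
    if (noisy) sig <- add_rician_noise(sig, 15, 21L)
    rm_ <- msmt_csd(sig, sch, fix_responses())
    rs_ <- ss3t_csd(sig[fix_b1000_scheme()$parent_idx], sub,
                    fix_responses_b1000())
    for (r in list(rm_, rs_)) {
      expect_gte(r$gm, 0)
      expect_gte(r$csf, 0)
      expect_gt(min(B %*% r$wm_sh), -1e-6 * max(abs(B %*% r$wm_sh)))
    }
  }
  # scaling equivariance
  sig <- add_rician_noise(crossing_signal(sch), 25, 3L)
  r1 <- msmt_csd(sig, sch, fix_responses())
  r2 <- msmt_csd(3 * sig, sch, fix_responses())
  expect_equal(c(r2$wm_sh, r2$gm, r2$csf), 3 * c(r1$wm_sh, r1$gm, r1$csf),
               tolerance = 1e-6)
})

test_that("MSMT and SS3T agree in the identifiable noiseless limit", {
  sch <- fix_scheme()
  sub <- fix_b1000_scheme()
  for (sig_full in list(fiber_signal(uvec(20), sch),
                        crossing_signal(sch, angle = 70))) {
    pm <- extract_peaks(msmt_csd(sig_full, sch, fix_responses())$wm_sh)
    ps <- extract_peaks(ss3t_csd(sig_full[sub$parent_idx], sub,
                                 fix_responses_b1000())$wm_sh)
    expect_equal(pm$n, ps$n)
    for (i in seq_len(pm$n))
      expect_lt(min(fodlab:::angular_sep_many(ps$directions,
                                              pm$directions[i, ])), 5)
  }
})

test_that("tensor fit and FA behave at the limiting cases", {
  sch <- fix_scheme()
  iso <- simulate_voxel(list(iso_compartment("gm", 1e-3, 1)), sch)
  expect_lt(fa(fit_tensor(iso, sch)), 1e-6)
  expect_equal(fa(diag(c(1, 0, 0))), 1, tolerance = 1e-12)
  expect_equal(fa(diag(c(1, 1, 1))), 0, tolerance = 1e-12)
  expect_equal(fa(matrix(0, 3, 3)), 0)
  sig <- fiber_signal(uvec(30), sch)
  ev <- eigen(fit_tensor(sig, sch), symmetric = TRUE)$vectors[, 1L]
  expect_lt(angular_sep(ev, uvec(30)), 1)
  expect_error(fit_tensor(iso[1:5], scheme_subset(sch, 1:5)), "needs")
})

test_that("wm_mask combines threshold and labels", {
  famap <- array(0, dim = c(3, 3, 3))
  expect_false(any(wm_mask(famap)))
  famap[2, 2, 2] <- 0.3
  m <- wm_mask(famap)
  expect_identical(which(m), 14L)
  lab <- array("gm", dim = c(3, 3, 3)); lab[1, 1, 1] <- "wm_single"
  m2 <- wm_mask(array(0, dim = c(3, 3, 3)), lab)
  expect_identical(which(m2), 1L)
})

test_that("responses estimated from a noiseless phantom match the generator", {
  vol <- fix_noiseless_phantom()
  est <- estimate_responses_from_phantom(vol)
  p <- fix_params(0.2)
  for (b in c(400, 1000, 2600)) {
    truth <- zonal_from_tensor(p$wm_axial, p$wm_radial, b, 8L)
    got <- fodlab:::kernel_row(est$wm, b)
    expect_lt(max(abs(got - truth)) / max(abs(truth)), 0.01)
  }
  k0 <- fodlab:::kernel_row(est$csf, 0)[1L]
  k1 <- fodlab:::kernel_row(est$csf, 1000)[1L]
  expect_equal(k1 / k0, exp(-3), tolerance = 0.01)
  expect_identical(est, estimate_responses_from_phantom(vol))
  vol2 <- list(dwi = vol$dwi, scheme = vol$scheme,
               tissue_label = array("gm", dim = dim(vol$tissue_label)),
               gt_peaks = vol$gt_peaks)
  expect_error(estimate_responses_from_phantom(vol2), "lacks")
})
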