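# Constrained spherical deconvolution ground-truth generators.
#
# MSMT-CSD: one convex quadratic program per voxel -- linear least squares
# on all shells jointly, subject to non-negative WM FOD amplitude on a
# constraint grid and non-negative GM/CSF compartments.
#
# SS3T-CSD: from a single non-zero shell plus b0, a two-step alternating
# scheme: (A) with WM fixed, solve for the non-negative GM and CSF
# compartments; (B) with CSF fixed, solve for WM (amplitude-constrained)
# and GM jointly; iterate to convergence.  Each step solves its convex
# subproblem exactly, so the residual norm is non-increasing.

#' Per-tissue response set
#'
#' @param wm [zonal_kernel()] of the anisotropic single-fiber response
#'   (per shell).
#' @param gm,csf [zonal_kernel()]s of the isotropic responses; coefficients
#'   beyond degree 0 must be zero.
#' @return object of class `response_set`.
#' @export
response_set <- function(wm, gm, csf) {
  for (k in list(gm, csf))
    if (ncol(k$coef) > 1L && any(abs(k$coef[, -1L]) > 1e-12))
      stop("gm/csf responses must be isotropic (degree 0 only)")
  if (!identical(wm$shell_bvals, gm$shell_bvals) ||
      !identical(wm$shell_bvals, csf$shell_bvals))
    stop("all tissues must share the same shell list")
  structure(list(wm = wm, gm = gm, csf = csf,
                 shell_bvals = wm$shell_bvals),
            class = "response_set")
}

#' Response set from generating tensor parameters
#'
#' Convenience constructor producing the exact responses of the phantom's
#' forward model at the given maturation.
#'
#' @param shell_bvals shells to cover (include 0).
#' @param maturation maturation in [0, 1] selecting the default tissue
#'   parameters.
#' @param lmax even maximum degree of the WM kernel.
#' @param s0 baseline signal scale.
#' @return a [response_set()].
#' @export
response_set_from_params <- function(shell_bvals, maturation = 0.2, lmax = 8L,
                                     s0 = 1) {
  p <- tissue_params(maturation)
  nz <- lmax / 2 + 1
  wm <- t(vapply(shell_bvals, function(b)
    s0 * zonal_from_tensor(p$wm_axial, p$wm_radial, b, lmax), numeric(nz)))
  iso <- function(d) t(vapply(shell_bvals, function(b)
    c(s0 * exp(-b * d) * sqrt(4 * pi), rep(0, nz - 1L)), numeric(nz)))
  response_set(zonal_kernel(wm, shell_bvals, lmax),
               zonal_kernel(iso(p$gm_d), shell_bvals, lmax),
               zonal_kernel(iso(p$csf_d), shell_bvals, lmax))
}

#' Forward matrix of the three-tissue deconvolution model
#'
#' Maps the stacked unknown `[wm_sh (n_coeffs(lmax)), gm, csf]` to the
#' predicted signal of every measurement in the scheme.  WM columns apply
#' the per-shell spherical convolution with the WM kernel evaluated at the
#' measurement direction; GM and CSF columns are the per-shell isotropic
#' response amplitudes.
#'
#' @param scheme a [gradient_scheme()].
#' @param responses a [response_set()] covering every shell in `scheme`.
#' @param lmax even maximum degree of the WM FOD (default 8).
#' @return numeric matrix, `length(scheme$bvals)` x `(n_coeffs(lmax) + 2)`.
#' @export
build_forward_matrix <- function(scheme, responses, lmax = 8L) {
  for (b in scheme$shell_bvals)
    if (!any(abs(responses$shell_bvals - b) < 1e-6))
      stop("responses missing shell b = ", b)
  nc <- n_coeffs(lmax)
  idx <- sh_index_table(lmax)
  A <- matrix(0, length(scheme$bvals), nc + 2L)
  B <- basis_matrix(scheme$directions, lmax)
  for (si in seq_along(scheme$shell_bvals)) {
    b <- scheme$shell_bvals[si]
    rows <- which(scheme$shell_id == si)
    kw <- kernel_row(responses$wm, b)
    scale <- sqrt(4 * pi / (2 * idx$l + 1)) * kw[idx$l / 2 + 1L]
    A[rows, seq_len(nc)] <- B[rows, , drop = FALSE] *
      matrix(scale, length(rows), nc, byrow = TRUE)
    # isotropic compartments: the unknown is the degree-0 SH coefficient,
    # so the predicted signal is c * sqrt(4pi) * k0 * Y00 = c * k0
    A[rows, nc + 1L] <- kernel_row(responses$gm, b)[1L]
    A[rows, nc + 2L] <- kernel_row(responses$csf, b)[1L]
  }
  A
}

# default 300-direction hemisphere constraint grid (memoized)
.grid_cache <- new.env(parent = emptyenv())
default_constraint_grid <- function(n = 300L) {
  key <- as.character(n)
  if (is.null(.grid_cache[[key]]))
    .grid_cache[[key]] <- sphere_grid(n, hemisphere = TRUE)
  .grid_cache[[key]]
}

# FOD result container
fod_result <- function(wm_sh, gm, csf, n_iter, residual_norm, converged) {
  structure(list(wm_sh = wm_sh, gm = gm, csf = csf, n_iter = n_iter,
                 residual_norm = residual_norm, converged = converged),
            class = "fod_result")
}

#' @export
print.fod_result <- function(x, ...) {
  cat(sprintf(
    "fod_result: lmax %d, gm %.4g, csf %.4g, residual %.4g, %d iteration(s)%s\n",
    lmax_for_n_coeffs(length(x$wm_sh)), x$gm, x$csf, x$residual_norm,
    x$n_iter, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# solve min 1/2 x' D x - d' x subject to G x >= 0 (Goldfarb-Idnani via
# quadprog) with deterministic constraint pruning: starting from the
# constraints violated or nearly active at the guess `x0`, solve on the
# subset, verify full feasibility, and grow the set until feasible
# (falling back to the full set).  Returns list (x, ok).
qp_nonneg_qd <- function(D, d, G, tG, sel = NULL, max_grow = 2L) {
  n_con <- nrow(G)
  if (is.null(sel)) sel <- seq_len(n_con)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    sol <- tryCatch(
      quadprog::solve.QP(D, d, tG[, sel, drop = FALSE], rep(0, length(sel))),
      error = function(e) NULL)
    if (is.null(sol)) {
      if (length(sel) < n_con) { sel <- seq_len(n_con); next }
      return(list(x = rep(0, ncol(G)), ok = FALSE, active = integer(0)))
    }
    a <- as.numeric(G %*% sol$solution)
    scale <- max(abs(a), 1e-300)
    bad <- which(a < -1e-9 * scale)
    if (length(bad) == 0L || length(sel) == n_con)
      return(list(x = sol$solution, ok = TRUE,
                  active = which(a < 1e-7 * scale)))
    # too many violations or too many passes: give up pruning
    sel <- if (pass > max_grow || length(bad) > 60L) seq_len(n_con)
           else sort(unique(c(sel, bad)))
  }
}

# constraint subset suggested by a guess: the near-zero/violated band
sel_from_guess <- function(G, x0, margin = 0.05, cap = 120L) {
  a0 <- as.numeric(G %*% x0)
  sel <- which(a0 < margin * max(abs(a0), 1e-300))
  if (length(sel) == 0L || length(sel) > cap) NULL else sel
}

# convenience wrapper building the quadratic form from A, s
qp_nonneg <- function(A, s, G, ridge = 1e-10) {
  D <- crossprod(A)
  diag(D) <- diag(D) + ridge * max(diag(D))
  qp_nonneg_qd(D, as.numeric(crossprod(A, s)), G, t(G))
}

# Precomputed per-scheme operators shared by every voxel of a volume.
msmt_precompute <- function(scheme, responses, lmax, grid) {
  A <- build_forward_matrix(scheme, responses, lmax)
  nc <- n_coeffs(lmax)
  Bgrid <- basis_matrix(grid$directions, lmax)
  G <- rbind(cbind(Bgrid, matrix(0, nrow(Bgrid), 2L)),
             c(rep(0, nc), 1, 0), c(rep(0, nc), 0, 1))
  D <- crossprod(A)
  diag(D) <- diag(D) + 1e-10 * max(diag(D))
  list(A = A, nc = nc, G = G, tG = t(G), D = D, qrA = qr(A))
}

msmt_solve <- function(signals, pre, x0 = NULL) {
  if (is.null(x0)) x0 <- qr.coef(pre$qrA, signals)
  sol <- qp_nonneg_qd(pre$D, as.numeric(crossprod(pre$A, signals)),
                      pre$G, pre$tG, sel_from_guess(pre$G, x0))
  x <- sol$x
  fod_result(x[seq_len(pre$nc)], max(0, x[pre$nc + 1L]),
             max(0, x[pre$nc + 2L]), 1L,
             sqrt(sum((pre$A %*% x - signals)^2)), sol$ok)
}

ss3t_precompute <- function(scheme, responses, lmax, grid) {
  A <- build_forward_matrix(scheme, responses, lmax)
  nc <- n_coeffs(lmax)
  Bgrid <- basis_matrix(grid$directions, lmax)
  rows <- which(scheme$bvals > 0)
  A_B <- cbind(A[, seq_len(nc), drop = FALSE], A[, nc + 1L])
  G_B <- rbind(cbind(Bgrid, 0), c(rep(0, nc), 1))
  # the single-shell problem can sit at the identifiability edge (e.g. 44
  # directions for 45 coefficients); a small ridge keeps the quadratic
  # form positive definite and the init solvable
  D_B <- crossprod(A_B)
  diag(D_B) <- diag(D_B) + 1e-8 * max(diag(D_B))
  a_gm <- A[, nc + 1L]; a_csf <- A[, nc + 2L]
  M <- rbind(c(sum(a_gm^2), sum(a_gm * a_csf)),
             c(sum(a_gm * a_csf), sum(a_csf^2)))
  A_nz <- A[rows, seq_len(nc), drop = FALSE]
  init_ridge <- sqrt(1e-8 * max(colSums(A_nz^2))) * diag(nc)
  list(A_wm = A[, seq_len(nc), drop = FALSE], a_gm = a_gm, a_csf = a_csf,
       nc = nc, Bgrid = Bgrid,
       qr_init = qr(rbind(A_nz, init_ridge)), n_init_rows = length(rows),
       qr_grid = qr(Bgrid), rows = rows,
       A_B = A_B, D_B = D_B, tG_B = t(G_B), G_B = G_B,
       tA_B = t(A_B), v_csf = as.numeric(crossprod(A_B, a_csf)),
       Minv = solve(M), gm_nrm2 = M[1, 1], csf_nrm2 = M[2, 2])
}

# exact non-negative LS for the two isotropic compartments, closed form
iso_step <- function(pre, r) {
  rhs <- c(sum(pre$a_gm * r), sum(pre$a_csf * r))
  x <- as.numeric(pre$Minv %*% rhs)
  if (x[1L] >= 0 && x[2L] >= 0) return(x)
  cand <- list(c(max(0, rhs[1L] / pre$gm_nrm2), 0),
               c(0, max(0, rhs[2L] / pre$csf_nrm2)))
  obj <- vapply(cand, function(z)
    sum((pre$a_gm * z[1L] + pre$a_csf * z[2L] - r)^2), numeric(1))
  cand[[which.min(obj)]]
}

ss3t_solve <- function(signals, pre, max_iter, tol) {
  nc <- pre$nc
  w <- qr.coef(pre$qr_init, c(signals[pre$rows], numeric(nc)))
  amp <- pmax(as.numeric(pre$Bgrid %*% w), 0)
  w <- qr.coef(pre$qr_grid, amp)
  g <- 0; cf <- 0
  f_B <- as.numeric(pre$tA_B %*% signals)
  x_prev <- c(w, g, cf)
  converged <- FALSE
  n_iter <- 0L
  sel_B <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # step A: WM fixed, non-negative (gm, csf)
    r <- signals - as.numeric(pre$A_wm %*% w)
    gc <- iso_step(pre, r)
    g <- gc[1L]; cf <- gc[2L]
    # step B: CSF fixed, (wm, gm) under amplitude >= 0 and gm >= 0;
    # warm-started from the previous iteration's active constraint set
    d <- f_B - cf * pre$v_csf
    sol <- qp_nonneg_qd(pre$D_B, d, pre$G_B, pre$tG_B, sel_B)
    if (!sol$ok) break
    sel_B <- if (length(sol$active) > 0L) sol$active else NULL
    w <- sol$x[seq_len(nc)]; g <- sol$x[nc + 1L]
    x <- c(w, g, cf)
    rel <- sqrt(sum((x - x_prev)^2)) / max(sqrt(sum(x^2)), 1e-12)
    x_prev <- x
    if (is.infinite(tol) || rel < tol) { converged <- TRUE; break }
  }
  res <- sqrt(sum((pre$A_wm %*% w + pre$a_gm * g + pre$a_csf * cf -
                     signals)^2))
  fod_result(w, max(0, g), max(0, cf), n_iter, res, converged)
}

#' Multi-shell multi-tissue constrained spherical deconvolution
#'
#' Minimizes `||A x - signals||^2` over `x = [wm_sh, gm, csf]` subject to
#' WM FOD amplitude >= 0 on every constraint-grid direction and gm, csf
#' >= 0, solved as a convex quadratic program (dual active set).
#' Deterministic for fixed inputs.  Requires at least 3 distinct b-values.
#'
#' @param signals per-measurement signal vector.
#' @param scheme a [gradient_scheme()] with >= 3 distinct b-values.
#' @param responses a [response_set()].
#' @param constraint_grid a [sphere_grid()]; default 300 hemisphere
#'   directions.
#' @param lmax WM FOD maximum degree (default 8).
#' @param constrained set FALSE to drop all constraints (plain least
#'   squares; used for oracle comparisons).
#' @return a `fod_result`.
#' @export
msmt_csd <- function(signals, scheme, responses,
                     constraint_grid = default_constraint_grid(),
                     lmax = 8L, constrained = TRUE) {
  if (length(scheme$shell_bvals) < 3L)
    stop("msmt_csd requires at least 3 distinct b-values, got ",
         length(scheme$shell_bvals))
  if (length(signals) != length(scheme$bvals))
    stop("signals length does not match scheme")
  pre <- msmt_precompute(scheme, responses, lmax, constraint_grid)
  if (!constrained) {
    x <- qr.coef(pre$qrA, signals)
    return(fod_result(x[seq_len(pre$nc)], x[pre$nc + 1L], x[pre$nc + 2L], 1L,
                      sqrt(sum((pre$A %*% x - signals)^2)), TRUE))
  }
  msmt_solve(signals, pre)
}

#' Single-shell three-tissue constrained spherical deconvolution
#'
#' Alternating two-step estimation from one non-zero shell plus b0:
#' step A fixes the WM coefficients and solves for the non-negative GM and
#' CSF compartments; step B fixes the CSF compartment and solves for WM
#' (amplitude >= 0 on the constraint grid) and GM (>= 0) jointly; the pair
#' of steps repeats until the relative L2 change of the stacked solution
#' falls below `tol` or `max_iter` is reached.  WM is initialized from an
#' unconstrained single-tissue deconvolution of the non-zero shell with
#' negative amplitudes clipped.
#'
#' @param signals per-measurement signal vector.
#' @param scheme a [gradient_scheme()] with exactly one non-zero shell plus
#'   b0.
#' @param responses a [response_set()] covering both shells.
#' @param max_iter maximum number of (A, B) iterations (default 50).
#' @param tol relative L2 change threshold (default 1e-5); `Inf` returns
#'   after one iteration.
#' @param constraint_grid a [sphere_grid()].
#' @param lmax WM FOD maximum degree (default 8).
#' @return a `fod_result` (with `n_iter` and `converged` reflecting the
#'   alternation); non-convergence is flagged, the last iterate is
#'   returned.
#' @export
ss3t_csd <- function(signals, scheme, responses, max_iter = 50L, tol = 1e-5,
                     constraint_grid = default_constraint_grid(),
                     lmax = 8L) {
  nz <- setdiff(scheme$shell_bvals, 0)
  if (length(nz) != 1L || !any(scheme$shell_bvals == 0))
    stop("ss3t_csd needs exactly one non-zero shell plus b0 (got shells ",
         paste(scheme$shell_bvals, collapse = ", "),
         "); use msmt_csd for multi-shell data")
  if (length(signals) != length(scheme$bvals))
    stop("signals length does not match scheme")
  pre <- ss3t_precompute(scheme, responses, lmax, constraint_grid)
  ss3t_solve(signals, pre, max_iter, tol)
}

#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on `log(signal)` with the 6 unique tensor
#' elements plus log-baseline.  Non-positive signals are clamped at
#' `eps` before the log.
#'
#' @param signals per-measurement signal vector.
#' @param scheme a [gradient_scheme()] with >= 6 non-b0 and >= 1 b0
#'   measurements.
#' @param eps clamp for non-positive signals (default 1e-8).
#' @return 3 x 3 symmetric tensor (mm^2/s).
#' @export
fit_tensor <- function(signals, scheme, eps = 1e-8) {
  nb0 <- sum(scheme$bvals == 0)
  ndw <- sum(scheme$bvals > 0)
  if (nb0 < 1L || ndw < 6L)
    stop("tensor fit needs >= 1 b0 and >= 6 diffusion-weighted measurements")
  g <- scheme$directions; b <- scheme$bvals
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  y <- log(pmax(signals, eps))
  beta <- qr.solve(X, y)
  matrix(c(beta[2], beta[5], beta[6],
           beta[5], beta[3], beta[7],
           beta[6], beta[7], beta[4]), 3, 3)
}

#' Fractional anisotropy of a diffusion tensor
#'
#' Eigenvalues are clamped at 0; the normalized standard deviation formula
#' guarantees FA in [0, 1].
#'
#' @param tensor 3 x 3 symmetric matrix.
#' @return scalar FA.
#' @export
fa <- function(tensor) {
  ev <- pmax(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (sum(ev^2) < .Machine$double.eps) return(0)
  mb <- mean(ev)
  sqrt(3 / 2 * sum((ev - mb)^2) / sum(ev^2))
}

#' White matter mask from FA and optional tissue labels
#'
#' Union of `FA > threshold` and, when labels are supplied, membership in
#' the WM-like label set.
#'
#' @param fa_map 3D numeric array of FA values.
#' @param tissue_label optional 3D character array.
#' @param threshold FA threshold (default 0.25).
#' @param wm_labels labels treated as WM.
#' @return logical 3D array.
#' @export
wm_mask <- function(fa_map, tissue_label = NULL, threshold = 0.25,
                    wm_labels = c("wm_single", "wm_cross2", "wm_cross3")) {
  m <- fa_map > threshold
  if (!is.null(tissue_label)) {
    stopifnot(all(dim(tissue_label) == dim(fa_map)))
    m <- m | array(tissue_label %in% wm_labels, dim = dim(fa_map))
  }
  m
}

#' FA map of a 4D diffusion volume
#'
#' @param dwi 4D array (x, y, z, measurement).
#' @param scheme matching [gradient_scheme()].
#' @return 3D array of FA values.
#' @export
fa_map <- function(dwi, scheme) {
  d <- dim(dwi)
  flat <- matrix(dwi, prod(d[1:3]), d[4L])
  out <- apply(flat, 1L, function(s) fa(fit_tensor(s, scheme)))
  array(out, dim = d[1:3])
}

#' Estimate per-tissue responses from a phantom volume
#'
#' WM kernel: per shell, the mean signal over pure single-fiber voxels is
#' expressed in angle from the (known) fiber axis and fit with zonal SH.
#' GM and CSF kernels: per-shell mean isotropic signals.  On a noiseless
#' phantom this recovers the generating kernels.
#'
#' @param volume a `phantom_volume` containing `wm_single`, `gm` and `csf`
#'   regions.
#' @param lmax even maximum degree of the WM kernel (default 8).
#' @return a [response_set()].
#' @export
estimate_responses_from_phantom <- function(volume, lmax = 8L) {
  lab <- as.vector(volume$tissue_label)
  for (r in c("wm_single", "gm", "csf"))
    if (!any(lab == r)) stop("phantom lacks a ", r, " region")
  scheme <- volume$scheme
  d <- dim(volume$dwi)
  flat <- matrix(volume$dwi, prod(d[1:3]), d[4L])
  mean_sig <- function(region) colMeans(flat[lab == region, , drop = FALSE])
  wm_sig <- mean_sig("wm_single")
  fiber <- volume$gt_peaks[[which(lab == "wm_single")[1L]]][1L, ]
  shells <- scheme$shell_bvals
  nz <- lmax / 2 + 1L
  ls <- seq(0L, lmax, by = 2L)
  wm <- matrix(0, length(shells), nz)
  iso_row <- function(v) c(v * sqrt(4 * pi), rep(0, nz - 1L))
  for (si in seq_along(shells)) {
    rows <- which(scheme$shell_id == si)
    if (shells[si] == 0) {
      wm[si, ] <- iso_row(mean(wm_sig[rows]))
    } else {
      ct <- as.numeric(scheme$directions[rows, , drop = FALSE] %*% fiber)
      Z <- vapply(ls, function(l) {
        P <- pracma::legendre(l, pmin(1, pmax(-1, ct)))
        p0 <- if (is.null(dim(P))) P else P[1L, ]
        sqrt((2 * l + 1) / (4 * pi)) * p0
      }, numeric(length(rows)))
      wm[si, ] <- qr.solve(Z, wm_sig[rows])
    }
  }
  gm_sig <- mean_sig("gm"); csf_sig <- mean_sig("csf")
  gm <- t(vapply(seq_along(shells), function(si)
    iso_row(mean(gm_sig[scheme$shell_id == si])), numeric(nz)))
  csf <- t(vapply(seq_along(shells), function(si)
    iso_row(mean(csf_sig[scheme$shell_id == si])), numeric(nz)))
  response_set(zonal_kernel(wm, shells, lmax),
               zonal_kernel(gm, shells, lmax),
               zonal_kernel(csf, shells, lmax))
}

#' Deconvolve every masked voxel of a diffusion volume
#'
#' Applies [msmt_csd()] or [ss3t_csd()] voxelwise.  For MSMT, voxels whose
#' unconstrained solution already satisfies the constraints (the common
#' case at high SNR) skip the quadratic program; results are independent
#' of evaluation order.
#'
#' @param dwi 4D array (x, y, z, measurement).
#' @param scheme matching [gradient_scheme()].
#' @param responses a [response_set()].
#' @param method `"msmt"` or `"ss3t"`.
#' @param mask logical 3D array (default: all voxels).
#' @param lmax WM FOD maximum degree.
#' @param ... forwarded to the per-voxel solver.
#' @return list of class `fod_volume`: `fod` (an [sh_image()] of WM FODs),
#'   `gm`, `csf` (3D arrays), `n_iter` (3D), `converged` (3D logical).
#' @export
fit_fod_volume <- function(dwi, scheme, responses, method = c("msmt", "ss3t"),
                           mask = NULL, lmax = 8L, ...) {
  method <- match.arg(method)
  d <- dim(dwi)
  if (d[4L] != length(scheme$bvals))
    stop("dwi has ", d[4L], " measurements, scheme has ", length(scheme$bvals))
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  nvox <- prod(d[1:3])
  flat <- matrix(dwi, nvox, d[4L])
  nc <- n_coeffs(lmax)
  coeffs <- matrix(0, nvox, nc)
  gm <- csf <- array(0, dim = d[1:3])
  n_it <- array(0L, dim = d[1:3])
  conv <- array(TRUE, dim = d[1:3])
  vox <- which(as.vector(mask))
  grid <- default_constraint_grid()
  if (method == "msmt") {
    if (length(scheme$shell_bvals) < 3L)
      stop("msmt requires at least 3 distinct b-values")
    pre <- msmt_precompute(scheme, responses, lmax, grid)
    # batch unconstrained solve, then QP only on constraint violators
    Xun <- qr.coef(pre$qrA, t(flat[vox, , drop = FALSE]))
    amp_min <- apply(pre$G[seq_len(nrow(pre$G) - 2L), seq_len(nc)] %*%
                       Xun[seq_len(nc), , drop = FALSE], 2L, min)
    ok <- amp_min >= -1e-10 & Xun[nc + 1L, ] >= -1e-12 &
      Xun[nc + 2L, ] >= -1e-12
    for (j in seq_along(vox)) {
      v <- vox[j]
      if (ok[j]) {
        x <- Xun[, j]
        coeffs[v, ] <- x[seq_len(nc)]
        gm[v] <- max(0, x[nc + 1L]); csf[v] <- max(0, x[nc + 2L])
        n_it[v] <- 0L
      } else {
        r <- msmt_solve(flat[v, ], pre, x0 = Xun[, j])
        coeffs[v, ] <- r$wm_sh; gm[v] <- r$gm; csf[v] <- r$csf
        n_it[v] <- r$n_iter; conv[v] <- r$converged
      }
    }
  } else {
    pre <- ss3t_precompute(scheme, responses, lmax, grid)
    opts <- list(...)
    max_iter <- if (is.null(opts$max_iter)) 50L else opts$max_iter
    tol <- if (is.null(opts$tol)) 1e-5 else opts$tol
    for (v in vox) {
      r <- ss3t_solve(flat[v, ], pre, max_iter, tol)
      coeffs[v, ] <- r$wm_sh; gm[v] <- r$gm; csf[v] <- r$csf
      n_it[v] <- r$n_iter; conv[v] <- r$converged
    }
  }
  structure(list(fod = sh_image(coeffs, lmax, "fod", mask,
                                grid_shape = d[1:3]),
                 gm = gm, csf = csf, n_iter = n_it, converged = conv),
            class = "fod_volume")
}
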