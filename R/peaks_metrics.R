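# FOD peak extraction and the evaluation metric suite: agreement rate (AR),
# angular error (AE), apparent fiber density (AFD) error, and the
# fiber-count confusion matrix.

#' Peak set container
#' @param directions k x 3 matrix of unit vectors (k <= 3).
#' @param amplitudes matching positive amplitudes, descending.
#' @return object of class `peak_set`.
#' @export
peak_set <- function(directions = matrix(0, 0, 3), amplitudes = numeric(0)) {
  structure(list(directions = directions, amplitudes = amplitudes,
                 n = nrow(directions)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set with", x$n, "peak(s)\n")
  if (x$n > 0)
    print(cbind(round(x$directions, 4), amplitude = round(x$amplitudes, 4)))
  invisible(x)
}

# cached dense hemisphere grid + basis for peak extraction
.peak_cache <- new.env(parent = emptyenv())
default_peak_grid <- function(n = 2000L) {
  key <- as.character(n)
  if (is.null(.peak_cache[[key]]))
    .peak_cache[[key]] <- sphere_grid(n, hemisphere = TRUE)
  .peak_cache[[key]]
}

peak_basis <- function(grid, lmax) {
  key <- paste0(nrow(grid$directions), "_", lmax, "_",
                signif(sum(grid$directions[1L, ]), 10))
  if (is.null(.peak_cache[[key]]))
    .peak_cache[[key]] <- basis_matrix(grid$directions, lmax)
  .peak_cache[[key]]
}

# Projected gradient ascent on the SH amplitude for a batch of candidate
# peaks (possibly from different FODs), staying on the unit sphere;
# removes grid quantization from peak directions.  One basis evaluation
# per iteration for all candidates and probes jointly; steps that do not
# improve are rejected and the step size halved.
refine_peaks_batch <- function(C, U, n_iter = 10L, h = 5e-3, step0 = 0.05) {
  n <- nrow(U)
  lmax <- lmax_for_n_coeffs(ncol(C))
  amp_of <- function(dirs, rows) {
    B <- basis_matrix(dirs, lmax)
    rowSums(B * C[rows, , drop = FALSE])
  }
  f <- amp_of(U, seq_len(n))
  step <- rep(step0, n)
  for (it in seq_len(n_iter)) {
    use_z <- abs(U[, 3L]) < 0.9
    a <- cbind(ifelse(use_z, 0, 1), 0, ifelse(use_z, 1, 0))
    e1 <- a - rowSums(a * U) * U
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(U[, 2L] * e1[, 3L] - U[, 3L] * e1[, 2L],
                U[, 3L] * e1[, 1L] - U[, 1L] * e1[, 3L],
                U[, 1L] * e1[, 2L] - U[, 2L] * e1[, 1L])
    probes <- rbind(U + h * e1, U - h * e1, U + h * e2, U - h * e2)
    probes <- probes / sqrt(rowSums(probes^2))
    fp <- amp_of(probes, rep(seq_len(n), 4L))
    g1 <- (fp[seq_len(n)] - fp[n + seq_len(n)]) / (2 * h)
    g2 <- (fp[2L * n + seq_len(n)] - fp[3L * n + seq_len(n)]) / (2 * h)
    cand <- U + step * (g1 * e1 + g2 * e2)
    cand <- cand / sqrt(rowSums(cand^2))
    fc <- amp_of(cand, seq_len(n))
    better <- fc > f
    U[better, ] <- cand[better, , drop = FALSE]
    f[better] <- fc[better]
    step[!better] <- step[!better] / 2
  }
  list(U = U, amp = f)
}

#' Extract FOD peaks
#'
#' Local maxima of the FOD amplitude over a dense hemisphere grid, each
#' refined by a few steps of projected gradient ascent, sorted by
#' amplitude and greedily accepted when at least `min_sep` degrees
#' (antipodally symmetric angle) away from all previously accepted peaks
#' and at least `rel_thresh` times the largest amplitude.  FODs whose
#' amplitude range is below `1e-6 * max(|coeffs|)` (near-isotropic or
#' empty) return an empty set.
#'
#' @param fod SH coefficient vector.
#' @param grid a [sphere_grid()] with >= 2000 hemisphere points
#'   (default 2000).
#' @param min_sep minimum separation angle between accepted peaks, degrees.
#' @param max_peaks maximum number of peaks returned.
#' @param rel_thresh relative peak amplitude threshold.
#' @return a [peak_set()].
#' @export
extract_peaks <- function(fod, grid = default_peak_grid(), min_sep = 45,
                          max_peaks = 3L, rel_thresh = 0.5, .amp = NULL) {
  scale <- max(abs(fod))
  if (scale == 0) return(peak_set())
  lmax <- lmax_for_n_coeffs(length(fod))
  amp <- if (is.null(.amp)) {
    B <- peak_basis(grid, lmax)
    as.numeric(B %*% fod)
  } else .amp
  if (diff(range(amp)) < 1e-6 * scale) return(peak_set())
  nb <- grid$neighbor_index
  nbmax <- amp[nb[, 1L]]
  for (k in seq_len(ncol(nb))[-1L]) nbmax <- pmax(nbmax, amp[nb[, k]])
  cand <- which(amp >= nbmax & amp > 0)
  cand <- prune_candidates(cand, amp, rel_thresh)
  if (length(cand) == 0L) return(peak_set())
  # refinement on scale-normalized coefficients: exactly scale-invariant
  C <- matrix(fod / scale, length(cand), length(fod), byrow = TRUE)
  ref <- refine_peaks_batch(C, grid$directions[cand, , drop = FALSE])
  select_peaks(ref$U, scale * ref$amp, min_sep, max_peaks, rel_thresh)
}

# candidates that can never pass the relative threshold (with a safety
# margin for refinement gains) are dropped before the ascent; at most 8
# candidates per FOD are kept, strongest first
prune_candidates <- function(cand, amp, rel_thresh, margin = 0.8,
                             max_cand = 8L) {
  if (length(cand) == 0L) return(cand)
  a <- amp[cand]
  keep <- a >= margin * rel_thresh * max(a)
  cand <- cand[keep]; a <- a[keep]
  if (length(cand) > max_cand)
    cand <- cand[order(a, decreasing = TRUE)[seq_len(max_cand)]]
  cand
}

# greedy amplitude-ordered acceptance under the separation and relative
# threshold rules
select_peaks <- function(ru, ra, min_sep, max_peaks, rel_thresh) {
  o <- order(ra, decreasing = TRUE)
  ru <- ru[o, , drop = FALSE]; ra <- ra[o]
  acc_u <- matrix(0, 0, 3); acc_a <- numeric(0)
  for (i in seq_along(ra)) {
    if (length(acc_a) >= max_peaks) break
    if (length(acc_a) > 0 && ra[i] < rel_thresh * acc_a[1L]) break
    if (nrow(acc_u) > 0 &&
        any(angular_sep_many(acc_u, ru[i, ]) < min_sep)) next
    acc_u <- rbind(acc_u, ru[i, ]); acc_a <- c(acc_a, ra[i])
  }
  peak_set(acc_u, acc_a)
}

#' Antipodally symmetric angle between two unit vectors
#'
#' @param a,b unit 3-vectors.
#' @return `acos(|a . b|)` in degrees, in [0, 90].
#' @export
angular_sep <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

# vectorized: angles (degrees) between rows of U and vector v
angular_sep_many <- function(U, v) {
  acos(pmin(1, abs(as.numeric(U %*% v)))) * 180 / pi
}

.perms <- list(`1` = list(1L),
               `2` = list(1:2, 2:1),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Mean angular error between matched peak sets
#'
#' Defined only when both sets contain the same number k >= 1 of peaks;
#' peaks are matched by the permutation minimizing the total angle
#' (exhaustive, k <= 3), and the mean matched angle is returned.  A count
#' mismatch returns `NA` (the voxel is excluded from AE aggregation), not
#' an error.
#'
#' @param pred,ref [peak_set()]s.
#' @return mean angle in degrees, or `NA_real_`.
#' @export
match_and_ae <- function(pred, ref) {
  k <- ref$n
  if (k == 0L || pred$n != k) return(NA_real_)
  ang <- matrix(0, k, k)
  for (i in seq_len(k))
    ang[i, ] <- angular_sep_many(ref$directions, pred$directions[i, ])
  best <- Inf
  for (p in .perms[[as.character(k)]]) {
    tot <- sum(ang[cbind(p, seq_len(k))])
    if (tot < best) best <- tot
  }
  best / k
}

#' Agreement rate per fiber-count class
#'
#' `AR(k) = 100 * |pred = k & ref = k| / |ref = k|` over the masked voxels,
#' for k in {1, 2, 3}.  Voxels with zero detected peaks in the reference
#' carry no class; zero-peak predictions for a ref-k voxel count as
#' disagreement when `include_zero_pred = TRUE` (the default here excludes
#' them, matching the confusion-matrix convention).  Classes with no
#' reference voxels are `NA`.
#'
#' @param pred_counts,ref_counts integer vectors/arrays of per-voxel peak
#'   counts.
#' @param mask logical vector/array selecting voxels.
#' @param include_zero_pred if TRUE, voxels where the prediction found no
#'   peaks stay in the denominator.
#' @return named numeric vector `c("1", "2", "3")` of percentages.
#' @export
agreement_rate <- function(pred_counts, ref_counts, mask = NULL,
                           include_zero_pred = FALSE) {
  p <- as.integer(pred_counts); r <- as.integer(ref_counts)
  if (length(p) != length(r)) stop("count vectors disagree in length")
  keep <- if (is.null(mask)) rep(TRUE, length(p)) else as.logical(mask)
  if (!include_zero_pred) keep <- keep & p > 0L
  out <- vapply(1:3, function(k) {
    den <- sum(keep & r == k)
    if (den == 0L) return(NA_real_)
    100 * sum(keep & r == k & p == k) / den
  }, numeric(1))
  names(out) <- as.character(1:3)
  out
}

#' Fiber-count confusion matrix
#'
#' Entry (i, j) is the fraction of included voxels with reference count i
#' and predicted count j; entries sum to 1.  Voxels with zero detected
#' peaks in either volume are excluded; counts are clipped to 3.
#'
#' @param pred_counts,ref_counts per-voxel peak counts.
#' @param mask logical selection; must select at least one voxel with
#'   nonzero counts in both volumes.
#' @return 3 x 3 matrix (rows: reference count, columns: predicted count).
#' @export
fiber_count_confusion <- function(pred_counts, ref_counts, mask = NULL) {
  p <- pmin(as.integer(pred_counts), 3L); r <- pmin(as.integer(ref_counts), 3L)
  keep <- if (is.null(mask)) rep(TRUE, length(p)) else as.logical(mask)
  if (!any(keep)) stop("empty mask")
  keep <- keep & p > 0L & r > 0L
  if (!any(keep)) stop("no voxels with nonzero counts in both volumes")
  M <- matrix(0, 3, 3, dimnames = list(ref = 1:3, pred = 1:3))
  for (i in 1:3) for (j in 1:3)
    M[i, j] <- sum(keep & r == i & p == j)
  M / sum(M)
}

#' Apparent fiber density of an FOD
#'
#' The total FOD integral, `sqrt(4 pi)` times the degree-0 coefficient.
#'
#' @param fod SH coefficient vector (or matrix with one FOD per row).
#' @return scalar (or vector) AFD.
#' @export
afd <- function(fod) {
  if (is.matrix(fod)) sqrt(4 * pi) * fod[, 1L] else sqrt(4 * pi) * fod[1L]
}

#' Mean absolute percentage error of AFD between two FOD volumes
#'
#' `100 * mean(|afd_other - afd_ref| / afd_ref)` over masked voxels whose
#' reference AFD exceeds `eps` (guard against division by zero).
#'
#' @param ref_fods,other_fods [sh_image()]s, or voxel x coefficient
#'   matrices.
#' @param mask logical selection (default: all voxels).
#' @param eps reference-AFD guard (default 1e-8).
#' @return percentage.
#' @export
afd_mape <- function(ref_fods, other_fods, mask = NULL, eps = 1e-8) {
  Rm <- if (inherits(ref_fods, "sh_image")) sh_image_matrix(ref_fods) else ref_fods
  Om <- if (inherits(other_fods, "sh_image")) sh_image_matrix(other_fods) else other_fods
  keep <- if (is.null(mask)) rep(TRUE, nrow(Rm)) else as.logical(mask)
  ar <- afd(Rm); ao <- afd(Om)
  keep <- keep & ar > eps
  if (!any(keep)) stop("no masked voxels with positive reference AFD")
  100 * mean(abs(ao[keep] - ar[keep]) / ar[keep])
}

#' Per-voxel peak extraction over a volume
#'
#' Batched [extract_peaks()] for every masked voxel of an [sh_image()].
#'
#' @param img an [sh_image()] of FODs.
#' @param mask logical selection of voxels (default: all).
#' @param grid,min_sep,max_peaks,rel_thresh as in [extract_peaks()].
#' @return list with `counts` (integer per voxel, 0 outside the mask) and
#'   `sets` (list of [peak_set()]s).
#' @export
extract_peaks_volume <- function(img, mask = NULL, grid = default_peak_grid(),
                                 min_sep = 45, max_peaks = 3L,
                                 rel_thresh = 0.5) {
  M <- sh_image_matrix(img)
  keep <- if (is.null(mask)) rep(TRUE, nrow(M)) else as.logical(mask)
  counts <- integer(nrow(M))
  sets <- vector("list", nrow(M))
  vox <- which(keep)
  if (length(vox) == 0L) return(list(counts = counts, sets = sets))
  B <- peak_basis(grid, img$lmax)
  AMP <- B %*% t(M[vox, , drop = FALSE])   # grid x voxel, one BLAS call
  nb <- grid$neighbor_index
  NBMAX <- AMP[nb[, 1L], , drop = FALSE]
  for (k in seq_len(ncol(nb))[-1L])
    NBMAX <- pmax(NBMAX, AMP[nb[, k], , drop = FALSE])
  scale <- apply(abs(M[vox, , drop = FALSE]), 1L, max)
  rng <- apply(AMP, 2L, function(a) diff(range(a)))
  flat <- scale == 0 | rng < 1e-6 * pmax(scale, .Machine$double.xmin)
  ispeak <- AMP >= NBMAX & AMP > 0
  ispeak[, flat] <- FALSE
  ci <- which(ispeak, arr.ind = TRUE)     # grid point, voxel-column pairs
  if (nrow(ci) > 0L) {
    pruned <- unlist(lapply(split(seq_len(nrow(ci)), ci[, 2L]), function(rows)
      rows[match(prune_candidates(ci[rows, 1L], AMP[, ci[rows[1L], 2L]],
                                  rel_thresh), ci[rows, 1L])]))
    ci <- ci[sort(pruned), , drop = FALSE]
  }
  if (nrow(ci) > 0L) {
    cscale <- scale[ci[, 2L]]
    ref <- refine_peaks_batch(M[vox[ci[, 2L]], , drop = FALSE] / cscale,
                              grid$directions[ci[, 1L], , drop = FALSE])
    by_vox <- split(seq_len(nrow(ci)), ci[, 2L])
    for (jc in names(by_vox)) {
      j <- as.integer(jc); rows <- by_vox[[jc]]
      ps <- select_peaks(ref$U[rows, , drop = FALSE],
                         cscale[rows] * ref$amp[rows],
                         min_sep, max_peaks, rel_thresh)
      counts[vox[j]] <- ps$n
      sets[[vox[j]]] <- ps
    }
  }
  for (v in vox) if (is.null(sets[[v]])) sets[[v]] <- peak_set()
  list(counts = counts, sets = sets)
}

#' Compare two FOD volumes
#'
#' Extracts peaks voxelwise from both volumes and aggregates the full
#' metric suite: per-class agreement rate, per-class mean angular error
#' over voxels with agreeing counts, AFD MAPE, and the normalized
#' fiber-count confusion matrix.  The first argument is the reference for
#' AR classes and the MAPE denominator.
#'
#' @param ref,other [sh_image()] FOD volumes (a `fod_volume` from
#'   [fit_fod_volume()] is also accepted).
#' @param mask logical 3D array (default: intersection of the images'
#'   masks).
#' @param min_sep,max_peaks,rel_thresh peak-extraction parameters.
#' @param grid peak-extraction [sphere_grid()].
#' @return object of class `metrics_report`: fields `ar`, `ae` (named by
#'   fiber count), `afd_mape`, `confusion`, `n_voxels`.
#' @export
compare_fod_volumes <- function(ref, other, mask = NULL, min_sep = 45,
                                max_peaks = 3L, rel_thresh = 0.5,
                                grid = default_peak_grid()) {
  if (inherits(ref, "fod_volume")) ref <- ref$fod
  if (inherits(other, "fod_volume")) other <- other$fod
  stopifnot(inherits(ref, "sh_image"), inherits(other, "sh_image"),
            all(ref$grid_shape == other$grid_shape))
  if (is.null(mask)) mask <- ref$mask & other$mask
  keep <- as.logical(mask)
  pr <- extract_peaks_volume(ref, keep, grid, min_sep, max_peaks, rel_thresh)
  po <- extract_peaks_volume(other, keep, grid, min_sep, max_peaks, rel_thresh)
  ar <- agreement_rate(po$counts, pr$counts, keep)
  ae <- vapply(1:3, function(k) {
    vs <- which(keep & pr$counts == k & po$counts == k)
    if (length(vs) == 0L) return(NA_real_)
    mean(vapply(vs, function(v) match_and_ae(po$sets[[v]], pr$sets[[v]]),
                numeric(1)))
  }, numeric(1))
  names(ae) <- as.character(1:3)
  conf <- fiber_count_confusion(po$counts, pr$counts, keep)
  mape <- afd_mape(ref, other, keep)
  structure(list(ar = ar, ae = ae, afd_mape = mape, confusion = conf,
                 n_voxels = sum(keep)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("metrics_report over", x$n_voxels, "voxels\n")
  tab <- rbind(`AR (%)` = x$ar, `AE (deg)` = x$ae)
  colnames(tab) <- paste0(1:3, "-fiber")
  print(round(tab, digits))
  cat("AFD MAPE (%):", round(x$afd_mape, digits), "\n")
  cat("confusion (fraction of voxels, rows = reference count):\n")
  print(round(x$confusion, 4))
  invisible(x)
}
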