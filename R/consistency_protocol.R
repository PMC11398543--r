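# Split-half ground-truth consistency: divide the acquisition into two
# disjoint, angularly balanced halves, reconstruct FODs from each half
# with the same deconvolution method, and score their mutual agreement.

#' Split protocol definition
#'
#' The canonical per-shell half counts: the multi-shell protocol takes 150
#' measurements per half (10 b0, 32 b400, 44 b1000, 64 b2600); the
#' single-shell protocol takes 54 per half (10 b0, 44 b1000).
#'
#' @param method `"msmt"` or `"ss3t"`.
#' @param half_counts optional named vector (names = shell b-values as
#'   characters) overriding the canonical per-half counts.
#' @param seed integer seed for the within-shell assignment.
#' @param balanced if TRUE (default), directions are dealt alternately
#'   along the hemisphere spiral order before seeded tie shuffling; if
#'   FALSE the split is purely seeded-random.
#' @return object of class `split_protocol`.
#' @export
split_protocol <- function(method = c("msmt", "ss3t"), half_counts = NULL,
                           seed = 1L, balanced = TRUE) {
  method <- match.arg(method)
  if (is.null(half_counts))
    half_counts <- switch(method,
      msmt = c(`0` = 10L, `400` = 32L, `1000` = 44L, `2600` = 64L),
      ss3t = c(`0` = 10L, `1000` = 44L))
  structure(list(method = method, half_counts = half_counts,
                 seed = as.integer(seed), balanced = balanced),
            class = "split_protocol")
}

#' Split a gradient scheme into two disjoint equivalent halves
#'
#' Within each shell of the protocol, measurements are ordered along the
#' hemisphere spiral (polar angle as primary key; a space-filling ordering
#' of the hemisphere) and dealt alternately into the two halves so that
#' both halves cover the sphere evenly; a seeded permutation decides which
#' half takes the even positions per shell.  With `balanced = FALSE` the
#' within-shell assignment is a seeded random draw.  Shells larger than
#' twice the requested count are first subsampled (seeded) to exactly
#' twice the count.
#'
#' @param scheme a [gradient_scheme()].
#' @param protocol a [split_protocol()].
#' @return list with `a`, `b` (gradient schemes), `idx_a`, `idx_b`
#'   (measurement indices into `scheme`).
#' @export
split_scheme <- function(scheme, protocol) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(protocol$seed)
  idx_a <- integer(0); idx_b <- integer(0)
  for (bname in names(protocol$half_counts)) {
    bval <- as.numeric(bname)
    cnt <- protocol$half_counts[[bname]]
    shell <- which(abs(scheme$bvals - bval) < 50)
    if (2L * cnt > length(shell))
      stop("protocol needs 2 x ", cnt, " measurements at b = ", bval,
           " but the scheme has ", length(shell))
    if (length(shell) > 2L * cnt)
      shell <- sort(sample(shell, 2L * cnt))
    if (bval == 0 || !protocol$balanced) {
      perm <- sample(length(shell))
    } else {
      # spiral order: polar angle is monotone along the Fibonacci spiral;
      # dealing alternately yields two evenly spread half sets
      perm <- order(scheme$directions[shell, 3L],
                    atan2(scheme$directions[shell, 2L],
                          scheme$directions[shell, 1L]))
    }
    first_a <- sample(2L, 1L) == 1L
    ev <- perm[seq(1L, length(perm), by = 2L)]
    od <- perm[seq(2L, length(perm), by = 2L)]
    if (first_a) {
      idx_a <- c(idx_a, shell[ev]); idx_b <- c(idx_b, shell[od])
    } else {
      idx_a <- c(idx_a, shell[od]); idx_b <- c(idx_b, shell[ev])
    }
  }
  idx_a <- sort(idx_a); idx_b <- sort(idx_b)
  list(a = scheme_subset(scheme, idx_a), b = scheme_subset(scheme, idx_b),
       idx_a = idx_a, idx_b = idx_b)
}

#' Ground-truth consistency of a deconvolution method
#'
#' Splits the volume's acquisition per the protocol, reconstructs FODs on
#' each half with the protocol's method, and compares the two half
#' reconstructions with the full metric suite.
#'
#' @param volume a `phantom_volume` (or a list with `dwi`, `scheme`).
#' @param protocol a [split_protocol()].
#' @param responses a [response_set()] covering the full shell list;
#'   per-half responses are taken on the half's shells.
#' @param mask logical 3D array of voxels to score (default: FA > 0.25
#'   white matter mask union tissue labels when available).
#' @param ... solver options forwarded to [fit_fod_volume()] (e.g. `tol`,
#'   `max_iter` for ss3t).
#' @return a `metrics_report` (see [compare_fod_volumes()]) with the two
#'   half `fod_volume`s attached as attributes `half_a`, `half_b`.
#' @export
gt_consistency <- function(volume, protocol, responses, mask = NULL, ...) {
  sp <- split_scheme(volume$scheme, protocol)
  if (is.null(mask)) {
    lab <- if (!is.null(volume$tissue_label)) volume$tissue_label else NULL
    fam <- fa_map(volume$dwi, volume$scheme)
    mask <- wm_mask(fam, lab)
  }
  method <- protocol$method
  resp_for <- function(sub) {
    keep <- vapply(sub$shell_bvals, function(b)
      which(abs(responses$shell_bvals - b) < 1e-6), integer(1))
    sub_k <- function(k) zonal_kernel(k$coef[keep, , drop = FALSE],
                                      responses$shell_bvals[keep], k$lmax)
    response_set(sub_k(responses$wm), sub_k(responses$gm),
                 sub_k(responses$csf))
  }
  fa_vol <- fit_fod_volume(volume$dwi[, , , sp$idx_a, drop = FALSE], sp$a,
                           resp_for(sp$a), method, mask, ...)
  fb_vol <- fit_fod_volume(volume$dwi[, , , sp$idx_b, drop = FALSE], sp$b,
                           resp_for(sp$b), method, mask, ...)
  rep <- compare_fod_volumes(fa_vol, fb_vol, mask)
  attr(rep, "half_a") <- fa_vol
  attr(rep, "half_b") <- fb_vol
  attr(rep, "protocol") <- protocol
  rep
}
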