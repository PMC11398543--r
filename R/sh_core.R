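# Real, even-order, antipodally symmetric spherical harmonic basis.
#
# Convention used throughout the package (documented once, here):
# coefficients are ordered by ascending even degree l in {0, 2, ..., lmax},
# within a degree by ascending order m in {-l, ..., l}.  The basis functions
# are the real orthonormal spherical harmonics
#   Y_{l,0}           = N_{l,0} P_l^0(cos theta)
#   Y_{l,m},  m > 0   = sqrt(2) N_{l,m}  P_l^m(cos theta)  cos(m phi)
#   Y_{l,m},  m < 0   = sqrt(2) N_{l,|m|} P_l^|m|(cos theta) sin(|m| phi)
# with N_{l,m} = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) and associated Legendre
# functions carrying the Condon-Shortley phase (the Matlab convention
# implemented by pracma::legendre).  Only even degrees are used, so every
# basis function is antipodally symmetric: Y(g) = Y(-g) exactly.

#' Number of even-order spherical harmonic coefficients
#'
#' @param lmax even, non-negative maximum harmonic degree.
#' @return `(lmax + 1) * (lmax + 2) / 2`, e.g. 45 for `lmax = 8`,
#'   15 for `lmax = 4`.
#' @export
n_coeffs <- function(lmax) {
  if (length(lmax) != 1L || lmax < 0 || lmax %% 2L != 0)
    stop("lmax must be a single even non-negative integer, got ", lmax)
  as.integer((lmax + 1L) * (lmax + 2L) / 2L)
}

#' Degree and order index table for the SH coefficient ordering
#'
#' @param lmax even maximum degree.
#' @return data.frame with columns `l` and `m`, one row per coefficient, in
#'   the package's canonical ordering (ascending l, within l ascending m).
#' @export
sh_index_table <- function(lmax) {
  ls <- seq(0L, lmax, by = 2L)
  l <- rep(ls, times = 2L * ls + 1L)
  m <- unlist(lapply(ls, function(li) seq(-li, li)))
  data.frame(l = l, m = m)
}

#' Maximum even SH degree resolvable by a coefficient count
#' @param n number of coefficients, must equal `n_coeffs(lmax)` for some even lmax.
#' @return the even lmax.
#' @export
lmax_for_n_coeffs <- function(n) {
  lmax <- 0L
  while (n_coeffs(lmax) < n) lmax <- lmax + 2L
  if (n_coeffs(lmax) != n)
    stop("no even lmax has ", n, " coefficients")
  lmax
}

# directions as an N x 3 matrix of unit rows; accepts a single vector too
as_direction_matrix <- function(directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be N x 3")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("directions must be unit vectors (max deviation ",
         signif(max(abs(nrm - 1)), 3), ")")
  directions
}

#' Real even-order SH basis matrix
#'
#' Evaluates every basis function of the canonical ordering at each
#' direction.  Rows for antipodal directions are identical (even degrees
#' only).
#'
#' @param directions N x 3 matrix of unit vectors (a single vector is
#'   accepted).
#' @param lmax even maximum degree.
#' @return N x `n_coeffs(lmax)` matrix.
#' @export
basis_matrix <- function(directions, lmax) {
  g <- as_direction_matrix(directions)
  n <- nrow(g)
  ct <- pmin(1, pmax(-1, g[, 3L]))          # cos(theta)
  phi <- atan2(g[, 2L], g[, 1L])
  P <- assoc_legendre(lmax, ct)             # list P[[l+1]][[m+1]], vectors
  B <- matrix(0, n, n_coeffs(lmax))
  col <- 1L
  for (l in seq(0L, lmax, by = 2L)) {
    for (m in seq(-l, l)) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      Plm <- P[[l + 1L]][[am + 1L]]
      if (m == 0L) {
        B[, col] <- N * Plm
      } else if (m > 0L) {
        B[, col] <- sqrt(2) * N * Plm * cos(am * phi)
      } else {
        B[, col] <- sqrt(2) * N * Plm * sin(am * phi)
      }
      col <- col + 1L
    }
  }
  B
}

# associated Legendre functions P_l^m(x) for all l <= lmax, 0 <= m <= l,
# Condon-Shortley phase, by the standard three-term recurrences; vectorized
# over x.  Returns a nested list indexed [[l+1]][[m+1]].
assoc_legendre <- function(lmax, x) {
  sx <- sqrt(pmax(0, 1 - x^2))
  out <- vector("list", lmax + 1L)
  for (l in 0:lmax) out[[l + 1L]] <- vector("list", l + 1L)
  # P_m^m and P_{m+1}^m seeds, then upward recurrence in l
  for (m in 0:lmax) {
    pmm <- if (m == 0L) rep(1, length(x))
           else (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * sx^m
    out[[m + 1L]][[m + 1L]] <- pmm
    if (m < lmax) {
      pm1 <- x * (2 * m + 1) * pmm
      out[[m + 2L]][[m + 1L]] <- pm1
      if (m + 2L <= lmax) {
        pprev <- pmm; pcur <- pm1
        for (l in (m + 2L):lmax) {
          pnext <- ((2 * l - 1) * x * pcur - (l + m - 1) * pprev) / (l - m)
          out[[l + 1L]][[m + 1L]] <- pnext
          pprev <- pcur; pcur <- pnext
        }
      }
    }
  }
  out
}

# Laplace-Beltrami penalty diagonal: (l (l+1))^2 per coefficient
lb_penalty <- function(lmax) {
  idx <- sh_index_table(lmax)
  (idx$l * (idx$l + 1))^2
}

#' Fit SH coefficients to sampled amplitudes
#'
#' Regularized linear least squares: minimizes
#' `||B c - a||^2 + reg * c' L c` with `L` the squared Laplace-Beltrami
#' operator diagonal `(l(l+1))^2`.  With `reg = 0` this is ordinary least
#' squares and requires at least `n_coeffs(lmax)` directions.
#'
#' @param amplitudes numeric vector (length N) or N-column matrix whose rows
#'   are separate functions to fit.
#' @param directions N x 3 unit vectors paired with `amplitudes`.
#' @param lmax even maximum degree of the fit.
#' @param reg non-negative Laplace-Beltrami regularization weight
#'   (default 0; signal fits in this package use 0.006).
#' @return coefficient vector (or matrix with one row per input row).
#' @export
fit_sh <- function(amplitudes, directions, lmax, reg = 0) {
  B <- basis_matrix(directions, lmax)
  nc <- ncol(B)
  if (reg <= 0 && nrow(B) < nc)
    stop("underdetermined SH fit: ", nrow(B), " directions for ", nc,
         " coefficients and reg = 0")
  A <- crossprod(B) + reg * diag(lb_penalty(lmax), nc)
  y <- if (is.matrix(amplitudes)) t(amplitudes) else amplitudes
  cf <- solve(A, crossprod(B, y))
  if (is.matrix(amplitudes)) t(cf) else as.numeric(cf)
}

#' Evaluate SH coefficients at directions
#'
#' @param coeffs coefficient vector (canonical ordering) or matrix with one
#'   row per function.
#' @param directions N x 3 unit vectors.
#' @return amplitude vector of length N (or matrix, functions x N).
#' @export
evaluate_sh <- function(coeffs, directions) {
  lmax <- lmax_for_n_coeffs(if (is.matrix(coeffs)) ncol(coeffs) else length(coeffs))
  B <- basis_matrix(directions, lmax)
  if (is.matrix(coeffs)) coeffs %*% t(B) else as.numeric(B %*% coeffs)
}

#' Zonal SH projection of an axially symmetric tensor signal
#'
#' Projects the single-fiber tensor signal
#' `exp(-b (radial + (axial - radial) cos^2 theta))` for a fiber along +z
#' onto the m = 0 spherical harmonics by Gauss-Legendre quadrature in
#' cos(theta) (64 nodes, exact for the band limits used here).
#'
#' @param axial,radial tensor eigenvalues in mm^2/s, `axial >= radial > 0`.
#' @param bval b-value in s/mm^2.
#' @param lmax even maximum degree.
#' @return vector of length `lmax/2 + 1`: the coefficient of `Y_{l,0}` for
#'   l = 0, 2, ..., lmax.
#' @export
zonal_from_tensor <- function(axial, radial, bval, lmax) {
  if (radial <= 0 || axial < radial)
    stop("need axial >= radial > 0")
  gl <- pracma::gaussLegendre(64, -1, 1)
  f <- exp(-bval * (radial + (axial - radial) * gl$x^2))
  vapply(seq(0L, lmax, by = 2L), function(l) {
    N <- sqrt((2 * l + 1) / (4 * pi))
    Pl <- pracma::legendre(l, gl$x)
    P0 <- if (is.null(dim(Pl))) Pl else Pl[1L, ]
    2 * pi * N * sum(gl$w * f * P0)
  }, numeric(1))
}

#' Zonal kernel: per-shell axially symmetric response
#'
#' @param coef_by_shell matrix (n_shells x (lmax/2 + 1)) or list of vectors of
#'   zonal coefficients, one row/element per shell.
#' @param shell_bvals the b-values the rows correspond to.
#' @param lmax even maximum degree represented.
#' @return object of class `zonal_kernel`.
#' @export
zonal_kernel <- function(coef_by_shell, shell_bvals, lmax) {
  if (is.list(coef_by_shell)) coef_by_shell <- do.call(rbind, coef_by_shell)
  coef_by_shell <- as.matrix(coef_by_shell)
  if (ncol(coef_by_shell) != lmax / 2 + 1)
    stop("kernel rows must have lmax/2 + 1 = ", lmax / 2 + 1, " coefficients")
  if (nrow(coef_by_shell) != length(shell_bvals))
    stop("one coefficient row per shell b-value required")
  structure(list(coef = coef_by_shell, shell_bvals = as.numeric(shell_bvals),
                 lmax = as.integer(lmax)),
            class = "zonal_kernel")
}

kernel_row <- function(kernel, bval) {
  i <- which(abs(kernel$shell_bvals - bval) < 1e-6)
  if (length(i) != 1L)
    stop("kernel has no (unique) shell at b = ", bval)
  kernel$coef[i, ]
}

#' Spherical convolution of an FOD with a zonal kernel
#'
#' Funk-Hecke per-degree scaling: the signal coefficient is
#' `fod_{l,m} * sqrt(4 pi / (2 l + 1)) * k_l` where `k_l` is the kernel's
#' zonal coefficient at degree l on the requested shell.
#'
#' @param fod SH coefficient vector of the FOD.
#' @param kernel a [zonal_kernel()].
#' @param bval which shell of the kernel to convolve with.
#' @return SH coefficient vector of the predicted signal (same lmax as `fod`).
#' @export
spherical_convolution <- function(fod, kernel, bval) {
  lmax <- lmax_for_n_coeffs(length(fod))
  if (kernel$lmax < lmax) stop("kernel lmax smaller than FOD lmax")
  k <- kernel_row(kernel, bval)
  idx <- sh_index_table(lmax)
  scale <- sqrt(4 * pi / (2 * idx$l + 1)) * k[idx$l / 2 + 1L]
  fod * scale
}

#' Deterministic near-uniform sphere grid with neighbor index
#'
#' Spherical Fibonacci point set.  With `hemisphere = TRUE` (the default) the
#' points tile the upper hemisphere (z > 0), which is the natural domain for
#' antipodally symmetric functions; angular distances used for the neighbor
#' index are antipodally symmetric.
#'
#' @param n number of points.
#' @param hemisphere logical; upper hemisphere (default) or full sphere.
#' @param k_neighbors number of nearest neighbors stored per point.
#' @return object of class `sphere_grid`: list with `directions` (n x 3) and
#'   `neighbor_index` (n x k matrix of row indices).
#' @export
sphere_grid <- function(n, hemisphere = TRUE, k_neighbors = 8L) {
  dirs <- fibonacci_directions(n, hemisphere = hemisphere)
  ad <- abs(tcrossprod(dirs))          # antipodal |dot|
  diag(ad) <- -Inf
  nb <- t(apply(ad, 1L, function(r) order(r, decreasing = TRUE)[seq_len(k_neighbors)]))
  structure(list(directions = dirs, neighbor_index = nb),
            class = "sphere_grid")
}

#' Volumetric SH coefficient image
#'
#' A light container for per-voxel SH coefficient vectors on a 3D grid,
#' used both for signal representations (network inputs) and FODs.
#'
#' @param coeffs 4D array (x, y, z, coefficient) in the canonical ordering,
#'   or a voxel x coefficient matrix together with `grid_shape`.
#' @param lmax even maximum degree; inferred from the coefficient count if
#'   omitted.
#' @param provenance `"signal"` or `"fod"`.
#' @param mask logical 3D array (default: all TRUE).
#' @param grid_shape required when `coeffs` is a matrix.
#' @return object of class `sh_image` with fields `coeffs` (4D array),
#'   `grid_shape`, `lmax`, `provenance`, `mask`.
#' @export
sh_image <- function(coeffs, lmax = NULL, provenance = c("fod", "signal"),
                     mask = NULL, grid_shape = NULL) {
  provenance <- match.arg(provenance)
  if (is.matrix(coeffs)) {
    if (is.null(grid_shape)) stop("grid_shape required for matrix input")
    stopifnot(nrow(coeffs) == prod(grid_shape))
    coeffs <- array(coeffs, dim = c(grid_shape, ncol(coeffs)))
  }
  d <- dim(coeffs)
  if (length(d) != 4L) stop("coeffs must be a 4D array")
  if (is.null(lmax)) lmax <- lmax_for_n_coeffs(d[4L])
  if (n_coeffs(lmax) != d[4L])
    stop("coefficient count ", d[4L], " inconsistent with lmax ", lmax)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  structure(list(coeffs = coeffs, grid_shape = d[1:3], lmax = as.integer(lmax),
                 provenance = provenance, mask = mask),
            class = "sh_image")
}

#' @export
print.sh_image <- function(x, ...) {
  cat("sh_image (", x$provenance, "): ",
      paste(x$grid_shape, collapse = " x "), " voxels, lmax ", x$lmax,
      " (", n_coeffs(x$lmax), " coefficients), ",
      sum(x$mask), " masked voxels\n", sep = "")
  invisible(x)
}

# voxel x coefficient matrix view of an sh_image
sh_image_matrix <- function(img) {
  matrix(img$coeffs, prod(img$grid_shape), dim(img$coeffs)[4L])
}

#' Spherical Fibonacci directions
#'
#' @param n number of points.
#' @param hemisphere if TRUE, z ranges over (0, 1); otherwise (-1, 1).
#' @return n x 3 matrix of unit vectors; bit-identical across calls.
#' @export
fibonacci_directions <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  st <- sqrt(pmax(0, 1 - z^2))
  cbind(x = st * cos(phi), y = st * sin(phi), z = z)
}
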