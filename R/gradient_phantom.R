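# Synthetic acquisition scheme and multi-compartment crossing-fiber phantom.
#
# The phantom emulates a neonatal-style multi-shell acquisition: shells at
# b = 0, 400, 1000, 2600 s/mm^2 with 20, 64, 88 and 128 measurements, and a
# `maturation` parameter in [0, 1] that jointly controls white matter
# anisotropy and the white/gray matter diffusion contrast.  At low maturation
# the mean gray matter signal on every non-zero shell lies inside the range
# of white matter voxel signals (the low-contrast regime typical of
# developing brains); at high maturation the tissues separate.

#' Gradient scheme constructor
#'
#' @param bvals numeric vector of per-measurement b-values (s/mm^2).
#' @param directions N x 3 matrix of unit vectors (b = 0 rows hold a
#'   placeholder unit vector).
#' @param shell_tol b-values closer than this are grouped into one shell.
#' @return object of class `gradient_scheme` with fields `bvals`,
#'   `directions`, `shell_id` and `shell_bvals` (ascending).
#' @export
gradient_scheme <- function(bvals, directions, shell_tol = 50) {
  directions <- as_direction_matrix(directions)
  if (length(bvals) != nrow(directions))
    stop("bvals (", length(bvals), ") and directions (", nrow(directions),
         ") disagree in length")
  # single-linkage clustering on the sorted b-values: a gap larger than
  # shell_tol between consecutive values starts a new shell
  ub <- sort(unique(bvals))
  cluster <- cumsum(c(1, diff(ub) > shell_tol))
  centers <- vapply(seq_len(max(cluster)),
                    function(i) mean(ub[cluster == i]), numeric(1))
  shell_id <- vapply(bvals, function(b) which.min(abs(centers - b)), integer(1))
  shell_bvals <- vapply(seq_along(centers),
                        function(i) mean(bvals[shell_id == i]), numeric(1))
  structure(list(bvals = as.numeric(bvals), directions = directions,
                 shell_id = as.integer(shell_id),
                 shell_bvals = as.numeric(shell_bvals)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvals), "measurements,",
      length(x$shell_bvals), "shells\n")
  for (i in seq_along(x$shell_bvals))
    cat(sprintf("  b = %6.0f : %3d measurements\n", x$shell_bvals[i],
                sum(x$shell_id == i)))
  invisible(x)
}

#' Subset a gradient scheme by measurement index
#' @param scheme a [gradient_scheme()].
#' @param idx measurement indices to keep.
#' @return a `gradient_scheme` over the kept measurements.
#' @export
scheme_subset <- function(scheme, idx) {
  gradient_scheme(scheme$bvals[idx], scheme$directions[idx, , drop = FALSE])
}

#' Canonical 4-shell neonatal-style acquisition scheme
#'
#' Shells b = 0, 400, 1000, 2600 s/mm^2 with 20, 64, 88 and 128
#' measurements (300 in total).  Per-shell directions are deterministic
#' hemisphere spherical-Fibonacci point sets (near-uniform, antipodally
#' unique); b = 0 rows carry the +z placeholder.  Repeated calls are
#' bit-identical.
#'
#' @return a [gradient_scheme()].
#' @export
make_dhcp_scheme <- function() {
  shells <- c(0, 400, 1000, 2600)
  counts <- c(20L, 64L, 88L, 128L)
  bvals <- rep(shells, counts)
  dirs <- do.call(rbind, lapply(seq_along(shells), function(i) {
    if (shells[i] == 0) {
      matrix(rep(c(0, 0, 1), counts[i]), ncol = 3, byrow = TRUE)
    } else {
      fibonacci_directions(counts[i], hemisphere = TRUE)
    }
  }))
  gradient_scheme(bvals, dirs)
}

#' Compartment constructors
#'
#' A voxel is a mixture of compartments whose volume fractions sum to 1:
#' `fiber_compartment` is an axially symmetric diffusion tensor along
#' `orientation`; `iso_compartment` is isotropic (gray matter or CSF).
#'
#' @param orientation unit 3-vector (fiber).
#' @param fraction volume fraction in [0, 1].
#' @param axial,radial tensor eigenvalues, mm^2/s, `axial >= radial > 0`.
#' @param kind `"gm"` or `"csf"` (isotropic compartments).
#' @param diffusivity isotropic diffusivity, mm^2/s.
#' @return a list of class `compartment_spec`.
#' @export
fiber_compartment <- function(orientation, fraction, axial = 1.7e-3,
                              radial = 0.5e-3) {
  if (fraction < 0) stop("negative fraction")
  if (radial <= 0 || axial < radial) stop("need axial >= radial > 0")
  orientation <- as.numeric(orientation)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(kind = "fiber", orientation = orientation,
                 axial = axial, radial = radial, fraction = fraction),
            class = "compartment_spec")
}

#' @rdname fiber_compartment
#' @export
iso_compartment <- function(kind = c("gm", "csf"), diffusivity, fraction) {
  kind <- match.arg(kind)
  if (fraction < 0) stop("negative fraction")
  if (diffusivity <= 0) stop("diffusivity must be positive")
  structure(list(kind = kind, isotropic_diffusivity = diffusivity,
                 fraction = fraction),
            class = "compartment_spec")
}

#' Noiseless multi-compartment voxel signal
#'
#' Multi-tensor forward model: each fiber compartment contributes
#' `s0 f exp(-b g' D g)` with an axially symmetric tensor, each isotropic
#' compartment `s0 f exp(-b d)`.
#'
#' @param compartments list of [fiber_compartment()] / [iso_compartment()];
#'   fractions must sum to 1 (within 1e-9).
#' @param scheme a [gradient_scheme()].
#' @param s0 baseline (b = 0) signal.
#' @return numeric vector, one signal per measurement.
#' @export
simulate_voxel <- function(compartments, scheme, s0 = 1) {
  fr <- vapply(compartments, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("compartment fractions sum to ", sum(fr), ", not 1")
  sig <- numeric(length(scheme$bvals))
  b <- scheme$bvals
  for (cmp in compartments) {
    if (cmp$kind == "fiber") {
      ug <- as.numeric(scheme$directions %*% cmp$orientation)
      sig <- sig + cmp$fraction *
        exp(-b * (cmp$radial + (cmp$axial - cmp$radial) * ug^2))
    } else {
      sig <- sig + cmp$fraction * exp(-b * cmp$isotropic_diffusivity)
    }
  }
  s0 * sig
}

#' Rician noise
#'
#' Returns `|signal + n1 + i n2|` with independent zero-mean Gaussian
#' components of standard deviation `sigma = s0 / snr` (noise referenced to
#' the b = 0 signal, the usual dMRI convention).  `snr = Inf` returns the
#' input unchanged.  Seeded and reproducible.
#'
#' @param signal non-negative numeric vector (or array).
#' @param snr signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed integer RNG seed.
#' @param s0 the baseline signal defining the noise scale.
#' @return numeric object shaped like `signal`.
#' @export
add_rician_noise <- function(signal, snr, seed, s0 = 1) {
  if (is.infinite(snr)) return(signal)
  if (snr <= 0) stop("snr must be positive or Inf")
  sigma <- s0 / snr
  # deterministic local RNG without disturbing the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(signal)
  noised <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                   stats::rnorm(n, 0, sigma)^2)
  attributes(noised) <- attributes(signal)
  noised
}

# Per-degree Hann apodization of the band-limited delta: suppresses the
# ringing (negative lobes) of a hard SH truncation.
apodization_taper <- function(lmax) {
  l <- seq(0L, lmax, by = 2L)
  0.5 * (1 + cos(pi * l / (lmax + 2)))
}

# Non-negative apodized delta taper.  Starting from the Hann-tapered
# band-limited delta (zonal, so one profile in cos(theta) suffices), 300
# rounds of alternating projection between the non-negative cone and the
# even band-limited zonal subspace, a degree-0 offset absorbing the
# residual negativity, and normalization to unit integral.  Memoized; the
# result is deterministic.
.taper_cache <- new.env(parent = emptyenv())
nonneg_delta_taper <- function(lmax) {
  key <- as.character(lmax)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  gl <- pracma::gaussLegendre(128, -1, 1)
  ls <- seq(0L, lmax, by = 2L)
  Z <- vapply(ls, function(l) {
    P <- pracma::legendre(l, gl$x)
    p0 <- if (is.null(dim(P))) P else P[1L, ]
    sqrt((2 * l + 1) / (4 * pi)) * p0
  }, numeric(length(gl$x)))
  z <- apodization_taper(lmax) * sqrt((2 * ls + 1) / (4 * pi))
  for (it in seq_len(300L)) {
    f <- pmax(as.numeric(Z %*% z), 0)
    z <- 2 * pi * as.numeric(crossprod(Z, gl$w * f))
  }
  f <- as.numeric(Z %*% z)
  z[1L] <- z[1L] + max(0, -min(f)) * sqrt(4 * pi)   # lift residual negativity
  z <- z / (z[1L] * sqrt(4 * pi))                    # unit integral
  taper <- z / sqrt((2 * ls + 1) / (4 * pi))
  .taper_cache[[key]] <- taper
  taper
}

#' Ground-truth FOD from known fiber orientations
#'
#' Sum of apodized band-limited delta kernels: each fiber contributes
#' `fraction * w_l * Y_lm(u)` where `w_l` is a per-degree taper derived from
#' a Hann window refined to non-negativity (see `nonneg_delta_taper`).  The
#' taper removes the negative ringing of a hard lmax-8 delta while keeping
#' the global maxima aligned with the generating orientations; the FOD
#' integral equals the sum of the fractions.
#'
#' @param orientations list (or k x 3 matrix) of up to 3 unit vectors.
#' @param fractions matching non-negative weights (the FOD integral equals
#'   their sum).
#' @param lmax even maximum degree (default 8).
#' @return SH coefficient vector of length `n_coeffs(lmax)`.
#' @export
gt_fod_from_fibers <- function(orientations, fractions, lmax = 8L) {
  if (is.matrix(orientations))
    orientations <- lapply(seq_len(nrow(orientations)),
                           function(i) orientations[i, ])
  if (length(orientations) > 3L)
    stop("at most 3 fiber orientations are supported")
  if (length(orientations) != length(fractions))
    stop("orientations and fractions disagree in length")
  w <- nonneg_delta_taper(lmax)
  idx <- sh_index_table(lmax)
  wl <- w[idx$l / 2 + 1L]
  cf <- numeric(n_coeffs(lmax))
  for (i in seq_along(orientations)) {
    Y <- as.numeric(basis_matrix(orientations[[i]], lmax))
    cf <- cf + fractions[i] * wl * Y
  }
  cf
}

# default tissue parameters as a function of maturation in [0, 1]
# (mm^2/s).  Immature cortex has high mean diffusivity; myelination lowers
# white matter radial diffusivity with age.  These defaults put the mean GM
# signal inside the WM signal range on every shell for maturation <~ 0.3.
tissue_params <- function(maturation) {
  m <- min(1, max(0, maturation))
  list(
    csf_d = 3.0e-3,
    gm_d = 1.3e-3 + (0.8e-3 - 1.3e-3) * m,
    wm_axial = 1.7e-3,
    wm_radial = 1.1e-3 + (0.3e-3 - 1.1e-3) * m
  )
}

# spatial myelination heterogeneity: per-region maturation offsets give the
# white matter regions a spread of radial diffusivities
region_maturation_offset <- c(wm_single = 0, wm_cross2 = 0.08,
                              wm_cross3 = -0.08)

region_levels <- c("csf", "gm", "wm_single", "wm_cross2", "wm_cross3")

# default layout: five equal slabs along x
default_region_layout <- function(grid_shape) {
  nx <- grid_shape[1]
  cuts <- round(seq(0, nx, length.out = 6))
  layout <- list()
  for (i in 1:5) {
    if (cuts[i + 1] > cuts[i])
      layout[[region_levels[i]]] <-
        rbind(x = c(cuts[i] + 1, cuts[i + 1]),
              y = c(1, grid_shape[2]), z = c(1, grid_shape[3]))
  }
  layout
}

# fiber orientations for each region given crossing angles (degrees)
region_fibers <- function(crossing_angles) {
  a2 <- crossing_angles[["cross2"]] * pi / 180
  a3 <- crossing_angles[["cross3"]] * pi / 180
  # two fibers in the xz-plane, symmetric about z
  f2 <- rbind(c(sin(a2 / 2), 0, cos(a2 / 2)),
              c(-sin(a2 / 2), 0, cos(a2 / 2)))
  # three fibers on a cone about z with equal pairwise angle a3
  sb2 <- 2 * (1 - cos(a3)) / 3
  sb <- sqrt(min(1, sb2))
  cb <- sqrt(max(0, 1 - sb2))
  f3 <- t(vapply(0:2, function(i) {
    ph <- 2 * pi * i / 3
    c(sb * cos(ph), sb * sin(ph), cb)
  }, numeric(3)))
  list(wm_single = rbind(c(0, 0, 1)), wm_cross2 = f2, wm_cross3 = f3)
}

#' Phantom specification
#'
#' @param grid_shape integer 3-vector of voxel grid dimensions.
#' @param region_layout named list mapping region labels (`csf`, `gm`,
#'   `wm_single`, `wm_cross2`, `wm_cross3`) to 3 x 2 matrices of inclusive
#'   voxel index ranges; `NULL` for the default five-slab layout.  Regions
#'   must be disjoint.
#' @param crossing_angles named degrees for the 2- and 3-fiber regions,
#'   in (0, 90].
#' @param snr signal-to-noise ratio at b = 0 (`Inf` = noiseless).
#' @param maturation scalar in [0, 1]; 0 is most immature.
#' @param s0 baseline signal.
#' @param seed integer seed for the noise stream.
#' @param gm_mix isotropic (gray-matter-like) volume fraction mixed into
#'   crossing-fiber voxels, so that crossings exercise the three-tissue
#'   separation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L), region_layout = NULL,
                         crossing_angles = c(cross2 = 90, cross3 = 60),
                         snr = Inf, maturation = 0.2, s0 = 1, seed = 1L,
                         gm_mix = 0.2) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (any(crossing_angles <= 0 | crossing_angles > 90))
    stop("crossing angles must lie in (0, 90] degrees")
  if (maturation < 0 || maturation > 1) stop("maturation must be in [0, 1]")
  if (is.null(region_layout)) region_layout <- default_region_layout(grid_shape)
  # validate disjointness by painting a label array
  lab <- array("", dim = grid_shape)
  for (rn in names(region_layout)) {
    if (!rn %in% region_levels) stop("unknown region label: ", rn)
    blk <- region_layout[[rn]]
    xs <- blk[1, 1]:blk[1, 2]; ys <- blk[2, 1]:blk[2, 2]; zs <- blk[3, 1]:blk[3, 2]
    if (any(lab[xs, ys, zs] != ""))
      stop("region layout overlaps at region ", rn)
    lab[xs, ys, zs] <- rn
  }
  structure(list(grid_shape = grid_shape, region_layout = region_layout,
                 tissue_label = lab, crossing_angles = crossing_angles,
                 snr = snr, maturation = maturation, s0 = s0,
                 seed = as.integer(seed), gm_mix = gm_mix,
                 fiber_rotation = diag(3)),
            class = "phantom_spec")
}

# region -> list of compartment_spec, given spec-level parameters
region_compartments <- function(region, spec) {
  m <- spec$maturation + if (region %in% names(region_maturation_offset))
    region_maturation_offset[[region]] else 0
  p <- tissue_params(m)
  pg <- tissue_params(spec$maturation)
  fibers <- region_fibers(spec$crossing_angles)
  R <- spec$fiber_rotation
  rot <- function(v) as.numeric(R %*% v)
  switch(region,
    csf = list(iso_compartment("csf", p$csf_d, 1)),
    gm = list(iso_compartment("gm", pg$gm_d, 1)),
    wm_single = list(fiber_compartment(rot(fibers$wm_single[1, ]), 1,
                                       p$wm_axial, p$wm_radial)),
    wm_cross2 = c(lapply(1:2, function(i)
      fiber_compartment(rot(fibers$wm_cross2[i, ]), (1 - spec$gm_mix) / 2,
                        p$wm_axial, p$wm_radial)),
      list(iso_compartment("gm", pg$gm_d, spec$gm_mix))),
    wm_cross3 = c(lapply(1:3, function(i)
      fiber_compartment(rot(fibers$wm_cross3[i, ]), (1 - spec$gm_mix) / 3,
                        p$wm_axial, p$wm_radial)),
      list(iso_compartment("gm", pg$gm_d, spec$gm_mix))),
    stop("unknown region ", region))
}

#' Build a phantom volume
#'
#' Fills every region of the spec with its multi-compartment signal
#' (regions are homogeneous before noise), applies Rician noise at the
#' spec's SNR, and records the generating geometry as ground truth:
#' per-voxel FOD (lmax 8, apodized deltas), peak orientations, fiber count
#' and tissue label.  Bit-reproducible given the spec (which includes the
#' seed).
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [gradient_scheme()]; default [make_dhcp_scheme()].
#' @return object of class `phantom_volume` with fields `dwi`
#'   (4D array x,y,z,measurement), `scheme`, `gt_fod` (4D array, 45
#'   coefficient volumes), `gt_peaks` (list of k x 3 matrices, voxel-linear
#'   order), `gt_count` (3D integer array), `tissue_label` (3D character
#'   array) and `spec`.
#' @export
build_phantom <- function(spec, scheme = make_dhcp_scheme()) {
  gs <- spec$grid_shape
  nvox <- prod(gs)
  nmeas <- length(scheme$bvals)
  lab <- spec$tissue_label
  dwi <- array(0, dim = c(gs, nmeas))
  gt_fod <- array(0, dim = c(gs, n_coeffs(8L)))
  gt_count <- array(0L, dim = gs)
  gt_peaks <- vector("list", nvox)
  flat_dwi <- matrix(0, nvox, nmeas)
  flat_fod <- matrix(0, nvox, n_coeffs(8L))
  R <- spec$fiber_rotation
  for (rn in unique(as.vector(lab))) {
    if (rn == "") next
    vox <- which(as.vector(lab) == rn)
    cmp <- region_compartments(rn, spec)
    sig <- simulate_voxel(cmp, scheme, spec$s0)
    flat_dwi[vox, ] <- matrix(sig, length(vox), nmeas, byrow = TRUE)
    fib <- cmp[vapply(cmp, function(x) x$kind == "fiber", logical(1))]
    k <- length(fib)
    gt_count[vox] <- k
    if (k > 0) {
      ors <- t(vapply(fib, `[[`, numeric(3), "orientation"))
      frs <- vapply(fib, `[[`, numeric(1), "fraction")
      fod <- gt_fod_from_fibers(ors, frs, 8L)
      flat_fod[vox, ] <- matrix(fod, length(vox), n_coeffs(8L), byrow = TRUE)
      for (v in vox) gt_peaks[[v]] <- ors
    }
  }
  flat_dwi <- add_rician_noise(flat_dwi, spec$snr, spec$seed, spec$s0)
  dwi[] <- flat_dwi
  gt_fod[] <- flat_fod
  structure(list(dwi = dwi, scheme = scheme, gt_fod = gt_fod,
                 gt_peaks = gt_peaks, gt_count = gt_count,
                 tissue_label = lab, spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("phantom_volume:", paste(dim(x$gt_count), collapse = " x "),
      "voxels,", length(x$scheme$bvals), "measurements\n")
  print(table(as.vector(x$tissue_label)))
  invisible(x)
}

# small random rotation matrix: uniform axis, angle in degrees
small_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_angle_deg * pi / 180)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a cohort of phantom subjects
#'
#' Subjects share the base spec; per subject, maturation is drawn uniformly
#' from `maturation_range`, the fiber geometry receives a small random
#' rotation (uniform axis, angle uniform in [0, `jitter_deg`] degrees,
#' emulating anatomical variability), and the noise seed is derived from
#' the master seed.  Deterministic given (`base_spec`, `n_subjects`,
#' `maturation_range`, `seed`).
#'
#' @param base_spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param maturation_range length-2 interval inside [0, 1] (degenerate
#'   allowed).
#' @param seed master seed.
#' @param jitter_deg maximum fiber-rotation jitter in degrees.
#' @param scheme acquisition scheme shared by the cohort.
#' @return list of `phantom_volume` objects.
#' @export
make_cohort <- function(base_spec, n_subjects, maturation_range, seed = 1L,
                        jitter_deg = 10, scheme = make_dhcp_scheme()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(maturation_range) != 2L ||
      maturation_range[2] < maturation_range[1])
    stop("maturation_range must be a non-empty interval")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  mats <- stats::runif(n_subjects, maturation_range[1], maturation_range[2])
  rots <- lapply(seq_len(n_subjects), function(i) small_rotation(jitter_deg))
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    sp <- base_spec
    sp$maturation <- mats[i]
    sp$fiber_rotation <- rots[[i]]
    sp$seed <- seeds[i]
    build_phantom(sp, scheme)
  })
}
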