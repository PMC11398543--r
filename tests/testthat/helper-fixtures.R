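# Shared fixtures, memoized per test session to keep the suite fast.

.fix <- new.env(parent = emptyenv())

fix_scheme <- function() {
  if (is.null(.fix$scheme)) .fix$scheme <- make_dhcp_scheme()
  .fix$scheme
}

fix_b1000_scheme <- function() {
  if (is.null(.fix$b1000)) {
    sch <- fix_scheme()
    idx <- which(sch$bvals == 0 | sch$bvals == 1000)
    s <- scheme_subset(sch, idx)
    s$parent_idx <- idx
    .fix$b1000 <- s
  }
  .fix$b1000
}

fix_responses <- function(maturation = 0.2) {
  key <- paste0("resp", maturation)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- response_set_from_params(fix_scheme()$shell_bvals,
                                            maturation)
  .fix[[key]]
}

fix_responses_b1000 <- function(maturation = 0.2) {
  key <- paste0("respb1000_", maturation)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- response_set_from_params(c(0, 1000), maturation)
  .fix[[key]]
}

# default phantom tissue parameters at a given maturation
fix_params <- function(maturation = 0.2) {
  list(csf_d = 3.0e-3,
       gm_d = 1.3e-3 + (0.8e-3 - 1.3e-3) * maturation,
       wm_axial = 1.7e-3,
       wm_radial = 1.1e-3 + (0.3e-3 - 1.1e-3) * maturation)
}

# single-fiber / crossing voxel signals on a scheme
fiber_signal <- function(orientation, scheme, maturation = 0.2) {
  p <- fix_params(maturation)
  simulate_voxel(list(fiber_compartment(orientation, 1, p$wm_axial,
                                        p$wm_radial)), scheme)
}

crossing_signal <- function(scheme, angle = 90, maturation = 0.2,
                            gm_mix = 0.2) {
  p <- fix_params(maturation)
  a <- angle * pi / 180
  u1 <- c(sin(a / 2), 0, cos(a / 2))
  u2 <- c(-sin(a / 2), 0, cos(a / 2))
  simulate_voxel(list(
    fiber_compartment(u1, (1 - gm_mix) / 2, p$wm_axial, p$wm_radial),
    fiber_compartment(u2, (1 - gm_mix) / 2, p$wm_axial, p$wm_radial),
    iso_compartment("gm", p$gm_d, gm_mix)), scheme)
}

# planar unit vector at angle theta (degrees) from +z in the xz-plane
uvec <- function(theta_deg) {
  t <- theta_deg * pi / 180
  c(sin(t), 0, cos(t))
}

# rotation matrix about an axis
rot_about <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
             c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

fix_noiseless_phantom <- function(shape = c(10, 10, 6), maturation = 0.2) {
  key <- paste0("ph", paste(shape, collapse = "_"), "_", maturation)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_phantom(
      phantom_spec(grid_shape = shape, maturation = maturation, snr = Inf),
      fix_scheme())
  .fix[[key]]
}
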