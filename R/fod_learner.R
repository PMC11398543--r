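# Patch-based volumetric regression from signal SH coefficients to FOD SH
# coefficients: direction subsampling, b0 normalization + SH projection,
# patch sampling, a compact 3D encoder-decoder convolutional network with
# a skip connection (written directly on BLAS matrix products), Adam
# training with early stopping, and sliding-window inference.

#' Greedy well-spread subsampling of the b1000 shell
#'
#' Deterministically selects `n_sig` directions from the non-zero shell by
#' greedy farthest-point selection under the antipodal angle (starting
#' from the direction closest to +z, ties by index), plus the first b0
#' measurement.
#'
#' @param scheme a [gradient_scheme()] containing a b1000 shell and b0s.
#' @param n_sig number of diffusion-weighted directions to keep.
#' @param shell_bval which shell to subsample (default 1000).
#' @return a [gradient_scheme()] with `n_sig + 1` measurements and a
#'   `parent_idx` field mapping back into `scheme`.
#' @export
subsample_directions <- function(scheme, n_sig, shell_bval = 1000) {
  shell <- which(abs(scheme$bvals - shell_bval) < 50)
  if (length(shell) == 0L) stop("scheme has no b = ", shell_bval, " shell")
  if (n_sig > length(shell))
    stop("n_sig = ", n_sig, " exceeds shell size ", length(shell))
  b0 <- which(scheme$bvals == 0)[1L]
  if (is.na(b0)) stop("scheme has no b0 measurement")
  if (n_sig == length(shell)) {
    keep <- shell
  } else {
    dirs <- scheme$directions[shell, , drop = FALSE]
    chosen <- which.max(abs(dirs[, 3L]))
    while (length(chosen) < n_sig) {
      # antipodal angle to the nearest chosen direction, per candidate
      ad <- abs(dirs %*% t(dirs[chosen, , drop = FALSE]))
      minang <- apply(acos(pmin(ad, 1)), 1L, min)
      minang[chosen] <- -Inf
      chosen <- c(chosen, which.max(minang))
    }
    keep <- shell[sort(chosen)]
  }
  idx <- c(b0, keep)
  out <- scheme_subset(scheme, idx)
  out$parent_idx <- idx
  out
}

#' SH order paired with a direction count
#'
#' The largest even degree whose coefficient count does not exceed the
#' number of directions: 6 -> 2, 15 -> 4, 28 -> 6, 45+ -> 8 (capped at 8).
#'
#' @param n_sig number of directions.
#' @return even lmax.
#' @export
lmax_for_nsig <- function(n_sig) {
  lmax <- 0L
  while (lmax + 2L <= 8L && n_coeffs(lmax + 2L) <= n_sig) lmax <- lmax + 2L
  lmax
}

#' Network input: b0-normalized signal SH image
#'
#' Subsamples `n_sig` b1000 directions, divides each voxel's signals by
#' its b0 value (voxels with b0 below `eps` are masked out), and projects
#' onto the SH basis of order [lmax_for_nsig()] with Laplace-Beltrami
#' regularization.
#'
#' @param dwi 4D array matching `scheme`.
#' @param scheme the full acquisition [gradient_scheme()].
#' @param n_sig number of input directions.
#' @param mask optional logical 3D array to intersect with the b0 validity
#'   mask.
#' @param reg SH fit regularization weight (default 0.006).
#' @param eps b0 guard.
#' @return an [sh_image()] with provenance `"signal"`.
#' @export
prepare_input <- function(dwi, scheme, n_sig, mask = NULL, reg = 0.006,
                          eps = 1e-8) {
  sub <- subsample_directions(scheme, n_sig)
  d <- dim(dwi)
  flat <- matrix(dwi, prod(d[1:3]), d[4L])
  b0 <- flat[, sub$parent_idx[1L]]
  dwv <- flat[, sub$parent_idx[-1L], drop = FALSE]
  ok <- b0 > eps
  norm <- dwv / ifelse(ok, b0, 1)
  norm[!ok, ] <- 0
  lmax <- lmax_for_nsig(n_sig)
  cf <- fit_sh(norm, sub$directions[-1L, , drop = FALSE], lmax, reg)
  cf[!ok, ] <- 0
  m <- array(ok, dim = d[1:3])
  if (!is.null(mask)) m <- m & mask
  sh_image(cf, lmax, "signal", m, grid_shape = d[1:3])
}

#' Sample aligned training patches
#'
#' Patch origins are drawn uniformly (seeded) from all positions where the
#' patch lies inside the volume and contains at least one masked voxel;
#' along axes shorter than `size` the patch is zero-padded at the volume
#' border.
#'
#' @param input_img,target_img aligned [sh_image()]s.
#' @param n number of patches (default 128).
#' @param size patch edge length (default 16).
#' @param seed integer seed.
#' @return list of patches; each has `x` and `y` (channel x voxel
#'   matrices), `dims` (spatial extent) and `mask` (logical vector).
#' @export
sample_patches <- function(input_img, target_img, n = 128L, size = 16L,
                           seed = 1L) {
  stopifnot(all(input_img$grid_shape == target_img$grid_shape))
  gs <- input_img$grid_shape
  eff <- pmin(gs, size)
  starts <- lapply(1:3, function(a) seq_len(gs[a] - eff[a] + 1L))
  origins <- as.matrix(expand.grid(starts[[1L]], starts[[2L]], starts[[3L]]))
  has_mask <- apply(origins, 1L, function(o) {
    any(input_img$mask[o[1L]:(o[1L] + eff[1L] - 1L),
                       o[2L]:(o[2L] + eff[2L] - 1L),
                       o[3L]:(o[3L] + eff[3L] - 1L)])
  })
  origins <- origins[has_mask, , drop = FALSE]
  if (nrow(origins) == 0L) stop("no patch origin intersects the mask")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  picks <- origins[sample.int(nrow(origins), n, replace = TRUE), ,
                   drop = FALSE]
  Xi <- sh_image_matrix(input_img); Yi <- sh_image_matrix(target_img)
  lapply(seq_len(n), function(i) {
    o <- picks[i, ]
    extract_patch(Xi, Yi, input_img$mask, gs, o, eff, size)
  })
}

# cut one zero-padded patch (channels x size^3 matrices)
extract_patch <- function(Xi, Yi, mask, gs, o, eff, size) {
  sel <- array(FALSE, dim = gs)
  sel[o[1L]:(o[1L] + eff[1L] - 1L), o[2L]:(o[2L] + eff[2L] - 1L),
      o[3L]:(o[3L] + eff[3L] - 1L)] <- TRUE
  vox <- which(as.vector(sel))
  x <- matrix(0, ncol(Xi), size^3)
  y <- matrix(0, ncol(Yi), size^3)
  m <- logical(size^3)
  # position of interior voxels inside the padded cube (corner-aligned)
  cube <- array(seq_len(size^3), dim = c(size, size, size))
  pos <- as.vector(cube[seq_len(eff[1L]), seq_len(eff[2L]), seq_len(eff[3L])])
  x[, pos] <- t(Xi[vox, , drop = FALSE])
  y[, pos] <- t(Yi[vox, , drop = FALSE])
  m[pos] <- mask[vox]
  list(x = x, y = y, dims = c(size, size, size), mask = m, origin = o)
}

## ---- minimal 3D conv net machinery -------------------------------------

# cached im2col index sets per spatial extent
.conv_cache <- new.env(parent = emptyenv())
conv_indices <- function(dims) {
  key <- paste(dims, collapse = "x")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  pd <- dims + 2L
  inner <- as.vector(array(seq_len(prod(pd)), dim = pd)[
    2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  coords <- as.matrix(expand.grid(seq_len(dims[1L]) + 1L,
                                  seq_len(dims[2L]) + 1L,
                                  seq_len(dims[3L]) + 1L))
  idx <- matrix(0L, nrow(coords), 27L)
  for (o in seq_len(27L)) {
    cc <- sweep(coords, 2L, offs[o, ], `+`)
    idx[, o] <- (cc[, 3L] - 1L) * pd[1L] * pd[2L] +
      (cc[, 2L] - 1L) * pd[1L] + cc[, 1L]
  }
  res <- list(pd = pd, inner = inner, idx = idx)
  .conv_cache[[key]] <- res
  res
}

# within one kernel offset every output voxel maps to a distinct padded
# voxel, so gather and scatter-add decompose into 27 plain vectorized
# column operations
conv3_forward <- function(X, W, b, dims) {
  ci <- conv_indices(dims)
  C <- nrow(X)
  V <- ncol(X)
  Xp <- matrix(0, C, prod(ci$pd))
  Xp[, ci$inner] <- X
  cols <- matrix(0, C * 27L, V)
  for (o in seq_len(27L))
    cols[(o - 1L) * C + seq_len(C), ] <- Xp[, ci$idx[, o], drop = FALSE]
  list(out = W %*% cols + b, cols = cols)
}

conv3_backward <- function(dY, cols, W, dims, C_in) {
  ci <- conv_indices(dims)
  dW <- tcrossprod(dY, cols)
  db <- rowSums(dY)
  dcols <- crossprod(W, dY)                  # (27 C_in) x V
  dXp <- matrix(0, C_in, prod(ci$pd))
  for (o in seq_len(27L)) {
    j <- ci$idx[, o]
    dXp[, j] <- dXp[, j, drop = FALSE] +
      dcols[(o - 1L) * C_in + seq_len(C_in), , drop = FALSE]
  }
  list(dX = dXp[, ci$inner, drop = FALSE], dW = dW, db = db)
}

pool_indices <- function(dims) {
  key <- paste("pool", paste(dims, collapse = "x"))
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  hd <- dims %/% 2L
  grp <- array(0L, dim = dims)
  coords <- as.matrix(expand.grid(seq_len(dims[1L]), seq_len(dims[2L]),
                                  seq_len(dims[3L])))
  g <- ((coords[, 3L] + 1L) %/% 2L - 1L) * hd[1L] * hd[2L] +
    ((coords[, 2L] + 1L) %/% 2L - 1L) * hd[1L] + (coords[, 1L] + 1L) %/% 2L
  res <- list(group = g, hd = hd)
  .conv_cache[[key]] <- res
  res
}

avgpool2_forward <- function(X, dims) {
  pi <- pool_indices(dims)
  t(rowsum(t(X), pi$group) / 8)
}

avgpool2_backward <- function(dY, dims) {
  pi <- pool_indices(dims)
  dY[, pi$group, drop = FALSE] / 8
}

upsample2_forward <- function(X, half_dims) {
  pi <- pool_indices(half_dims * 2L)
  X[, pi$group, drop = FALSE]
}

upsample2_backward <- function(dY, half_dims) {
  pi <- pool_indices(half_dims * 2L)
  t(rowsum(t(dY), pi$group))
}

#' Model specification for the volumetric FOD regressor
#'
#' A compact 3D encoder-decoder with one downsampling stage and a skip
#' connection: two 3x3x3 conv+ReLU blocks at full resolution, average-pool
#' 2x, two conv+ReLU blocks at half resolution, nearest-neighbor
#' upsampling, skip concatenation, one conv+ReLU fusion block and a 1x1x1
#' linear output head producing the 45 FOD coefficients.
#'
#' @param in_channels input SH channel count (e.g. [n_coeffs()] of the
#'   input lmax).
#' @param out_channels output channels (default 45, lmax 8).
#' @param base base channel width (default 8).
#' @param dropout dropout probability applied to hidden activations during
#'   training (default 0.1).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(in_channels, out_channels = 45L, base = 8L,
                       dropout = 0.1) {
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base = as.integer(base), dropout = dropout),
            class = "model_spec")
}

# He-style initialization
init_model <- function(spec, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  cw <- function(cout, cin, k = 27L) {
    matrix(stats::rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))),
           cout, cin * k)
  }
  b <- spec$base
  params <- list(
    W1 = cw(b, spec$in_channels), b1 = numeric(b),
    W2 = cw(b, b), b2 = numeric(b),
    W3 = cw(2L * b, b), b3 = numeric(2L * b),
    W4 = cw(2L * b, 2L * b), b4 = numeric(2L * b),
    W5 = cw(b, 3L * b), b5 = numeric(b),
    W6 = matrix(stats::rnorm(spec$out_channels * b, 0, sqrt(1 / b)),
                spec$out_channels, b),
    b6 = numeric(spec$out_channels))
  structure(list(spec = spec, params = params), class = "fod_net")
}

#' @export
print.fod_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("fod_net:", x$spec$in_channels, "->", x$spec$out_channels,
      "channels, base", x$spec$base, "-", np, "parameters\n")
  invisible(x)
}

# forward pass; drop_masks NULL for inference.  Returns prediction and,
# when keep = TRUE, the intermediates needed for backprop.
net_forward <- function(model, x, dims, drop_masks = NULL, keep = FALSE) {
  p <- model$params
  relu <- function(z) { z[z < 0] <- 0; z }
  dm <- function(i, a) if (is.null(drop_masks)) a else a * drop_masks[[i]]
  c1 <- conv3_forward(x, p$W1, p$b1, dims); a1 <- dm(1L, relu(c1$out))
  c2 <- conv3_forward(a1, p$W2, p$b2, dims); a2 <- dm(2L, relu(c2$out))
  hd <- dims %/% 2L
  d1 <- avgpool2_forward(a2, dims)
  c3 <- conv3_forward(d1, p$W3, p$b3, hd); a3 <- dm(3L, relu(c3$out))
  c4 <- conv3_forward(a3, p$W4, p$b4, hd); a4 <- dm(4L, relu(c4$out))
  u1 <- upsample2_forward(a4, hd)
  cat1 <- rbind(u1, a2)
  c5 <- conv3_forward(cat1, p$W5, p$b5, dims); a5 <- dm(5L, relu(c5$out))
  out <- p$W6 %*% a5 + p$b6
  if (!keep) return(list(out = out))
  list(out = out, x = x, c1 = c1, a1 = a1, c2 = c2, a2 = a2, d1 = d1,
       c3 = c3, a3 = a3, c4 = c4, a4 = a4, u1 = u1, cat1 = cat1, c5 = c5,
       a5 = a5, dims = dims, hd = hd)
}

net_backward <- function(model, fw, dout, drop_masks = NULL) {
  p <- model$params
  dmask <- function(i, g) if (is.null(drop_masks)) g else g * drop_masks[[i]]
  drelu <- function(g, pre) { g[pre <= 0] <- 0; g }
  b <- model$spec$base
  g <- list()
  g$W6 <- tcrossprod(dout, fw$a5); g$b6 <- rowSums(dout)
  da5 <- crossprod(p$W6, dout)
  d5 <- drelu(dmask(5L, da5), fw$c5$out)
  bk5 <- conv3_backward(d5, fw$c5$cols, p$W5, fw$dims, 3L * b)
  g$W5 <- bk5$dW; g$b5 <- bk5$db
  du1 <- bk5$dX[seq_len(2L * b), , drop = FALSE]
  da2_skip <- bk5$dX[2L * b + seq_len(b), , drop = FALSE]
  da4 <- upsample2_backward(du1, fw$hd)
  d4 <- drelu(dmask(4L, da4), fw$c4$out)
  bk4 <- conv3_backward(d4, fw$c4$cols, p$W4, fw$hd, 2L * b)
  g$W4 <- bk4$dW; g$b4 <- bk4$db
  d3 <- drelu(dmask(3L, bk4$dX), fw$c3$out)
  bk3 <- conv3_backward(d3, fw$c3$cols, p$W3, fw$hd, b)
  g$W3 <- bk3$dW; g$b3 <- bk3$db
  dd1 <- bk3$dX
  da2 <- avgpool2_backward(dd1, fw$dims) + da2_skip
  d2 <- drelu(dmask(2L, da2), fw$c2$out)
  bk2 <- conv3_backward(d2, fw$c2$cols, p$W2, fw$dims, b)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  d1g <- drelu(dmask(1L, bk2$dX), fw$c1$out)
  bk1 <- conv3_backward(d1g, fw$c1$cols, p$W1, fw$dims,
                        model$spec$in_channels)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  g
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param dropout dropout rate (default 0.1).
#' @param patches_per_subject patches sampled per subject per epoch
#'   (default 128).
#' @param patch_size patch edge length (default 16).
#' @param max_epochs maximum epochs (default 30).
#' @param patience early-stopping patience on validation loss, in epochs
#'   (default 10).
#' @param seed RNG seed for initialization, patch sampling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, dropout = 0.1,
                         patches_per_subject = 128L, patch_size = 16L,
                         max_epochs = 30L, patience = 10L, seed = 1L) {
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1,
            patches_per_subject >= 1, patch_size >= 1, max_epochs >= 1,
            patience >= 1)
  structure(list(learning_rate = learning_rate, dropout = dropout,
                 patches_per_subject = as.integer(patches_per_subject),
                 patch_size = as.integer(patch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

# squared-error loss (mean over channels x voxels) and gradient
l2_loss <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d^2), grad = 2 * d / length(d))
}

#' Train the FOD regressor
#'
#' Adam optimization of the voxelwise squared-error loss between predicted
#' and target FOD SH coefficients, with per-epoch patch resampling (the
#' configured number of patches per training subject, each processed as
#' one optimization step), dropout on hidden activations, and early
#' stopping on the validation loss with the configured patience; the
#' weights achieving the best validation loss are returned.  Fully seeded
#' and reproducible.
#'
#' @param spec a [model_spec()] (its `in_channels` must match the subject
#'   inputs).
#' @param train_subjects,val_subjects lists of subjects, each a list with
#'   elements `input` and `target` ([sh_image()]s).
#' @param config a [train_config()].
#' @return a `fod_net` with an attached `history` (data.frame of epoch,
#'   training loss, validation loss).
#' @export
train_fod_net <- function(spec, train_subjects, val_subjects, config) {
  stopifnot(length(train_subjects) >= 1, length(val_subjects) >= 1)
  model <- init_model(spec, seed = config$seed)
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  tstep <- 0L
  val_patches <- unlist(lapply(seq_along(val_subjects), function(i)
    sample_patches(val_subjects[[i]]$input, val_subjects[[i]]$target,
                   n = max(8L, config$patches_per_subject %/% 4L),
                   size = config$patch_size,
                   seed = config$seed + 7919L * i)),
    recursive = FALSE)
  val_loss <- function(m) {
    mean(vapply(val_patches, function(pt) {
      fw <- net_forward(m, pt$x, pt$dims)
      l2_loss(fw$out, pt$y)$loss
    }, numeric(1)))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed + 1L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  dims_area <- function(pt) prod(pt$dims)
  for (epoch in seq_len(config$max_epochs)) {
    patches <- unlist(lapply(seq_along(train_subjects), function(i)
      sample_patches(train_subjects[[i]]$input, train_subjects[[i]]$target,
                     n = config$patches_per_subject,
                     size = config$patch_size,
                     seed = config$seed + 104729L * epoch + i)),
      recursive = FALSE)
    patches <- patches[sample.int(length(patches))]
    eloss <- 0
    for (pt in patches) {
      drop_masks <- if (config$dropout > 0) {
        nv <- prod(pt$dims); hv <- prod(pt$dims %/% 2L)
        b <- spec$base
        sz <- list(c(b, nv), c(b, nv), c(2L * b, hv), c(2L * b, hv),
                   c(b, nv))
        lapply(sz, function(s)
          matrix((stats::runif(prod(s)) >= config$dropout) /
                   (1 - config$dropout), s[1L], s[2L]))
      } else NULL
      fw <- net_forward(model, pt$x, pt$dims, drop_masks, keep = TRUE)
      ls <- l2_loss(fw$out, pt$y)
      if (!is.finite(ls$loss))
        stop("training loss became non-finite at epoch ", epoch)
      eloss <- eloss + ls$loss
      gr <- net_backward(model, fw, ls$grad, drop_masks)
      tstep <- tstep + 1L
      for (nm in names(gr)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^tstep)
        vhat <- vstate[[nm]] / (1 - beta2^tstep)
        model$params[[nm]] <- model$params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    vl <- val_loss(model)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = eloss / length(patches),
                                   val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = model$params,
                                     epoch = epoch)
    if (epoch - best$epoch >= config$patience) break
  }
  model$params <- best$params
  attr(model, "history") <- hist
  attr(model, "config") <- config
  model
}

#' Single-patch overfit capacity check
#'
#' Fits one patch exactly: full-batch quasi-Newton optimization (L-BFGS
#' with the network's analytic gradient) of the squared-error loss on a
#' single (input, target) patch.  A healthy architecture and gradient
#' implementation drive the loss far below its initial value; used as a
#' sanity oracle for the model family.
#'
#' @param patch one element of [sample_patches()].
#' @param base model width for the check (default 24; wider than the
#'   training default so capacity, not width, is what is tested).
#' @param maxit optimizer iterations (default 500).
#' @param seed initialization seed.
#' @return list with `initial_loss`, `final_loss` and their `ratio`.
#' @export
overfit_patch <- function(patch, base = 24L, maxit = 500L, seed = 2L) {
  spec <- model_spec(in_channels = nrow(patch$x), base = base, dropout = 0)
  m <- init_model(spec, seed = seed)
  lens <- vapply(m$params, length, numeric(1))
  flat0 <- unlist(m$params, use.names = FALSE)
  unflat <- function(v) {
    out <- m$params; o <- 0
    for (nm in names(out)) {
      out[[nm]][] <- v[o + seq_len(lens[[nm]])]
      o <- o + lens[[nm]]
    }
    out
  }
  fn <- function(v) {
    mm <- m; mm$params <- unflat(v)
    l2_loss(net_forward(mm, patch$x, patch$dims)$out, patch$y)$loss
  }
  grf <- function(v) {
    mm <- m; mm$params <- unflat(v)
    fw <- net_forward(mm, patch$x, patch$dims, keep = TRUE)
    ls <- l2_loss(fw$out, patch$y)
    unlist(net_backward(mm, fw, ls$grad)[names(m$params)],
           use.names = FALSE)
  }
  l0 <- fn(flat0)
  res <- stats::optim(flat0, fn, grf, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(initial_loss = l0, final_loss = res$value, ratio = res$value / l0)
}

#' Sliding-window inference
#'
#' Tiles the volume with windows of the training patch size at half-window
#' stride, averages overlapping predictions, and masks the output like the
#' input.  Volumes smaller than the window are zero-padded.
#'
#' @param model a trained `fod_net`.
#' @param input_img [sh_image()] whose channel count matches the model.
#' @param patch_size window edge length (default 16).
#' @param stride window stride (default `patch_size / 2`).
#' @return an [sh_image()] FOD volume (lmax 8 for the default head).
#' @export
predict_fod <- function(model, input_img, patch_size = 16L,
                        stride = patch_size %/% 2L) {
  if (n_coeffs(input_img$lmax) != model$spec$in_channels)
    stop("input has ", n_coeffs(input_img$lmax), " channels, model expects ",
         model$spec$in_channels)
  gs <- input_img$grid_shape
  eff <- pmin(gs, patch_size)
  Xi <- sh_image_matrix(input_img)
  acc <- matrix(0, prod(gs), model$spec$out_channels)
  wt <- numeric(prod(gs))
  starts <- lapply(1:3, function(a) {
    s <- seq(1L, max(1L, gs[a] - eff[a] + 1L), by = stride)
    unique(c(s, gs[a] - eff[a] + 1L))
  })
  cube <- array(seq_len(patch_size^3), dim = rep(patch_size, 3L))
  pos <- as.vector(cube[seq_len(eff[1L]), seq_len(eff[2L]), seq_len(eff[3L])])
  dims <- rep(patch_size, 3L)
  for (ox in starts[[1L]]) for (oy in starts[[2L]]) for (oz in starts[[3L]]) {
    o <- c(ox, oy, oz)
    sel <- array(FALSE, dim = gs)
    sel[o[1L]:(o[1L] + eff[1L] - 1L), o[2L]:(o[2L] + eff[2L] - 1L),
        o[3L]:(o[3L] + eff[3L] - 1L)] <- TRUE
    vox <- which(as.vector(sel))
    x <- matrix(0, ncol(Xi), patch_size^3)
    x[, pos] <- t(Xi[vox, , drop = FALSE])
    fw <- net_forward(model, x, dims)
    acc[vox, ] <- acc[vox, , drop = FALSE] + t(fw$out[, pos, drop = FALSE])
    wt[vox] <- wt[vox] + 1
  }
  out <- acc / pmax(wt, 1)
  out[!as.vector(input_img$mask), ] <- 0
  sh_image(out, lmax_for_n_coeffs(model$spec$out_channels), "fod",
           input_img$mask, grid_shape = gs)
}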