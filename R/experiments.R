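# Experiment orchestration: shared NIfTI/gradient-table I/O, manifests,
# and the two learning experiments (input-direction ablation and
# maturation domain shift) run end-to-end on synthetic cohorts.

#' Read a diffusion volume with FSL-style gradient tables
#'
#' @param path 4D NIfTI file.
#' @param bvals_path text file with one row of b-values.
#' @param bvecs_path text file with three rows of direction components
#'   (FSL dialect).
#' @return list with `dwi` (4D array), `scheme` ([gradient_scheme()]),
#'   `affine` (4 x 4 matrix, preserved through the pipeline).
#' @export
read_dwi <- function(path, bvals_path, bvecs_path) {
  img <- RNifti::readNifti(path)
  dwi <- array(as.numeric(img), dim = dim(img))
  bvals <- scan(bvals_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(bv) != 3L)
    stop("bvecs file must have 3 rows (FSL dialect), got ", nrow(bv))
  dirs <- t(bv)
  if (length(bvals) != nrow(dirs))
    stop("bvals has ", length(bvals), " entries but bvecs has ", nrow(dirs))
  if (length(dim(dwi)) != 4L || dim(dwi)[4L] != length(bvals))
    stop("image has ", if (length(dim(dwi)) == 4L) dim(dwi)[4L] else "no",
         " volumes but the gradient table lists ", length(bvals))
  nrm <- sqrt(rowSums(dirs^2))
  zero <- nrm < 1e-8
  if (any(zero & bvals > 0))
    stop("zero-norm bvec for non-b0 measurement(s): ",
         paste(which(zero & bvals > 0), collapse = ", "))
  dirs[zero, ] <- matrix(c(0, 0, 1), sum(zero), 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(dwi = dwi, scheme = gradient_scheme(bvals, dirs),
       affine = structure(RNifti::xform(img), class = "matrix"))
}

#' Write a diffusion volume and its gradient tables
#'
#' @param path output NIfTI path.
#' @param dwi 4D array.
#' @param scheme matching [gradient_scheme()].
#' @param bvals_path,bvecs_path gradient table paths (default: `path`
#'   with `.bval` / `.bvec` appended).
#' @param affine optional 4 x 4 affine.
#' @return `path`, invisibly.
#' @export
write_dwi <- function(path, dwi, scheme,
                      bvals_path = paste0(path, ".bval"),
                      bvecs_path = paste0(path, ".bvec"),
                      affine = NULL) {
  img <- RNifti::asNifti(dwi)
  if (!is.null(affine)) RNifti::`sform<-`(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  writeLines(paste(scheme$bvals, collapse = " "), bvals_path)
  bv <- t(scheme$directions)
  bv[, scheme$bvals == 0] <- 0
  writeLines(apply(bv, 1L, paste, collapse = " "), bvecs_path)
  invisible(path)
}

#' Write / read an SH image as 4D NIfTI with a JSON sidecar
#'
#' The sidecar documents the coefficient ordering and basis convention so
#' external viewers can interpret the volumes.
#'
#' @param path NIfTI path (`.json` sidecar written next to it).
#' @param img an [sh_image()].
#' @return `path` (write) or an `sh_image` (read).
#' @export
write_fod <- function(path, img) {
  RNifti::writeNifti(RNifti::asNifti(img$coeffs), path)
  side <- list(
    lmax = img$lmax, provenance = img$provenance,
    n_coeffs = n_coeffs(img$lmax),
    ordering = "ascending even degree l; within degree ascending order m",
    basis = paste("real orthonormal spherical harmonics;",
                  "m<0 -> sqrt2 * N * P_l^|m| * sin(|m| phi),",
                  "m>0 -> sqrt2 * N * P_l^m * cos(m phi);",
                  "Condon-Shortley phase included"))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_fod
#' @export
read_fod <- function(path) {
  arr <- RNifti::readNifti(path)
  arr <- array(as.numeric(arr), dim = dim(arr))
  side <- jsonlite::read_json(sidecar_path(path))
  sh_image(arr, lmax = side$lmax,
           provenance = if (identical(side$provenance, "signal"))
             "signal" else "fod")
}

# run manifest: configuration, seeds and package version beside outputs
write_manifest <- function(dir, config, extra = list()) {
  man <- c(list(package = "fodlab",
                version = as.character(utils::packageVersion("fodlab")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = config), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Desk-scale experiment configuration
#'
#' Shared settings for [run_ablation()] and [run_domain_shift()].  The
#' defaults are deliberately small (cohorts of a few 12^3 subjects, a
#' narrow network, few epochs) so that a full experiment runs on one CPU
#' in minutes while preserving the experimental design.
#'
#' @param gt_methods deconvolution ground truths to compare.
#' @param n_sig input direction counts for the ablation.
#' @param n_train,n_val,n_test cohort split sizes.
#' @param grid_shape phantom grid.
#' @param maturation_range cohort maturation interval (ablation) — the
#'   domain-shift experiment uses `early_range` / `late_range` instead.
#' @param early_range,late_range maturation intervals of the two age
#'   groups.
#' @param snr acquisition SNR at b0.
#' @param train_seeds one training replicate per seed.
#' @param master_seed seed for cohort generation and splits.
#' @param patch_size,base,epochs,patches_per_subject,patience,learning_rate
#'   network/training settings (see [train_config()]).
#' @param solver_opts list of options for the ss3t solver (`tol`,
#'   `max_iter`).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(gt_methods = "ss3t", n_sig = c(6L, 45L),
                              n_train = 3L, n_val = 1L, n_test = 2L,
                              grid_shape = c(12L, 12L, 12L),
                              maturation_range = c(0.1, 0.3),
                              early_range = c(0.05, 0.3),
                              late_range = c(0.65, 0.95),
                              snr = 20, train_seeds = 1:3,
                              master_seed = 1L, patch_size = 8L,
                              base = 8L, epochs = 30L,
                              patches_per_subject = 24L, patience = 10L,
                              learning_rate = 1e-3,
                              solver_opts = list(tol = 1e-3,
                                                 max_iter = 20L)) {
  structure(as.list(environment()), class = "experiment_config")
}

# ground-truth FODs for one subject with one method
subject_gt <- function(vol, method, solver_opts) {
  resp <- estimate_responses_from_phantom(vol)
  if (method == "msmt") {
    fit_fod_volume(vol$dwi, vol$scheme, resp, "msmt")
  } else {
    idx <- which(vol$scheme$bvals == 0 | abs(vol$scheme$bvals - 1000) < 50)
    sub <- scheme_subset(vol$scheme, idx)
    keep <- vapply(sub$shell_bvals, function(b)
      which(abs(resp$shell_bvals - b) < 1e-6), integer(1))
    sub_k <- function(k) zonal_kernel(k$coef[keep, , drop = FALSE],
                                      resp$shell_bvals[keep], k$lmax)
    resp2 <- response_set(sub_k(resp$wm), sub_k(resp$gm), sub_k(resp$csf))
    fit_fod_volume(vol$dwi[, , , idx, drop = FALSE], sub, resp2, "ss3t",
                   tol = solver_opts$tol, max_iter = solver_opts$max_iter)
  }
}

subject_wm_mask <- function(vol) {
  array(as.vector(vol$tissue_label) %in%
          c("wm_single", "wm_cross2", "wm_cross3"),
        dim = dim(vol$tissue_label))
}

# assemble (input, target) pairs for the learner
learner_subjects <- function(cohort, gts, n_sig) {
  lapply(seq_along(cohort), function(i) {
    list(input = prepare_input(cohort[[i]]$dwi, cohort[[i]]$scheme, n_sig),
         target = gts[[i]]$fod)
  })
}

train_once <- function(cfg, subs_train, subs_val, seed) {
  spec <- model_spec(in_channels = n_coeffs(subs_train[[1L]]$input$lmax),
                     base = cfg$base)
  tc <- train_config(learning_rate = cfg$learning_rate,
                     patches_per_subject = cfg$patches_per_subject,
                     patch_size = cfg$patch_size,
                     max_epochs = cfg$epochs, patience = cfg$patience,
                     seed = seed)
  train_fod_net(spec, subs_train, subs_val, tc)
}

evaluate_model <- function(model, test_inputs, test_gts, test_vols,
                           patch_size) {
  reps <- lapply(seq_along(test_inputs), function(i) {
    pred <- predict_fod(model, test_inputs[[i]], patch_size = patch_size)
    compare_fod_volumes(test_gts[[i]]$fod, pred,
                        subject_wm_mask(test_vols[[i]]))
  })
  list(reports = reps,
       ar = rowMeans(vapply(reps, `[[`, numeric(3), "ar"), na.rm = TRUE),
       ae = rowMeans(vapply(reps, `[[`, numeric(3), "ae"), na.rm = TRUE),
       afd_mape = mean(vapply(reps, `[[`, numeric(1), "afd_mape")))
}

#' Input-direction ablation experiment
#'
#' For each ground-truth method and each input direction count: build GT
#' FODs with that method on a shared phantom cohort, train the regressor
#' (one replicate per training seed), and score predictions on the test
#' subjects against that method's GT in the white matter mask.  All
#' conditions share the cohort, splits and test subjects.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory for per-condition JSON reports and a
#'   manifest.
#' @return list of class `experiment_report`: `conditions` (one entry per
#'   method x n_sig x seed with the averaged metrics and per-subject
#'   reports) and `config`.
#' @export
run_ablation <- function(cfg, out_dir = NULL) {
  n_tot <- cfg$n_train + cfg$n_val + cfg$n_test
  cohort <- make_cohort(
    phantom_spec(grid_shape = cfg$grid_shape, snr = cfg$snr),
    n_tot, cfg$maturation_range, seed = cfg$master_seed)
  i_train <- seq_len(cfg$n_train)
  i_val <- cfg$n_train + seq_len(cfg$n_val)
  i_test <- cfg$n_train + cfg$n_val + seq_len(cfg$n_test)
  conditions <- list()
  for (method in cfg$gt_methods) {
    gts <- lapply(cohort, subject_gt, method = method,
                  solver_opts = cfg$solver_opts)
    for (ns in cfg$n_sig) {
      subs <- learner_subjects(cohort, gts, ns)
      for (sd in cfg$train_seeds) {
        model <- train_once(cfg, subs[i_train], subs[i_val], sd)
        ev <- evaluate_model(model, lapply(subs[i_test], `[[`, "input"),
                             gts[i_test], cohort[i_test], cfg$patch_size)
        key <- sprintf("%s_nsig%d_seed%d", method, ns, sd)
        conditions[[key]] <- list(method = method, n_sig = ns, seed = sd,
                                  ar = ev$ar, ae = ev$ae,
                                  afd_mape = ev$afd_mape,
                                  reports = ev$reports,
                                  history = attr(model, "history"))
        if (!is.null(out_dir)) save_condition(out_dir, key, conditions[[key]])
      }
    }
  }
  rep <- structure(list(conditions = conditions, config = cfg,
                        experiment = "ablation"),
                   class = "experiment_report")
  if (!is.null(out_dir))
    write_manifest(out_dir, strip_config(cfg),
                   list(experiment = "ablation",
                        conditions = names(conditions)))
  rep
}

#' Maturation domain-shift experiment
#'
#' Two cohorts (early and late maturation ranges); per ground-truth
#' method, one model is trained on each cohort and tested on the test
#' subjects of both cohorts (self- and cross-testing), at a fixed input
#' direction count of 15 (SH order 4) unless overridden.
#'
#' @param cfg an [experiment_config()]; `early_range`, `late_range` and
#'   the first element of `cfg$n_sig` (default 15) are used.
#' @param n_sig input direction count (default 15).
#' @param out_dir optional output directory.
#' @return `experiment_report` with one condition per
#'   method x train-group x test-group x seed, each tagged
#'   `self`/`cross`.
#' @export
run_domain_shift <- function(cfg, n_sig = 15L, out_dir = NULL) {
  n_tot <- cfg$n_train + cfg$n_val + cfg$n_test
  groups <- list(
    early = make_cohort(phantom_spec(grid_shape = cfg$grid_shape,
                                     snr = cfg$snr),
                        n_tot, cfg$early_range,
                        seed = cfg$master_seed),
    late = make_cohort(phantom_spec(grid_shape = cfg$grid_shape,
                                    snr = cfg$snr),
                       n_tot, cfg$late_range,
                       seed = cfg$master_seed + 1L))
  i_train <- seq_len(cfg$n_train)
  i_val <- cfg$n_train + seq_len(cfg$n_val)
  i_test <- cfg$n_train + cfg$n_val + seq_len(cfg$n_test)
  conditions <- list()
  for (method in cfg$gt_methods) {
    gts <- lapply(groups, function(ch)
      lapply(ch, subject_gt, method = method, solver_opts = cfg$solver_opts))
    subs <- lapply(names(groups), function(g)
      learner_subjects(groups[[g]], gts[[g]], n_sig))
    names(subs) <- names(groups)
    for (train_grp in names(groups)) {
      for (sd in cfg$train_seeds) {
        model <- train_once(cfg, subs[[train_grp]][i_train],
                            subs[[train_grp]][i_val], sd)
        for (test_grp in names(groups)) {
          ev <- evaluate_model(
            model, lapply(subs[[test_grp]][i_test], `[[`, "input"),
            gts[[test_grp]][i_test], groups[[test_grp]][i_test],
            cfg$patch_size)
          key <- sprintf("%s_train-%s_test-%s_seed%d", method, train_grp,
                         test_grp, sd)
          conditions[[key]] <- list(
            method = method, train_group = train_grp,
            test_group = test_grp, seed = sd,
            setting = if (train_grp == test_grp) "self" else "cross",
            ar = ev$ar, ae = ev$ae, afd_mape = ev$afd_mape,
            reports = ev$reports)
          if (!is.null(out_dir))
            save_condition(out_dir, key, conditions[[key]])
        }
      }
    }
  }
  rep <- structure(list(conditions = conditions, config = cfg,
                        experiment = "domain_shift"),
                   class = "experiment_report")
  if (!is.null(out_dir))
    write_manifest(out_dir, strip_config(cfg),
                   list(experiment = "domain_shift", n_sig = n_sig,
                        conditions = names(conditions)))
  rep
}

strip_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg[vapply(cfg, function(x) is.numeric(x) || is.character(x) ||
               is.logical(x), logical(1))]
}

save_condition <- function(dir, key, cond) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- cond[c("method", "ar", "ae", "afd_mape")]
  out$confusion <- lapply(cond$reports, function(r) r$confusion)
  jsonlite::write_json(out, file.path(dir, paste0(key, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report (", x$experiment, "), ",
      length(x$conditions), " condition(s)\n", sep = "")
  for (key in names(x$conditions)) {
    c <- x$conditions[[key]]
    cat(sprintf("  %-34s AR(1)=%5.1f AR(2)=%5.1f AE(1)=%5.1f dAFD=%5.1f\n",
                key, c$ar[1L], c$ar[2L], c$ae[1L], c$afd_mape))
  }
  invisible(x)
}
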