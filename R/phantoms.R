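# Region layout shared by all block phantoms: three slabs along x
# (tissue-A / tissue-B / fluid), giving sharp recovery tolerances.
region_index <- function(shape) {
  cut <- ceiling(shape[1] * c(1, 2) / 3)
  reg <- array(3L, shape)
  reg[seq_len(cut[1]), , ] <- 1L
  reg[setdiff(seq_len(cut[2]), seq_len(cut[1])), , ] <- 2L
  reg
}

region_map <- function(reg, values) array(values[reg], dim(reg))

#' Literature-plausible block-phantom truth maps
#'
#' Builds the default three-region (tissue-A / tissue-B / fluid) ground
#' truth for a modality: e.g. T2 {45, 80, 400} ms, CBF {60, 20, 0}
#' ml/100g/min, NODDI v_in {0.6, 0.4, 0} with v_iso 1 in the fluid region.
#'
#' @param modality one of "asl", "t1", "t2", "t2epg", "dwi_dti",
#'   "dwi_noddi", "dwi_noddi_te", "joint_gratio".
#' @param shape spatial dimensions (X, Y, Z).
#' @return named list of 3D truth parameter maps (plus fixed scalars).
#' @export
default_brainlike_truth <- function(modality, shape = c(9, 9, 3)) {
  stopifnot(shape[1] >= 3)
  reg <- region_index(shape)
  switch(modality,
    asl = list(region = reg,
               cbf = region_map(reg, c(60, 20, 0)),
               m0 = region_map(reg, c(1000, 1000, 1200)),
               control = region_map(reg, c(1000, 1000, 1200))),
    t1 = list(region = reg,
              s0 = region_map(reg, c(1000, 1000, 1000)),
              t1_ms = region_map(reg, c(1400, 800, 4000))),
    t2 = list(region = reg,
              s0 = region_map(reg, c(1000, 1000, 1000)),
              t2_ms = region_map(reg, c(45, 80, 400))),
    t2epg = list(region = reg,
                 s0 = region_map(reg, c(1000, 1000, 1000)),
                 t2_grid_ms = c(20, 80, 400),
                 fractions = list(region_map(reg, c(0.15, 0.10, 0)),
                                  region_map(reg, c(0.80, 0.85, 0)),
                                  region_map(reg, c(0.05, 0.05, 1))),
                 alpha = region_map(reg, c(2.6, 2.6, 2.6))),
    dwi_dti = list(region = reg,
                   s0 = region_map(reg, c(1000, 1000, 1000)),
                   # rows: Dxx,Dxy,Dxz,Dyy,Dyz,Dzz per region (mm^2/s)
                   tensors = rbind(c(1.7e-3, 0, 0, 0.3e-3, 0, 0.3e-3),
                                   c(0.8e-3, 0, 0, 0.8e-3, 0, 0.8e-3),
                                   c(3.0e-3, 0, 0, 3.0e-3, 0, 3.0e-3))),
    dwi_noddi = ,
    dwi_noddi_te = list(region = reg,
                        s0 = region_map(reg, c(1000, 1000, 1000)),
                        v_in = region_map(reg, c(0.6, 0.4, 0)),
                        v_iso = region_map(reg, c(0.05, 0.10, 1)),
                        gamma = region_map(reg, c(0.15, 0.40, 0.5)),
                        theta = region_map(reg, c(0, pi / 2, 0)),
                        phi = region_map(reg, c(0, 0, 0))),
    joint_gratio = list(region = reg,
                        s_a0 = region_map(reg, c(1000, 1000, 1000)),
                        s_b0 = region_map(reg, c(1000, 1000, 1000)),
                        v_in = region_map(reg, c(0.55, 0.45, 0.5)),
                        v_iso = region_map(reg, c(0.05, 0.10, 0.08)),
                        gamma = region_map(reg, c(0.20, 0.35, 0.25)),
                        theta = region_map(reg, c(0, pi / 2, pi / 4)),
                        phi = region_map(reg, c(0, 0, pi / 4)),
                        v_mwf = region_map(reg, c(0.15, 0.12, 0.18))),
    stop(sprintf("unknown phantom modality '%s'", modality))
  )
}

default_phantom_schedule <- function(modality) {
  switch(modality,
    asl = acquisition_schedule(60, pair_labels = rep(c("control", "label"), 30)),
    t1 = acquisition_schedule(5, ti_ms = c(500, 1000, 2000, 3500, 5000)),
    t2 = acquisition_schedule(19, te_spacing_ms = 12),
    t2epg = acquisition_schedule(32, te_spacing_ms = 12),
    dwi_dti = ,
    dwi_noddi = dwi_shell_schedule(),
    dwi_noddi_te = dwi_shell_schedule(te_dwi_ms = 80,
                                      b0_te_ms = c(80, 130, 180, 230)),
    joint_gratio = list(dwi = dwi_shell_schedule(),
                        t2 = acquisition_schedule(32, te_spacing_ms = 12)),
    stop(sprintf("unknown phantom modality '%s'", modality))
  )
}

#' Multi-shell diffusion schedule matching the reference acquisition
#'
#' 12 b=0 volumes plus 8/32/72 directions at b = 300/700/2000 s/mm^2,
#' directions drawn per shell from deterministic Fibonacci point sets.
#' Optionally assigns echo times: a fixed TE for all diffusion-weighted
#' volumes and a variable-TE replacement for the b=0 volumes (for the
#' TE-augmented NODDI design).
#'
#' @param n_b0 number of b = 0 volumes.
#' @param shells nonzero b-values (s/mm^2).
#' @param n_dirs directions per shell.
#' @param te_dwi_ms optional fixed TE of the diffusion-weighted volumes.
#' @param b0_te_ms optional TE cycle assigned to the b = 0 volumes.
#' @return an \code{\link{acquisition_schedule}}.
#' @export
dwi_shell_schedule <- function(n_b0 = 12, shells = c(300, 700, 2000),
                               n_dirs = c(8, 32, 72), te_dwi_ms = NULL,
                               b0_te_ms = NULL) {
  bvals <- c(rep(0, n_b0), rep(shells, n_dirs))
  bvecs <- matrix(0, n_b0, 3)
  for (i in seq_along(shells)) {
    bvecs <- rbind(bvecs, fibonacci_sphere(n_dirs[i]))
  }
  te <- NULL
  if (!is.null(te_dwi_ms)) {
    te <- rep(te_dwi_ms, length(bvals))
    if (!is.null(b0_te_ms)) {
      te[bvals == 0] <- rep(b0_te_ms, length.out = n_b0)
    }
  }
  acquisition_schedule(length(bvals), te_ms = te, bvals_s_per_mm2 = bvals,
                       bvecs = bvecs)
}

phantom_noiseless <- function(modality, truth, schedule, shape) {
  n_vox <- prod(shape)
  reg <- truth$region
  make_series <- function(sig_by_region, t_len) {
    # sig_by_region: 3 x T matrix of region time-courses
    m <- sig_by_region[as.integer(reg), , drop = FALSE]
    array(m, c(shape, t_len))
  }
  regions_tc <- function(fun, t_len) {
    t(vapply(1:3, function(r) {
      if (!any(reg == r)) return(numeric(t_len))   # absent region
      fun(r)
    }, numeric(t_len)))
  }
  switch(modality,
    asl = {
      params <- asl_params(pld_ms = 1800, tau_ms = 1650)
      t_len <- schedule$n_volumes
      # per-slice scaling: invert the PCASL equation for the label signal
      series <- array(0, c(shape, t_len))
      is_control <- schedule$pair_labels == "control"
      for (k in seq_len(shape[3])) {
        sc <- asl_scaling_pcasl(params, k - 1L)
        dsig <- truth$cbf[, , k] * truth$m0[, , k] / sc
        for (t in seq_len(t_len)) {
          base <- array(truth$control[, , k], shape[1:2])
          series[, , k, t] <- if (is_control[t]) base else base - dsig
        }
      }
      attr(series, "asl_params") <- params
      series
    },
    t1 = make_series(regions_tc(function(r) {
      t1_forward(schedule$ti_ms, truth$s0[match(r, reg)][1],
                 truth$t1_ms[match(r, reg)][1], schedule$tr_ms, "saturation")
    }, schedule$n_volumes), schedule$n_volumes),
    t2 = make_series(regions_tc(function(r) {
      t2_forward(schedule$te_ms, truth$s0[match(r, reg)][1],
                 truth$t2_ms[match(r, reg)][1])
    }, schedule$n_volumes), schedule$n_volumes),
    t2epg = {
      esp <- diff(schedule$te_ms)[1]
      n_e <- schedule$n_volumes
      make_series(regions_tc(function(r) {
        i <- match(r, reg)
        fr <- vapply(truth$fractions, function(f) f[i], 1.0)
        basis <- epg_basis(n_e, esp, truth$alpha[i], truth$t2_grid_ms)
        truth$s0[i] * as.numeric(basis %*% fr)
      }, n_e), n_e)
    },
    dwi_dti = {
      b <- schedule$bvals_s_per_mm2; g <- schedule$bvecs
      make_series(regions_tc(function(r) {
        i <- match(r, reg)
        d6 <- truth$tensors[r, ]
        d <- matrix(c(d6[1], d6[2], d6[3], d6[2], d6[4], d6[5],
                      d6[3], d6[5], d6[6]), 3, 3)
        truth$s0[i] * exp(-b * rowSums((g %*% d) * g))
      }, schedule$n_volumes), schedule$n_volumes)
    },
    dwi_noddi = {
      ctx <- noddi_context(schedule)
      make_series(regions_tc(function(r) {
        i <- match(r, reg)
        noddi_signal(ctx, truth$v_in[i], truth$v_iso[i], truth$gamma[i],
                     truth$s0[i], truth$theta[i], truth$phi[i])
      }, schedule$n_volumes), schedule$n_volumes)
    },
    dwi_noddi_te = {
      ctx <- noddi_context(schedule)
      tc <- t2_constants()
      fwm <- exp(-schedule$te_ms / tc$t2_wm_ms)
      fiso <- exp(-schedule$te_ms / tc$t2_iso_ms)
      make_series(regions_tc(function(r) {
        i <- match(r, reg)
        noddi_te_signal(ctx, fwm, fiso, truth$v_in[i], truth$v_iso[i],
                        truth$gamma[i], truth$s0[i], truth$theta[i],
                        truth$phi[i])
      }, schedule$n_volumes), schedule$n_volumes)
    },
    joint_gratio = {
      ctx <- noddi_context(schedule$dwi)
      tc <- t2_constants()
      dwi <- make_series(regions_tc(function(r) {
        i <- match(r, reg)
        noddi_signal(ctx, truth$v_in[i], truth$v_iso[i], truth$gamma[i],
                     truth$s_a0[i], truth$theta[i], truth$phi[i])
      }, schedule$dwi$n_volumes), schedule$dwi$n_volumes)
      t2s <- make_series(regions_tc(function(r) {
        i <- match(r, reg)
        joint_t2_signal(schedule$t2$te_ms, tc, truth$s_b0[i],
                        truth$v_mwf[i], truth$v_iso[i])
      }, schedule$t2$n_volumes), schedule$t2$n_volumes)
      list(dwi = dwi, t2 = t2s)
    },
    stop(sprintf("unknown phantom modality '%s'", modality))
  )
}

add_noise <- function(arr, sigma, noise_model) {
  if (sigma <= 0) return(arr)
  if (noise_model == "gaussian") {
    arr + array(stats::rnorm(length(arr), 0, sigma), dim(arr))
  } else {
    re <- arr + array(stats::rnorm(length(arr), 0, sigma), dim(arr))
    im <- array(stats::rnorm(length(arr), 0, sigma), dim(arr))
    sqrt(re^2 + im^2)
  }
}

#' Generate a seeded synthetic phantom series with known ground truth
#'
#' Forward-simulates a 4D series from region-wise constant truth maps under
#' the modality's signal model and adds Gaussian noise with
#' sigma = mean(S0) / snr (snr = Inf gives the noiseless series). Identical
#' (spec, seed) inputs give bit-identical output.
#'
#' @param modality see \code{\link{default_brainlike_truth}}.
#' @param shape spatial dimensions.
#' @param snr signal-to-noise ratio S0/sigma; Inf for noiseless.
#' @param seed RNG seed for the noise realisation.
#' @param truth optional truth-map list overriding the default.
#' @param schedule optional \code{\link{acquisition_schedule}} override.
#' @param noise_model "gaussian" (the package's noise assumption) or
#'   "rician" (robustness experiments only).
#' @return list with \code{voxels} (or \code{voxels_dwi}/\code{voxels_t2}
#'   for the joint modality), \code{noiseless}, \code{schedule},
#'   \code{truth}, \code{mask}, \code{sigma} and \code{seed}.
#' @export
generate_phantom <- function(modality, shape = c(9, 9, 3), snr = Inf,
                             seed = 1L, truth = NULL, schedule = NULL,
                             noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  stopifnot(snr > 0)
  if (is.null(truth)) truth <- default_brainlike_truth(modality, shape)
  if (is.null(schedule)) schedule <- default_phantom_schedule(modality)
  noiseless <- phantom_noiseless(modality, truth, schedule, shape)

  s0_name <- intersect(c("s0", "s_a0", "m0"), names(truth))[1]
  sigma <- if (is.infinite(snr)) 0 else mean(truth[[s0_name]]) / snr
  if (sigma > 0) set.seed(seed)

  out <- list(schedule = schedule, truth = truth,
              mask = array(TRUE, shape), sigma = sigma, seed = seed,
              modality = modality)
  if (modality == "joint_gratio") {
    out$noiseless <- noiseless
    out$voxels_dwi <- add_noise(noiseless$dwi, sigma, noise_model)
    out$voxels_t2 <- add_noise(noiseless$t2, sigma, noise_model)
  } else {
    out$noiseless <- noiseless
    out$voxels <- add_noise(noiseless, sigma, noise_model)
    if (modality == "asl") attr(out$voxels, "asl_params") <- attr(noiseless, "asl_params")
  }
  out
}
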