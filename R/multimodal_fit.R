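#' Fixed compartment T2 constants for the multi-modal models
#'
#' The TE-augmented NODDI and joint g-ratio models hold the
#' compartment T2s fixed: white-matter (intra+extra cellular) water, free
#' (isotropic) water, and - for the joint g-ratio T2 block - myelin water.
#'
#' @param t2_wm_ms white-matter water T2 (ms).
#' @param t2_iso_ms free-water T2 (ms); must exceed t2_wm_ms.
#' @param t2_myelin_ms myelin-water T2 (ms), used by the joint g-ratio fit.
#' @return a \code{qmr_t2_constants} list.
#' @export
t2_constants <- function(t2_wm_ms = 80, t2_iso_ms = 400, t2_myelin_ms = 20) {
  stopifnot(t2_iso_ms > t2_wm_ms, t2_wm_ms > 0, t2_myelin_ms > 0)
  structure(list(t2_wm_ms = t2_wm_ms, t2_iso_ms = t2_iso_ms,
                 t2_myelin_ms = t2_myelin_ms), class = "qmr_t2_constants")
}

noddi_te_signal <- function(ctx, fwm, fiso, v_in, v_iso, gamma, s0, theta,
                            phi) {
  mu <- sph_to_unit(theta, phi)
  d_par <- ctx$d_parallel
  d_perp <- d_par * (1 - v_in)
  if (gamma < 1e-5) {
    gm2 <- as.numeric((ctx$g %*% mu)^2)
    a_in <- exp(-ctx$b * d_par * gm2)
    rtd <- d_perp + (d_par - d_perp) * gm2
  } else {
    ct2 <- as.numeric((ctx$dirs %*% mu)^2)
    w <- watson_weights(ct2, gamma)
    a_in <- as.numeric(ctx$e_stick %*% w)
    rtd <- d_perp + (d_par - d_perp) * as.numeric(ctx$gn2 %*% w)
  }
  a_ex <- exp(-ctx$b * rtd)
  v_ex <- 1 - v_in - v_iso
  s0 * ((v_in * a_in + v_ex * a_ex) * fwm + v_iso * ctx$e_iso * fiso)
}

#' TE-augmented NODDI forward model
#'
#' S = S0 [(v_in A_in + v_ex A_ex) exp(-TE/T2_wm)
#'        + v_iso exp(-b d_iso) exp(-TE/T2_iso)].
#' At b = 0 this reduces to a two-component T2 model, which ties v_iso
#' across the diffusion and relaxometry parts of the acquisition.
#'
#' @inheritParams noddi_forward
#' @param schedule schedule carrying b-values, directions and a per-volume
#'   TE vector (typically only the b=0 volumes vary in TE).
#' @param constants \code{\link{t2_constants}}.
#' @return predicted signal vector.
#' @export
noddi_te_forward <- function(params, schedule, constants = t2_constants(),
                             n_samples = 724, d_parallel = 1.7e-3,
                             d_iso = 3e-3) {
  if (is.null(schedule$te_ms)) stop("schedule has no TE list")
  p <- as.numeric(unlist(params))
  ctx <- noddi_context(schedule, n_samples, d_parallel, d_iso)
  fwm <- exp(-schedule$te_ms / constants$t2_wm_ms)
  fiso <- exp(-schedule$te_ms / constants$t2_iso_ms)
  noddi_te_signal(ctx, fwm, fiso, p[1], p[2], p[3], p[4], p[5], p[6])
}

#' Voxelwise TE-augmented NODDI fit
#'
#' Fits the same six parameters as \code{\link{fit_noddi}} but under the
#' TE-aware signal model, which separates free water from tissue using the
#' T2 contrast of the variable-TE b=0 volumes. With a single distinct TE the
#' model is TE-blind and the fit falls back to standard NODDI with a
#' warning.
#'
#' @inheritParams fit_noddi
#' @param constants \code{\link{t2_constants}}.
#' @return voxelwise outputs; mcmap volumes
#'   [v_in, v_iso, gamma, S0, theta, phi]. The fitted S0 is the signal
#'   before T2 decay.
#' @export
fit_noddi_te <- function(voxels, schedule, constants = t2_constants(),
                         mask = NULL, n_samples = 724, d_parallel = 1.7e-3,
                         d_iso = 3e-3,
                         config = solver_config(max_iterations = 200,
                                                residual_tolerance = 1e-12)) {
  te <- schedule$te_ms
  if (is.null(te) || length(unique(te)) < 2) {
    warning("fewer than 2 distinct TEs: falling back to standard NODDI")
    return(fit_noddi(voxels, schedule, mask, n_samples, d_parallel, d_iso,
                     config = config))
  }
  b <- schedule$bvals_s_per_mm2
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  ctx <- noddi_context(schedule, n_samples, d_parallel, d_iso)
  fwm <- exp(-te / constants$t2_wm_ms)
  fiso <- exp(-te / constants$t2_iso_ms)

  dti <- fit_dti(voxels, schedule, mask)
  n_vox <- prod(dm[1:3])
  fa_v <- as.numeric(dti$fa); md_v <- as.numeric(dti$md)
  pdd_m <- matrix(dti$pdd, n_vox, 3)
  lower <- c(0, 0, 1e-3, 0, -Inf, -Inf)
  upper <- c(1, 1, 1, Inf, Inf, Inf)

  fit_one <- function(y, v) {
    if (all(y == 0)) return(NULL)
    pdd <- pdd_m[v, ]
    if (all(pdd == 0)) pdd <- c(0, 0, 1)
    ang <- canonical_angles(acos(pmin(pmax(pdd[3], -1), 1)),
                            atan2(pdd[2], pdd[1]))
    v_iso0 <- min(max((md_v[v] - 0.7e-3) / (d_iso - 0.7e-3), 0.02), 0.95)
    v_in0 <- min(max(fa_v[v], 0.05), 0.9) * (1 - v_iso0)
    s0_0 <- if (any(b == 0)) max(y[b == 0]) / max(fwm[b == 0]) else max(y)
    b0 <- c(v_in0, v_iso0, 0.4, s0_0, ang[1], ang[2])
    model <- function(p) noddi_te_signal(ctx, fwm, fiso, p[1], p[2], p[3],
                                         p[4], p[5], p[6])
    pr <- nonlinear_problem(model, b0, lower = lower, upper = upper,
                            project = noddi_project)
    res <- fit_nonlinear(pr, y, config)
    res$params[5:6] <- canonical_angles(res$params[5], res$params[6])
    res$syn <- model(res$params)
    res
  }
  out <- fit_voxelwise(voxels, mask, 6L, fit_one)
  out$dti_init <- dti
  out
}

#' Two-step g-ratio from intra-axonal and myelin water fraction maps
#'
#' Rescales the diffusion intra-cellular fraction to the whole-voxel frame,
#' v_in' = v_in (1 - v_mwf), and evaluates
#' Gamma = (v_mwf / v_in' + 1)^(-1/2). Voxels with v_in' = 0 but
#' v_mwf > 0 are degenerate (Gamma = 0, flagged).
#'
#' @param v_in intra-cellular volume fraction map (from NODDI), in [0, 1].
#' @param v_mwf myelin water fraction map (from T2 relaxometry), in [0, 1].
#' @return list(gratio, v_in_prime, flagged), same shape as the inputs.
#' @export
gratio_two_step <- function(v_in, v_mwf) {
  if (any(v_in < 0 | v_in > 1, na.rm = TRUE) ||
      any(v_mwf < 0 | v_mwf > 1, na.rm = TRUE)) {
    stop("v_in and v_mwf must lie in [0, 1]")
  }
  v_in_prime <- v_in * (1 - v_mwf)
  gr <- ifelse(v_mwf == 0, 1,
               ifelse(v_in_prime > 0, (v_mwf / v_in_prime + 1)^(-0.5), 0))
  flagged <- v_in_prime == 0 & v_mwf > 0
  if (is.array(v_in)) {
    gr <- array(gr, dim(v_in)); flagged <- array(flagged, dim(v_in))
    v_in_prime <- array(v_in_prime, dim(v_in))
  }
  list(gratio = gr, v_in_prime = v_in_prime, flagged = flagged)
}

# Invert Gamma = (v_mwf/v_in' + 1)^(-1/2) for v_mwf given (Gamma, v_in):
# with c = v_in (1 - Gamma^2)/Gamma^2, v_mwf = c / (1 + c).
v_mwf_from_gratio <- function(gratio, v_in) {
  cc <- v_in * (1 - gratio^2) / gratio^2
  cc / (1 + cc)
}

joint_t2_signal <- function(te, tc, s_b0, v_mwf, v_iso) {
  s_b0 * (v_mwf * exp(-te / tc$t2_myelin_ms) +
            (1 - v_mwf) * (1 - v_iso) * exp(-te / tc$t2_wm_ms) +
            (1 - v_mwf) * v_iso * exp(-te / tc$t2_iso_ms))
}

#' Joint (coupled) g-ratio estimation from DWI and T2 relaxometry
#'
#' Single Levenberg-Marquardt optimisation over the stacked DWI and T2
#' residual blocks. The DWI block is the NODDI model with its own S0
#' (parameters S_a0, v_in, gamma, theta, phi); the T2 block is a
#' three-compartment decay (myelin / tissue / free water, fixed T2s) with
#' its own S0. The g-ratio Gamma and v_iso are single shared unknowns:
#' Gamma is parameterised directly and the myelin fraction is derived from
#' (Gamma, v_in) by inverting the g-ratio relation, which guarantees
#' internal consistency; all T2 compartment fractions carry the
#' (1 - v_mwf) rescaling. The DWI residuals are down-weighted by
#' \code{weight_dwi} (multiplied by its square root) so the T2 data dominate
#' the shared v_iso estimate. If the joint fit does not converge, the
#' two-step result is returned for that voxel with a flag.
#'
#' @param dwi_voxels,dwi_schedule the diffusion series and its schedule.
#' @param t2_voxels,t2_schedule the multi-echo T2 series and its schedule.
#' @param mask 3D logical array on the common grid.
#' @param weight_dwi relative weight of the DWI residual block (default
#'   0.2).
#' @param constants \code{\link{t2_constants}}.
#' @param n_samples,d_parallel,d_iso NODDI forward-model settings.
#' @param config \code{\link{solver_config}}.
#' @return voxelwise outputs; mcmap volumes
#'   [v_in, v_iso, gamma, S_a0, theta, phi, S_b0, Gamma], plus derived
#'   \code{gratio}, \code{v_mwf} maps, the \code{two_step} result, and a
#'   \code{fallback} map marking voxels where the two-step result was
#'   substituted.
#' @export
fit_joint_gratio <- function(dwi_voxels, dwi_schedule, t2_voxels, t2_schedule,
                             mask = NULL, weight_dwi = 0.2,
                             constants = t2_constants(), n_samples = 724,
                             d_parallel = 1.7e-3, d_iso = 3e-3,
                             config = solver_config(max_iterations = 200,
                                                    residual_tolerance = 1e-12)) {
  dm <- dim(dwi_voxels)
  if (!all(dim(t2_voxels)[1:3] == dm[1:3])) {
    stop("DWI and T2 series must share a spatial grid")
  }
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  te <- t2_schedule$te_ms
  if (is.null(te)) stop("T2 schedule has no TE list")
  n_dwi <- dm[4]; n_te <- dim(t2_voxels)[4]

  # two-step path: NODDI on the DWI block, spectrum fit on the T2 block
  nod <- fit_noddi(dwi_voxels, dwi_schedule, mask, n_samples, d_parallel,
                   d_iso, config = config)
  grid3 <- c(constants$t2_myelin_ms, constants$t2_wm_ms, constants$t2_iso_ms)
  t2fit <- fit_t2_multicomponent(t2_voxels, t2_schedule, grid3, mask)
  v_in_map <- nod$mcmap[, , , 1, drop = FALSE]; dim(v_in_map) <- dm[1:3]
  v_mwf_map <- t2fit$mcmap[, , , 1, drop = FALSE]; dim(v_mwf_map) <- dm[1:3]
  two_step <- gratio_two_step(v_in_map, v_mwf_map)

  ctx <- noddi_context(dwi_schedule, n_samples, d_parallel, d_iso)
  sw <- sqrt(weight_dwi)
  n_vox <- prod(dm[1:3])
  nod_mc <- matrix(nod$mcmap, n_vox, 6)
  t2_mc <- matrix(t2fit$mcmap, n_vox, 4)

  joint <- array(0, c(dm[1:3], n_dwi + n_te))
  joint[, , , seq_len(n_dwi)] <- dwi_voxels
  joint[, , , n_dwi + seq_len(n_te)] <- t2_voxels

  lower <- c(0, 0, 1e-3, 0, -Inf, -Inf, 0, 1e-3)
  upper <- c(1, 1, 1, Inf, Inf, Inf, Inf, 1)
  project <- function(p) { p[1:2] <- noddi_project(p[1:2]); p }
  tc <- constants

  model <- function(p) {
    v_mwf <- v_mwf_from_gratio(p[8], p[1])
    c(sw * noddi_signal(ctx, p[1], p[2], p[3], p[4], p[5], p[6]),
      joint_t2_signal(te, tc, p[7], v_mwf, p[2]))
  }

  fallback <- array(FALSE, dm[1:3])
  fit_one <- function(y, v) {
    if (all(y == 0)) return(NULL)
    y_w <- c(sw * y[seq_len(n_dwi)], y[n_dwi + seq_len(n_te)])
    g0 <- min(max(two_step$gratio[v], 0.05), 0.999)
    b0 <- c(nod_mc[v, 1:3], nod_mc[v, 4], nod_mc[v, 5:6], t2_mc[v, 4], g0)
    b0[1] <- min(max(b0[1], 1e-3), 0.999)
    pr <- nonlinear_problem(model, b0, lower = lower, upper = upper,
                            project = project)
    res <- fit_nonlinear(pr, y_w, config)
    if (!res$converged) {
      fallback[v] <<- TRUE
      res$params <- c(nod_mc[v, ], t2_mc[v, 4], g0)
    }
    res$params[5:6] <- canonical_angles(res$params[5], res$params[6])
    res$syn <- model(res$params)
    res
  }
  out <- fit_voxelwise(joint, mask, 8L, fit_one)
  gr <- out$mcmap[, , , 8, drop = FALSE]; dim(gr) <- dm[1:3]
  vin <- out$mcmap[, , , 1, drop = FALSE]; dim(vin) <- dm[1:3]
  out$gratio <- gr
  out$v_mwf <- array(v_mwf_from_gratio(pmax(gr, 1e-6), vin), dm[1:3])
  out$two_step <- two_step
  out$v_mwf_two_step <- v_mwf_map
  out$fallback <- fallback
  out$shared_parameters <- c("gratio", "v_iso")
  out
}
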