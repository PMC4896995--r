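#' Voxelwise isotropic ADC fit
#'
#' Fits [S0, d] in S = S0 exp(-b d), either by log-linear least squares on
#' ln S (non-positive samples excluded per observation) or by nonlinear
#' least squares on the raw signal started from the log-linear solution.
#'
#' @param voxels 4D series.
#' @param schedule \code{\link{acquisition_schedule}} with b-values.
#' @param method "loglinear" or "nonlinear".
#' @param mask 3D logical array.
#' @param config \code{\link{solver_config}} (nonlinear method).
#' @return voxelwise outputs; mcmap volumes [S0, d(mm^2/s)].
#' @export
fit_adc <- function(voxels, schedule, method = c("loglinear", "nonlinear"),
                    mask = NULL, config = solver_config()) {
  method <- match.arg(method)
  b <- schedule$bvals_s_per_mm2
  if (is.null(b)) stop("schedule has no b-values")
  if (length(unique(b)) < 2) stop("at least 2 distinct b-values are required")
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])

  fit_one <- function(y, v) {
    use <- y > 0
    if (sum(use) < 2) return(NULL)
    beta <- solve_ls(cbind(1, -b[use]), log(y[use]))
    pars <- c(exp(beta[1]), beta[2])
    if (method == "nonlinear") {
      pr <- nonlinear_problem(function(p) p[1] * exp(-b * p[2]), pars,
                              lower = c(0, -1e-2), upper = c(Inf, 1e-1))
      pars <- fit_nonlinear(pr, y, config)$params
    }
    syn <- pars[1] * exp(-b * pars[2])
    list(params = pars, residual = sum((y - syn)^2), param_errors = NULL,
         syn = syn, converged = TRUE)
  }
  fit_voxelwise(voxels, mask, 2L, fit_one)
}

#' Scalar metrics of a diffusion tensor
#'
#' @param d6 the 6 unique tensor elements (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return list with eigenvalues (descending), md, fa, and the principal
#'   diffusion direction (sign fixed to non-negative z, then y, then x).
#' @export
dti_metrics <- function(d6) {
  d <- matrix(c(d6[1], d6[2], d6[3],
                d6[2], d6[4], d6[5],
                d6[3], d6[5], d6[6]), 3, 3)
  eg <- eigen(d, symmetric = TRUE)
  ev <- eg$values            # descending
  md <- mean(ev)
  denom <- sqrt(sum(ev^2))
  fa <- if (denom > 0) sqrt(1.5 * sum((ev - md)^2)) / denom else 0
  pdd <- eg$vectors[, 1]
  flip <- if (pdd[3] != 0) sign(pdd[3]) else if (pdd[2] != 0) sign(pdd[2]) else
    if (pdd[1] != 0) sign(pdd[1]) else 1
  pdd <- pdd * flip
  list(evals = ev, md = md, fa = fa, pdd = pdd)
}

#' Voxelwise diffusion tensor fit
#'
#' Linear least squares for [ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz] on the log
#' signal, with design rows
#' (1, -b gx^2, -2b gx gy, -2b gx gz, -b gy^2, -2b gy gz, -b gz^2).
#' The tensor is diagonalised for MD, FA and the principal diffusion
#' direction. mcmap volume order: the 6 tensor elements then S0.
#'
#' @inheritParams fit_adc
#' @return voxelwise outputs plus 3D \code{md}, \code{fa} and 4D \code{pdd}
#'   maps.
#' @export
fit_dti <- function(voxels, schedule, mask = NULL) {
  b <- schedule$bvals_s_per_mm2
  g <- schedule$bvecs
  if (is.null(b) || is.null(g)) stop("schedule needs b-values and b-vectors")
  design <- cbind(1, -b * g[, 1]^2, -2 * b * g[, 1] * g[, 2],
                  -2 * b * g[, 1] * g[, 3], -b * g[, 2]^2,
                  -2 * b * g[, 2] * g[, 3], -b * g[, 3]^2)
  if (qr(design)$rank < 7) {
    stop("rank-deficient direction set: at least 6 non-collinear directions plus b=0 required")
  }
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])

  fit_one <- function(y, v) {
    use <- y > 0
    if (sum(use) < 7) return(NULL)
    a <- design[use, , drop = FALSE]
    if (qr(a)$rank < 7) return(NULL)
    beta <- solve_ls(a, log(y[use]))
    s0 <- exp(beta[1])
    d6 <- beta[2:7]
    syn <- exp(as.numeric(design %*% beta))
    list(params = c(d6, s0), residual = sum((y - syn)^2),
         param_errors = NULL, syn = syn, converged = TRUE)
  }
  out <- fit_voxelwise(voxels, mask, 7L, fit_one)

  n_vox <- prod(dm[1:3])
  mc <- matrix(out$mcmap, n_vox, 7)
  md <- fa <- numeric(n_vox)
  pdd <- matrix(0, n_vox, 3)
  for (v in which(as.logical(mask))) {
    met <- dti_metrics(mc[v, 1:6])
    md[v] <- met$md; fa[v] <- met$fa; pdd[v, ] <- met$pdd
  }
  out$md <- array(md, dm[1:3])
  out$fa <- array(fa, dm[1:3])
  out$pdd <- array(pdd, c(dm[1:3], 3))
  out
}

# --- Watson-dispersed stick machinery for NODDI ---------------------------

#' Deterministic Fibonacci-sphere direction set
#' @param n number of points.
#' @return n x 3 matrix of unit vectors covering the sphere quasi-uniformly.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

# Orientation-dispersion index gamma in (0,1] -> Watson concentration kappa.
watson_kappa <- function(gamma) 1 / tan(gamma * pi / 2)

sph_to_unit <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Normalised Watson density weights over a fixed point set.
# ct2: (mu . n_i)^2 per sample; computed as exp(kappa (t^2 - 1)) for
# overflow-safe normalisation at high concentration.
watson_weights <- function(ct2, gamma) {
  w <- exp(watson_kappa(gamma) * (ct2 - 1))
  w / sum(w)
}

# Precompute the schedule-dependent pieces of the NODDI forward model.
noddi_context <- function(schedule, n_samples = 724, d_parallel = 1.7e-3,
                          d_iso = 3e-3) {
  b <- schedule$bvals_s_per_mm2
  g <- schedule$bvecs
  if (is.null(b) || is.null(g)) stop("schedule needs b-values and b-vectors")
  if (n_samples < 30) {
    warning("fewer than 30 Watson samples: quadrature error may be large")
  }
  dirs <- fibonacci_sphere(n_samples)
  gn2 <- (g %*% t(dirs))^2            # T x n: (r . n)^2
  list(b = b, g = g, dirs = dirs, gn2 = gn2,
       e_stick = exp(-b * d_parallel * gn2),
       e_iso = exp(-b * d_iso),
       d_parallel = d_parallel, d_iso = d_iso)
}

noddi_signal <- function(ctx, v_in, v_iso, gamma, s0, theta, phi) {
  mu <- sph_to_unit(theta, phi)
  d_par <- ctx$d_parallel
  d_perp <- d_par * (1 - v_in)        # tortuosity coupling
  if (gamma < 1e-5) {                 # zero-dispersion limit: stick at mu
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
  s0 * (v_in * a_in + v_ex * a_ex + v_iso * ctx$e_iso)
}

#' NODDI forward signal model
#'
#' Three-compartment signal
#' S = S0 (v_in A_in + v_ex A_ex + v_iso exp(-b d_iso)) with Watson-dispersed
#' sticks: A_in averages the stick response exp(-b d_par (r.n)^2) over a
#' deterministic Fibonacci direction set weighted by the Watson density with
#' axis (theta, phi) and concentration kappa = 1/tan(gamma pi/2); A_ex is a
#' zeppelin with the Watson-averaged orientation tensor and tortuosity
#' radial diffusivity d_perp = d_par (1 - v_in).
#'
#' @param params named list or vector [v_in, v_iso, gamma, s0, theta, phi].
#' @param schedule \code{\link{acquisition_schedule}} with b-values and
#'   directions.
#' @param n_samples Watson quadrature size (default 724).
#' @param d_parallel intra-cellular parallel diffusivity (mm^2/s).
#' @param d_iso free-water diffusivity (mm^2/s, default 3e-3).
#' @return predicted signal vector.
#' @export
noddi_forward <- function(params, schedule, n_samples = 724,
                          d_parallel = 1.7e-3, d_iso = 3e-3) {
  p <- as.numeric(unlist(params))
  ctx <- noddi_context(schedule, n_samples, d_parallel, d_iso)
  noddi_signal(ctx, p[1], p[2], p[3], p[4], p[5], p[6])
}

# Canonicalise (theta, phi) so theta in [0, pi], phi in [0, 2pi), axis sign
# fixed to non-negative z (sticks are antipodally symmetric).
canonical_angles <- function(theta, phi) {
  mu <- sph_to_unit(theta, phi)
  flip <- if (mu[3] != 0) sign(mu[3]) else if (mu[2] != 0) sign(mu[2]) else
    if (mu[1] != 0) sign(mu[1]) else 1
  mu <- mu * flip
  c(theta = acos(pmin(pmax(mu[3], -1), 1)),
    phi = atan2(mu[2], mu[1]) %% (2 * pi))
}

noddi_project <- function(b) {
  b[1] <- min(max(b[1], 0), 1)
  b[2] <- min(max(b[2], 0), 1)
  tot <- b[1] + b[2]
  if (tot > 1) { b[1] <- b[1] / tot; b[2] <- b[2] / tot }
  b
}

#' Voxelwise NODDI fit
#'
#' Levenberg-Marquardt minimisation of the Gaussian chi-square over
#' [v_in, v_iso, gamma, S0, theta, phi], initialised from a diffusion tensor
#' fit of the same data (PDD for the orientation; FA- and MD-based guesses
#' for the fractions). Fractions are kept in the simplex
#' (v_in + v_iso <= 1) and gamma in [0, 1]. Jacobians are computed by
#' central finite differences through the shared engine.
#'
#' @inheritParams fit_adc
#' @param n_samples Watson quadrature size.
#' @param d_parallel,d_iso fixed compartment diffusivities (mm^2/s).
#' @param init optional 4D init map with 6 volumes in mcmap order.
#' @return voxelwise outputs; mcmap volumes
#'   [v_in, v_iso, gamma, S0, theta, phi].
#' @export
fit_noddi <- function(voxels, schedule, mask = NULL, n_samples = 724,
                      d_parallel = 1.7e-3, d_iso = 3e-3, init = NULL,
                      config = solver_config(max_iterations = 200,
                                             residual_tolerance = 1e-12)) {
  b <- schedule$bvals_s_per_mm2
  shells <- unique(b[b > 0])
  if (length(shells) < 2) {
    warning("fewer than 2 nonzero shells: NODDI parameters may be poorly determined")
  }
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  ctx <- noddi_context(schedule, n_samples, d_parallel, d_iso)
  dti <- fit_dti(voxels, schedule, mask)
  n_vox <- prod(dm[1:3])
  fa_v <- as.numeric(dti$fa); md_v <- as.numeric(dti$md)
  pdd_m <- matrix(dti$pdd, n_vox, 3)
  init_mat <- if (!is.null(init)) matrix(init, n_vox, 6) else NULL

  lower <- c(0, 0, 1e-3, 0, -Inf, -Inf)
  upper <- c(1, 1, 1, Inf, Inf, Inf)

  fit_one <- function(y, v) {
    if (all(y == 0)) return(NULL)
    if (!is.null(init_mat) && all(is.finite(init_mat[v, ]))) {
      b0 <- init_mat[v, ]
    } else {
      pdd <- pdd_m[v, ]
      if (all(pdd == 0)) pdd <- c(0, 0, 1)
      ang <- canonical_angles(acos(pmin(pmax(pdd[3], -1), 1)),
                              atan2(pdd[2], pdd[1]))
      v_iso0 <- min(max((md_v[v] - 0.7e-3) / (d_iso - 0.7e-3), 0.02), 0.95)
      v_in0 <- min(max(fa_v[v], 0.05), 0.9) * (1 - v_iso0)
      s0_0 <- if (any(b == 0)) mean(y[b == 0]) else max(y)
      b0 <- c(v_in0, v_iso0, 0.4, s0_0, ang[1], ang[2])
    }
    model <- function(p) noddi_signal(ctx, p[1], p[2], p[3], p[4], p[5], p[6])
    pr <- nonlinear_problem(model, b0, lower = lower, upper = upper,
                            project = noddi_project)
    res <- fit_nonlinear(pr, y, config)
    ang <- canonical_angles(res$params[5], res$params[6])
    res$params[5:6] <- ang
    res$syn <- model(res$params)
    res
  }
  out <- fit_voxelwise(voxels, mask, 6L, fit_one)
  out$dti_init <- dti
  out
}
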