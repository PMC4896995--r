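#' Mono-exponential T2 decay
#' @param te_ms echo times (ms).
#' @param s0 signal at TE = 0.
#' @param t2_ms transverse relaxation time (ms).
#' @return predicted signal vector S = S0 exp(-TE/T2).
#' @export
t2_forward <- function(te_ms, s0, t2_ms) s0 * exp(-te_ms / t2_ms)

#' Voxelwise single-component T2 fit
#'
#' Fits [S0, T2] in S = S0 exp(-TE/T2) by nonlinear least squares, started
#' from the log-linear solution over the positive samples. All-zero voxels
#' are flagged (output 0).
#'
#' @param voxels 4D series [X,Y,Z,T].
#' @param schedule \code{\link{acquisition_schedule}} with te_ms.
#' @param mask 3D logical array.
#' @param init optional 4D init map with volumes [S0, T2].
#' @param config \code{\link{solver_config}}.
#' @return voxelwise outputs; mcmap volumes [S0, T2].
#' @export
fit_t2_single <- function(voxels, schedule, mask = NULL, init = NULL,
                          config = solver_config()) {
  te <- schedule$te_ms
  if (is.null(te)) stop("schedule has no TE list")
  if (length(unique(te)) < 2) stop("at least 2 distinct TEs are required")
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  init_mat <- if (!is.null(init)) matrix(init, prod(dm[1:3]), 2) else NULL

  model_for <- function(b) t2_forward(te, b[1], b[2])
  fit_one <- function(y, v) {
    if (all(y == 0)) return(NULL)
    b0 <- loglin_exp_start(te, y)
    if (!is.null(init_mat)) {
      cand <- init_mat[v, ]
      if (all(is.finite(cand)) && cand[2] > 0) b0 <- cand
    }
    pr <- nonlinear_problem(model_for, b0, lower = c(0, 0.1), upper = c(Inf, 2e4))
    res <- fit_nonlinear(pr, y, config)
    res$syn <- model_for(res$params)
    res
  }
  fit_voxelwise(voxels, mask, 2L, fit_one)
}

# Log-linear start for S0 exp(-x/T): LS on ln(y) over positive samples.
loglin_exp_start <- function(x, y) {
  use <- y > 0
  if (sum(use) >= 2) {
    b <- solve_ls(cbind(1, -x[use]), log(y[use]))
    t_est <- if (b[2] > 1e-6) 1 / b[2] else max(x)
    c(exp(b[1]), min(max(t_est, 1), 1e4))
  } else {
    c(max(y, 1e-6), stats::median(x))
  }
}

#' Voxelwise multi-component T2 spectrum fit
#'
#' Non-negative least squares of the component amplitudes S0 v_i over the
#' exponential basis exp(-TE/T2_i) for a fixed grid of T2s, normalised so
#' the fractions sum to 1. Optional per-component voxelwise priors add a
#' Tikhonov pull of the fractions toward the prior (rows
#' sqrt(strength) I appended to the design). With \code{init}, the NNLS
#' solution seeds a nonlinear refinement of the amplitudes.
#'
#' @inheritParams fit_t2_single
#' @param t2_grid_ms strictly increasing component T2s (ms).
#' @param priors optional 4D array [X,Y,Z,n_components] of prior fractions.
#' @param prior_strength Tikhonov weight (0 disables the pull).
#' @param init optional 4D map of component amplitudes seeding a nonlinear
#'   refinement.
#' @return voxelwise outputs; mcmap volumes [v_1..v_n, S0].
#' @export
fit_t2_multicomponent <- function(voxels, schedule, t2_grid_ms, mask = NULL,
                                  priors = NULL, prior_strength = 0,
                                  init = NULL, config = solver_config()) {
  te <- schedule$te_ms
  if (is.null(te)) stop("schedule has no TE list")
  if (is.unsorted(t2_grid_ms, strictly = TRUE)) {
    stop("t2_grid_ms must be strictly increasing")
  }
  n_c <- length(t2_grid_ms)
  basis <- vapply(t2_grid_ms, function(t2) exp(-te / t2), numeric(length(te)))
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  prior_mat <- if (!is.null(priors)) matrix(priors, prod(dm[1:3]), n_c) else NULL
  init_mat <- if (!is.null(init)) matrix(init, prod(dm[1:3]), n_c) else NULL

  fit_one <- function(y, v) {
    if (all(y == 0)) return(NULL)
    a <- basis
    obs <- y
    if (!is.null(prior_mat) && prior_strength > 0) {
      s0_rough <- sum(solve_nnls(basis, y))
      a <- rbind(basis, sqrt(prior_strength) * diag(n_c))
      obs <- c(y, sqrt(prior_strength) * s0_rough * prior_mat[v, ])
    }
    coef <- solve_nnls(a, obs)
    if (!is.null(init_mat)) {
      b0 <- init_mat[v, ]
      if (all(is.finite(b0)) && any(b0 > 0)) {
        pr <- nonlinear_problem(function(b) as.numeric(basis %*% b), b0,
                                lower = rep(0, n_c))
        coef <- fit_nonlinear(pr, y, config)$params
      }
    }
    s0 <- sum(coef)
    frac <- if (s0 > 0) coef / s0 else rep(0, n_c)
    syn <- as.numeric(basis %*% coef)
    list(params = c(frac, s0), residual = sum((y - syn)^2),
         param_errors = NULL, syn = syn, converged = TRUE)
  }
  fit_voxelwise(voxels, mask, n_c + 1L, fit_one)
}

#' Myelin water fraction from a T2 spectrum
#'
#' MWF = sum of the volume fractions of components with T2 below the
#' threshold (default 50 ms).
#'
#' @param fractions matrix/array of fractions whose last dimension matches
#'   the T2 grid, or an mcmap from \code{\link{fit_t2_multicomponent}}
#'   (trailing S0 volume tolerated via \code{has_s0}).
#' @param t2_grid_ms the component T2s.
#' @param threshold_ms MWF threshold (default 50 ms).
#' @param has_s0 set TRUE when \code{fractions} carries a final S0 volume.
#' @return array of MWF values (one dimension fewer than the input).
#' @export
compute_mwf <- function(fractions, t2_grid_ms, threshold_ms = 50,
                        has_s0 = FALSE) {
  x <- as.array(fractions)
  nd <- length(dim(x))
  if (nd == 0) x <- array(x, c(1, length(x)))
  n_last <- dim(x)[length(dim(x))]
  n_c <- length(t2_grid_ms)
  if (has_s0) {
    if (n_last != n_c + 1) stop("fraction map has wrong component count")
  } else if (n_last != n_c) {
    stop("fraction map has wrong component count")
  }
  sel <- which(t2_grid_ms < threshold_ms)
  m <- matrix(x, ncol = n_last)
  mwf <- if (length(sel)) rowSums(m[, sel, drop = FALSE]) else
    rep(0, nrow(m))
  out_dim <- dim(x)[-length(dim(x))]
  if (length(out_dim) <= 1) as.numeric(mwf) else array(mwf, out_dim)
}

#' CPMG echo amplitudes by the extended phase graph recursion
#'
#' Simulates the echo train of a multi-spin-echo (CPMG) acquisition with
#' refocusing angle \code{alpha} (radians, pi = ideal refocusing), including
#' stimulated-echo pathways and T1 relaxation of stored longitudinal states.
#' Each half echo-spacing applies relaxation and a unit gradient shift of
#' the transverse configuration states; each pulse mixes (F+, F-, Z) per
#' dephasing order. Because the excitation is 90 degrees out of phase with
#' the refocusing pulses, the state space splits into two closed real
#' subspaces (the in-phase transverse pathway and the quadrature pathway fed
#' by regrown longitudinal magnetisation), so the recursion runs entirely in
#' real arithmetic; the echo amplitude combines both in quadrature.
#'
#' @param n_echoes number of echoes.
#' @param echo_spacing_ms echo spacing (ms).
#' @param alpha refocusing flip angle in radians, 0 <= alpha <= pi.
#' @param t2_ms transverse relaxation time (ms).
#' @param t1_ms longitudinal relaxation time used for stored states
#'   (default 1000 ms).
#' @return vector of n_echoes echo amplitudes for unit S0.
#' @export
epg_forward <- function(n_echoes, echo_spacing_ms, alpha, t2_ms,
                        t1_ms = 1000) {
  stopifnot(n_echoes >= 1, echo_spacing_ms > 0, t2_ms > 0, t1_ms > 0)
  if (alpha < 0 || alpha > pi) {
    stop("refocusing angle must lie in [0, pi] radians")
  }
  e2h <- exp(-echo_spacing_ms / 2 / t2_ms)
  e1h <- exp(-echo_spacing_ms / 2 / t1_ms)
  n_s <- n_echoes + 1L     # dephasing orders 0..n_echoes

  c2 <- cos(alpha / 2)^2
  s2 <- sin(alpha / 2)^2
  sa <- sin(alpha)
  ca <- cos(alpha)

  # in-phase subspace: (Re F+, Re F-, Im Z); quadrature: (Im F+, Im F-, Re Z)
  fpA <- fmA <- zA <- numeric(n_s)
  fpB <- fmB <- zB <- numeric(n_s)
  fpA[1] <- 1
  fmA[1] <- 1    # F-(0) stores conj(F+(0)); both carry Re F(0)

  half_period <- function() {
    fpA <<- fpA * e2h; fmA <<- fmA * e2h; zA <<- zA * e1h
    fpB <<- fpB * e2h; fmB <<- fmB * e2h; zB <<- zB * e1h
    zB[1] <<- zB[1] + (1 - e1h)          # regrowth feeds real Z0
    # gradient shift: F(k) -> F(k+1)
    fpA <<- c(fmA[2], fpA[-n_s]); fmA <<- c(fmA[-1], 0)
    fpB <<- c(-fmB[2], fpB[-n_s]); fmB <<- c(fmB[-1], 0)
  }
  rf_pulse <- function() {
    fpA_n <- c2 * fpA + s2 * fmA + sa * zA
    fmA_n <- s2 * fpA + c2 * fmA - sa * zA
    zA_n <- -sa / 2 * fpA + sa / 2 * fmA + ca * zA
    fpB_n <- c2 * fpB + s2 * fmB - sa * zB
    fmB_n <- s2 * fpB + c2 * fmB + sa * zB
    zB_n <- sa / 2 * fpB - sa / 2 * fmB + ca * zB
    fpA <<- fpA_n; fmA <<- fmA_n; zA <<- zA_n
    fpB <<- fpB_n; fmB <<- fmB_n; zB <<- zB_n
  }

  echoes <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    half_period()
    rf_pulse()
    half_period()
    echoes[e] <- sqrt(fpA[1]^2 + fpB[1]^2)
  }
  echoes
}

# EPG decay basis: n_echoes x length(t2_grid) matrix at a given alpha.
epg_basis <- function(n_echoes, echo_spacing_ms, alpha, t2_grid_ms,
                      t1_ms = 1000) {
  vapply(t2_grid_ms,
         function(t2) epg_forward(n_echoes, echo_spacing_ms, alpha, t2, t1_ms),
         numeric(n_echoes))
}

#' Voxelwise EPG multi-component T2 fit with refocusing-angle estimation
#'
#' For each voxel, performs a 1D search for the refocusing angle alpha over
#' [0, pi] (coarse grid, then golden-section refinement to 1e-3 rad), with a
#' non-negative least-squares fit of the T2 spectrum over EPG basis curves
#' at each candidate alpha. Returns the minimising alpha per voxel (the B1
#' map, radians) alongside the spectrum. Requires an equally spaced echo
#' train.
#'
#' @inheritParams fit_t2_multicomponent
#' @param t1_ms fixed longitudinal relaxation used in the state evolution.
#' @param n_alpha_grid coarse grid size over [0, pi].
#' @return voxelwise outputs; mcmap volumes [v_1..v_n, S0, alpha]; the alpha
#'   map is also returned as \code{b1map}.
#' @export
fit_t2_epg <- function(voxels, schedule, t2_grid_ms, mask = NULL,
                       t1_ms = 1000, n_alpha_grid = 64) {
  te <- schedule$te_ms
  if (is.null(te)) stop("schedule has no TE list")
  dte <- diff(te)
  if (any(abs(dte - dte[1]) > 1e-6 * dte[1])) {
    stop("EPG fitting requires an equally spaced echo train")
  }
  esp <- dte[1]
  n_e <- length(te)
  n_c <- length(t2_grid_ms)
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])

  alphas <- seq(0.05, pi, length.out = n_alpha_grid)
  bases <- lapply(alphas, function(a) epg_basis(n_e, esp, a, t2_grid_ms, t1_ms))

  nnls_res <- function(a_mat, y) {
    coef <- solve_nnls(a_mat, y)
    list(coef = coef, res = sum((y - a_mat %*% coef)^2))
  }

  fit_one <- function(y, v) {
    if (max(y) - min(y) <= 0) return(NULL)   # flat signal: alpha undefined
    res_grid <- vapply(bases, function(b) nnls_res(b, y)$res, 1.0)
    i_best <- which.min(res_grid)
    lo <- alphas[max(1, i_best - 1)]
    hi <- alphas[min(n_alpha_grid, i_best + 1)]
    # golden-section refinement of alpha to 1e-3 rad
    gr <- (sqrt(5) - 1) / 2
    f_cache <- function(a) nnls_res(epg_basis(n_e, esp, a, t2_grid_ms, t1_ms), y)$res
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- f_cache(x1); f2 <- f_cache(x2)
    while (hi - lo > 1e-3) {
      if (f1 <= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- f_cache(x1)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- f_cache(x2)
      }
    }
    a_hat <- (lo + hi) / 2
    bb <- epg_basis(n_e, esp, a_hat, t2_grid_ms, t1_ms)
    fin <- nnls_res(bb, y)
    s0 <- sum(fin$coef)
    frac <- if (s0 > 0) fin$coef / s0 else rep(0, n_c)
    list(params = c(frac, s0, a_hat), residual = fin$res,
         param_errors = NULL, syn = as.numeric(bb %*% fin$coef),
         converged = TRUE)
  }
  out <- fit_voxelwise(voxels, mask, n_c + 2L, fit_one)
  out$b1map <- array(out$mcmap[, , , n_c + 2L], dm[1:3])
  out
}
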