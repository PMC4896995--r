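#' Saturation/inversion recovery signal models
#'
#' Saturation recovery: S = S0 (1 - exp(-TI/T1)).
#' Inversion recovery:  S = S0 (1 - 2 exp(-TI/T1) + exp(-TR/T1)).
#'
#' @param ti_ms inversion/saturation times (ms).
#' @param s0 equilibrium signal.
#' @param t1_ms longitudinal relaxation time (ms).
#' @param tr_ms repetition time (ms, inversion mode only).
#' @param mode "saturation" or "inversion".
#' @return predicted signal vector.
#' @export
t1_forward <- function(ti_ms, s0, t1_ms, tr_ms = NULL,
                       mode = c("saturation", "inversion")) {
  mode <- match.arg(mode)
  if (mode == "saturation") {
    s0 * (1 - exp(-ti_ms / t1_ms))
  } else {
    if (is.null(tr_ms)) stop("inversion recovery requires TR")
    s0 * (1 - 2 * exp(-ti_ms / t1_ms) + exp(-tr_ms / t1_ms))
  }
}

#' Voxelwise single-component T1 fit
#'
#' Nonlinear least-squares fit of [S0, T1] to a saturation- or
#' inversion-recovery series. The default initialisation is S0 = max signal
#' and T1 = median TI; a 4D init map (volumes [S0, T1]) overrides it.
#'
#' @param voxels 4D series [X,Y,Z,T].
#' @param schedule \code{\link{acquisition_schedule}} with ti_ms (and tr_ms
#'   for inversion mode).
#' @param mode "saturation" or "inversion".
#' @param mask 3D logical array.
#' @param init optional 4D initialisation map with 2 volumes [S0, T1].
#' @param config \code{\link{solver_config}}.
#' @return voxelwise outputs: mcmap [S0, T1], resmap, error, syn.
#' @export
fit_t1_single <- function(voxels, schedule, mode = c("saturation", "inversion"),
                          mask = NULL, init = NULL, config = solver_config()) {
  mode <- match.arg(mode)
  ti <- schedule$ti_ms
  if (is.null(ti)) stop("schedule has no TI list")
  if (length(unique(ti)) < 2) stop("at least 2 distinct TIs are required")
  tr <- schedule$tr_ms
  if (mode == "inversion" && is.null(tr)) stop("inversion mode requires TR")
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])

  init_mat <- if (!is.null(init)) matrix(init, prod(dm[1:3]), 2) else NULL

  model_for <- function(b) t1_forward(ti, b[1], b[2], tr, mode)
  fit_one <- function(y, v) {
    b0 <- c(max(y), stats::median(ti))
    if (!is.null(init_mat)) {
      cand <- init_mat[v, ]
      if (all(is.finite(cand)) && cand[2] > 0) b0 <- cand
    }
    pr <- nonlinear_problem(model_for, b0, lower = c(-Inf, 1), upper = c(Inf, 2e4))
    res <- fit_nonlinear(pr, y, config)
    res$syn <- model_for(res$params)
    res
  }
  fit_voxelwise(voxels, mask, 2L, fit_one)
}

#' Voxelwise multi-component T1 spectrum fit
#'
#' Linear non-negative least squares for the component amplitudes
#' S0 v_i over a fixed grid of T1s, then normalisation so the volume
#' fractions sum to 1. mcmap layout: the v_i followed by S0.
#'
#' @inheritParams fit_t1_single
#' @param t1_grid_ms fixed component T1s (ms).
#' @return voxelwise outputs; mcmap volumes [v_1..v_n, S0].
#' @export
fit_t1_multicomponent <- function(voxels, schedule, t1_grid_ms,
                                  mode = c("saturation", "inversion"),
                                  mask = NULL) {
  mode <- match.arg(mode)
  ti <- schedule$ti_ms
  if (is.null(ti)) stop("schedule has no TI list")
  n_c <- length(t1_grid_ms)
  if (n_c > length(ti)) {
    warning("more T1 components than TIs: the NNLS solution is under-determined")
  }
  basis <- vapply(t1_grid_ms,
                  function(t1) t1_forward(ti, 1, t1, schedule$tr_ms, mode),
                  numeric(length(ti)))
  dm <- dim(voxels)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  fit_one <- function(y, v) {
    coef <- solve_nnls(basis, y)
    s0 <- sum(coef)
    v <- if (s0 > 0) coef / s0 else rep(0, n_c)
    syn <- as.numeric(basis %*% coef)
    list(params = c(v, s0), residual = sum((y - syn)^2),
         param_errors = NULL, syn = syn, converged = TRUE)
  }
  fit_voxelwise(voxels, mask, n_c + 1L, fit_one)
}
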