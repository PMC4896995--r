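#' Quantification constants for ASL cerebral blood flow
#'
#' Defaults follow the ASL consensus recommendations: partition coefficient
#' lambda = 0.9 ml/g, blood T1 = 1650 ms at 3T, labelling efficiency 0.85
#' (PCASL) or 0.98 (PASL).
#'
#' @param partition_lambda blood/tissue partition coefficient (ml/g).
#' @param label_efficiency_alpha labelling efficiency in (0, 1].
#' @param t1_blood_ms longitudinal relaxation time of arterial blood (ms).
#' @param pld_ms post-labelling delay (PCASL, ms).
#' @param dpld_ms per-slice PLD increment for 2D read-outs (ms).
#' @param tau_ms label duration (PCASL, ms).
#' @param ti1_ms,ti2_ms QUIPSS-II bolus clipping time and imaging inversion
#'   time (PASL, ms).
#' @return an \code{qmr_asl_params} list.
#' @export
asl_params <- function(partition_lambda = 0.9, label_efficiency_alpha = 0.85,
                       t1_blood_ms = 1650, pld_ms = NULL, dpld_ms = 0,
                       tau_ms = NULL, ti1_ms = NULL, ti2_ms = NULL) {
  stopifnot(label_efficiency_alpha > 0, label_efficiency_alpha <= 1,
            t1_blood_ms > 0)
  structure(list(partition_lambda = partition_lambda,
                 label_efficiency_alpha = label_efficiency_alpha,
                 t1_blood_ms = t1_blood_ms, pld_ms = pld_ms,
                 dpld_ms = dpld_ms, tau_ms = tau_ms,
                 ti1_ms = ti1_ms, ti2_ms = ti2_ms),
            class = "qmr_asl_params")
}

#' Split an interleaved control/label series into a pair structure
#' @param voxels 4D array with 2R volumes.
#' @param order "cl" when control volumes come first in each pair, "lc"
#'   otherwise.
#' @return list(controls, labels, kept) with R repeats each.
#' @export
split_pairs <- function(voxels, order = c("cl", "lc")) {
  order <- match.arg(order)
  dm <- dim(voxels)
  if (dm[4] %% 2 != 0) stop("control/label series must have an even number of volumes")
  r <- dm[4] / 2
  ctrl_idx <- seq(if (order == "cl") 1 else 2, dm[4], by = 2)
  lab_idx <- setdiff(seq_len(dm[4]), ctrl_idx)
  list(controls = voxels[, , , ctrl_idx, drop = FALSE],
       labels = voxels[, , , lab_idx, drop = FALSE],
       kept = rep(TRUE, r))
}

mean_kept <- function(arr4d, kept) {
  dm <- dim(arr4d)
  m <- matrix(arr4d, prod(dm[1:3]), dm[4])[, kept, drop = FALSE]
  array(rowMeans(m), dm[1:3])
}

#' Reject outlier control/label repeats by z-score
#'
#' Each repeat is summarised by its mean within-mask intensity, either of
#' the raw control and label volumes ("raw" mode, a repeat is rejected if
#' either volume is an outlier) or of the pairwise control-label difference
#' ("difference" mode). Repeats whose summary z-score exceeds the threshold
#' in magnitude are dropped. A zero-variance summary set rejects nothing.
#'
#' @param pairs as returned by \code{\link{split_pairs}}.
#' @param mask 3D logical array.
#' @param mode "raw" or "difference".
#' @param z_threshold rejection threshold on |z| (default 2.5).
#' @return the pair structure with its \code{kept} vector updated.
#' @export
reject_outlier_pairs <- function(pairs, mask, mode = c("difference", "raw"),
                                 z_threshold = 2.5) {
  mode <- match.arg(mode)
  r <- length(pairs$kept)
  if (r < 3) stop("outlier rejection needs at least 3 repeats")
  cm <- masked_matrix(pairs$controls, mask)
  lm_ <- masked_matrix(pairs$labels, mask)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  if (mode == "difference") {
    summ <- colMeans(cm - lm_)
    bad <- abs(zscore(summ)) > z_threshold
  } else {
    zc <- abs(zscore(colMeans(cm))) > z_threshold
    zl <- abs(zscore(colMeans(lm_))) > z_threshold
    bad <- zc | zl
  }
  kept <- pairs$kept & !bad
  if (!any(kept)) {
    stop("all repeats rejected as outliers; increase the z threshold")
  }
  pairs$kept <- kept
  pairs
}

asl_scaling_pcasl <- function(params, slice_k = 0) {
  t1b <- params$t1_blood_ms
  pld <- params$pld_ms + slice_k * params$dpld_ms
  6000 * params$partition_lambda / (2 * params$label_efficiency_alpha) *
    exp(pld / t1b) / ((t1b / 1000) * (1 - exp(-params$tau_ms / t1b)))
}

asl_scaling_pasl <- function(params) {
  t1b <- params$t1_blood_ms
  6000 * params$partition_lambda / (2 * params$label_efficiency_alpha) *
    exp(params$ti2_ms / t1b) / (params$ti1_ms / 1000)
}

cbf_from_pairs <- function(pairs, m0, mask, per_slice_scale) {
  dm <- dim(pairs$controls)[1:3]
  dsig <- mean_kept(pairs$controls, pairs$kept) -
    mean_kept(pairs$labels, pairs$kept)
  cbf <- array(0, dm)
  invalid <- 0L
  for (k in seq_len(dm[3])) {
    sl_mask <- mask[, , k]
    m0_sl <- m0[, , k]
    ok <- sl_mask & m0_sl > 0
    invalid <- invalid + sum(sl_mask & m0_sl <= 0)
    sl <- array(0, dm[1:2])
    sl[ok] <- per_slice_scale[k] * dsig[, , k][ok] / m0_sl[ok]
    cbf[, , k] <- sl
  }
  attr(cbf, "invalid_m0_voxels") <- invalid
  cbf
}

#' PCASL cerebral blood flow quantification
#'
#' CBF = 6000 lambda / (2 alpha) * exp(PLD_k/T1b) /
#' (T1b_s (1 - exp(-tau/T1b))) * (mean S_C - mean S_L) / S_PD, in
#' ml/100g/min, where for 2D read-outs slice k uses PLD_k = PLD + k dPLD.
#' Voxels with non-positive M0 inside the mask are flagged invalid (output
#' 0; count in attribute \code{invalid_m0_voxels}).
#'
#' @param pairs control/label pair structure (\code{\link{split_pairs}}).
#' @param m0 3D proton-density normalisation volume S_PD (may come from a
#'   T1-fit S0 map).
#' @param params \code{\link{asl_params}} with pld_ms, tau_ms set.
#' @param mask 3D logical array (default all voxels).
#' @return 3D CBF map (ml/100g/min).
#' @export
cbf_pcasl <- function(pairs, m0, params, mask = NULL) {
  stopifnot(!is.null(params$pld_ms), !is.null(params$tau_ms))
  dm <- dim(pairs$controls)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  scale_k <- vapply(seq_len(dm[3]) - 1L,
                    function(k) asl_scaling_pcasl(params, k), 1.0)
  cbf_from_pairs(pairs, m0, mask, scale_k)
}

#' PASL (QUIPSS-II) cerebral blood flow quantification
#'
#' CBF = 6000 lambda / (2 alpha) * exp(TI2/T1b) / TI1_s *
#' (mean S_C - mean S_L) / S_PD, in ml/100g/min.
#'
#' @inheritParams cbf_pcasl
#' @param params \code{\link{asl_params}} with ti1_ms, ti2_ms set.
#' @return 3D CBF map (ml/100g/min).
#' @export
cbf_pasl <- function(pairs, m0, params, mask = NULL) {
  stopifnot(!is.null(params$ti1_ms), !is.null(params$ti2_ms))
  dm <- dim(pairs$controls)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dm)
  scale_k <- rep(asl_scaling_pasl(params), dm[3])
  cbf_from_pairs(pairs, m0, mask, scale_k)
}

#' Partial-volume correction of a CBF map (local linear regression)
#'
#' For each voxel, the CBF values in a local 2D (n x n in-plane) or 3D
#' (n x n x n) kernel are regressed on the grey- and white-matter partial
#' volume fractions under the assumption that local GM and WM CBF are
#' constant, yielding separate GM and WM CBF estimates. Voxels whose kernel
#' design is rank-deficient or has fewer than 2 usable voxels are flagged
#' (NA in the output), not fatal.
#'
#' @param cbf 3D CBF map.
#' @param gm_fraction,wm_fraction 3D partial volume maps in [0, 1].
#' @param kernel_size odd kernel width >= 3.
#' @param dims 2 for an in-plane kernel, 3 for a cubic kernel.
#' @param mask 3D logical array restricting solved voxels.
#' @return list(cbf_gm, cbf_wm, flagged) of 3D maps.
#' @export
pv_correct_cbf <- function(cbf, gm_fraction, wm_fraction, kernel_size = 3,
                           dims = 2, mask = NULL) {
  stopifnot(kernel_size >= 3, kernel_size %% 2 == 1, dims %in% c(2, 3))
  dm <- dim(cbf)
  if (!all(dim(gm_fraction) == dm) || !all(dim(wm_fraction) == dm)) {
    stop("partial volume maps must be congruent with the CBF map")
  }
  if (is.null(mask)) mask <- array(TRUE, dm)
  h <- (kernel_size - 1) / 2
  cbf_gm <- array(NA_real_, dm)
  cbf_wm <- array(NA_real_, dm)
  flagged <- array(FALSE, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!mask[i, j, k]) next
    ii <- max(1, i - h):min(dm[1], i + h)
    jj <- max(1, j - h):min(dm[2], j + h)
    kk <- if (dims == 3) max(1, k - h):min(dm[3], k + h) else k
    g <- as.numeric(gm_fraction[ii, jj, kk])
    w <- as.numeric(wm_fraction[ii, jj, kk])
    y <- as.numeric(cbf[ii, jj, kk])
    use <- is.finite(y)
    g <- g[use]; w <- w[use]; y <- y[use]
    a <- cbind(gm = g, wm = w)
    if (length(y) < 2 || qr(a)$rank < 2) {
      flagged[i, j, k] <- TRUE
      # degenerate designs: single-tissue kernels still yield that tissue's CBF
      if (length(y) >= 1 && sum(g) > 0 && sum(w) == 0) {
        cbf_gm[i, j, k] <- sum(g * y) / sum(g^2)
      } else if (length(y) >= 1 && sum(w) > 0 && sum(g) == 0) {
        cbf_wm[i, j, k] <- sum(w * y) / sum(w^2)
      }
      next
    }
    b <- solve_ls(a, y)
    cbf_gm[i, j, k] <- b[1]
    cbf_wm[i, j, k] <- b[2]
  }
  list(cbf_gm = cbf_gm, cbf_wm = cbf_wm, flagged = flagged)
}
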