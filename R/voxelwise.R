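# Generic voxelwise fitting loop shared by every modality driver.
# fit_fun(y, v) gets the voxel time-course and its flat spatial index and
# must return list(params, residual, param_errors, syn, converged).
# Voxels outside the mask are exactly 0 in all outputs.
fit_voxelwise <- function(voxels, mask, n_params, fit_fun) {
  dm <- dim(voxels)
  t_len <- dm[4]
  n_vox <- prod(dm[1:3])
  n_err <- n_params * (n_params + 1) / 2

  ymat <- matrix(voxels, nrow = n_vox, ncol = t_len)
  idx <- which(as.logical(mask))

  mc <- matrix(0, n_vox, n_params)
  res <- numeric(n_vox)
  err <- matrix(0, n_vox, n_err)
  syn <- matrix(0, n_vox, t_len)
  conv <- logical(n_vox)

  for (v in idx) {
    out <- fit_fun(ymat[v, ], v)
    if (is.null(out)) next
    mc[v, ] <- out$params
    res[v] <- out$residual
    if (!is.null(out$param_errors) && all(is.finite(out$param_errors))) {
      err[v, ] <- out$param_errors
    }
    if (!is.null(out$syn)) syn[v, ] <- out$syn
    conv[v] <- isTRUE(out$converged) || is.null(out$converged)
  }

  list(mcmap = array(mc, c(dm[1:3], n_params)),
       resmap = array(res, dm[1:3]),
       error = array(err, c(dm[1:3], n_err)),
       syn = array(syn, dm),
       converged = array(conv, dm[1:3]),
       n_fitted = length(idx))
}

# Extract the masked voxel-by-volume matrix of a 4D array.
masked_matrix <- function(voxels, mask) {
  dm <- dim(voxels)
  matrix(voxels, prod(dm[1:3]), dm[4])[which(as.logical(mask)), , drop = FALSE]
}
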