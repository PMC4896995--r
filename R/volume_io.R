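#' Read a 4D source series, with optional mask and voxel/slice selection
#'
#' The source must be a 3D or 4D NIfTI file with the dependent variable
#' (echo time, inversion time, diffusion volume, control/label repeat, ...)
#' along the fourth dimension. A 3D input is promoted to T = 1.
#'
#' @param source path to the NIfTI series, or an array.
#' @param mask optional path/array: 3D mask congruent with the source's
#'   spatial grid (default: all voxels).
#' @param slice_index optional single slice (0-based k) to restrict fitting.
#' @param voxel_index optional 0-based (i, j, k) triplet selecting a single
#'   voxel.
#' @return list with \code{voxels} (4D array), \code{reference} (RNifti image
#'   or NULL, carrying the affine/header), \code{mask} (3D logical) and
#'   \code{dim}.
#' @export
read_series <- function(source, mask = NULL, slice_index = NULL,
                        voxel_index = NULL) {
  ref <- NULL
  if (is.character(source)) {
    ref <- RNifti::readNifti(source)
    voxels <- as.array(ref)
  } else {
    voxels <- as.array(source)
  }
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4) stop("source must be a 3D or 4D image")
  dm <- dim(voxels)
  if (dm[4] < 1) stop("source has no volumes along the 4th dimension")

  if (is.null(mask)) {
    m <- array(TRUE, dm[1:3])
  } else {
    m_arr <- if (is.character(mask)) as.array(RNifti::readNifti(mask)) else as.array(mask)
    if (length(dim(m_arr)) != 3 || !all(dim(m_arr) == dm[1:3])) {
      stop(sprintf("mask shape (%s) does not match source spatial shape (%s)",
                   paste(dim(m_arr), collapse = "x"),
                   paste(dm[1:3], collapse = "x")))
    }
    m <- m_arr != 0
  }
  if (!is.null(slice_index)) {
    if (slice_index < 0 || slice_index >= dm[3]) stop("slice_index out of bounds")
    keep <- array(FALSE, dm[1:3])
    keep[, , slice_index + 1L] <- TRUE
    m <- m & keep
  }
  if (!is.null(voxel_index)) {
    v <- as.integer(voxel_index)
    if (length(v) != 3 || any(v < 0) || any(v >= dm[1:3])) {
      stop("voxel_index out of bounds")
    }
    keep <- array(FALSE, dm[1:3])
    keep[v[1] + 1L, v[2] + 1L, v[3] + 1L] <- TRUE
    m <- m & keep
  }
  list(voxels = voxels, reference = ref, mask = m, dim = dm)
}

read_row_vector <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_line <- function(ln, row) {
    toks <- strsplit(trimws(ln), "[ \t,]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) {
      col <- which(is.na(vals))[1]
      stop(sprintf("non-numeric token '%s' at line %d, field %d of %s",
                   toks[col], row, col, path))
    }
    vals
  }
  lapply(seq_along(lines), function(i) parse_line(lines[i], i))
}

#' Read a TE/TI/b-value list file (single whitespace-delimited row)
#' @param path text file containing one row of numbers.
#' @return numeric vector.
#' @export
read_list_file <- function(path) {
  rows <- read_row_vector(path)
  if (length(rows) != 1) stop(sprintf("%s must contain a single row", path))
  rows[[1]]
}

#' Read an FSL-style b-vector file (3 rows of T entries)
#' @param path text file with the x, y, z gradient components as 3 rows.
#' @return T x 3 matrix of gradient directions.
#' @export
read_bvec_file <- function(path) {
  rows <- read_row_vector(path)
  if (length(rows) != 3) stop(sprintf("%s must contain exactly 3 rows", path))
  len <- unique(vapply(rows, length, 1L))
  if (length(len) != 1) stop(sprintf("rows of %s have unequal lengths", path))
  t(do.call(rbind, rows))
}

#' Assemble and validate an acquisition schedule
#'
#' Times are stored in milliseconds, b-values in s/mm^2. Echo times may be
#' given as an explicit vector (\code{te_ms}), or as an even spacing
#' (\code{te_spacing_ms}) expanded to (s, 2s, ..., Ts) over \code{n_volumes}
#' echoes. b-vectors are interpreted in the image voxel frame (FSL dialect);
#' each b > 0 direction must have unit norm within 1e-3.
#'
#' @param n_volumes number of volumes T along the 4th dimension.
#' @param te_ms,ti_ms optional per-volume echo/inversion times (ms).
#' @param te_spacing_ms optional scalar echo spacing, exclusive with te_ms.
#' @param tr_ms optional repetition time (ms).
#' @param bvals_s_per_mm2 optional per-volume b-values.
#' @param bvecs optional T x 3 matrix of unit gradient directions.
#' @param pair_labels optional per-volume "control"/"label" tags.
#' @return an \code{qmr_schedule} list.
#' @export
acquisition_schedule <- function(n_volumes, te_ms = NULL, te_spacing_ms = NULL,
                                 ti_ms = NULL, tr_ms = NULL,
                                 bvals_s_per_mm2 = NULL, bvecs = NULL,
                                 pair_labels = NULL) {
  t_len <- as.integer(n_volumes)
  if (!is.null(te_ms) && !is.null(te_spacing_ms)) {
    stop("give echo times either as a list or as a spacing, not both")
  }
  if (!is.null(te_spacing_ms)) te_ms <- te_spacing_ms * seq_len(t_len)
  check_len <- function(x, what) {
    if (!is.null(x) && length(x) != t_len) {
      stop(sprintf("%s has length %d but the series has %d volumes",
                   what, length(x), t_len))
    }
  }
  check_len(te_ms, "TE list"); check_len(ti_ms, "TI list")
  check_len(bvals_s_per_mm2, "bval list"); check_len(pair_labels, "pair labels")
  for (v in list(te_ms, ti_ms, tr_ms)) {
    if (!is.null(v) && any(v < 0)) stop("times must be >= 0")
  }
  if (!is.null(bvecs)) {
    bvecs <- as.matrix(bvecs)
    if (nrow(bvecs) != t_len || ncol(bvecs) != 3) {
      stop(sprintf("bvec matrix is %dx%d but must be %dx3",
                   nrow(bvecs), ncol(bvecs), t_len))
    }
    if (!is.null(bvals_s_per_mm2)) {
      nrm <- sqrt(rowSums(bvecs^2))
      bad <- which(bvals_s_per_mm2 > 0 & abs(nrm - 1) > 1e-3)
      if (length(bad)) {
        stop(sprintf("b-vector %d has norm %.4f; b > 0 directions must be unit within 1e-3",
                     bad[1], nrm[bad[1]]))
      }
    }
  }
  structure(list(n_volumes = t_len, te_ms = te_ms, ti_ms = ti_ms,
                 tr_ms = tr_ms, bvals_s_per_mm2 = bvals_s_per_mm2,
                 bvecs = bvecs, pair_labels = pair_labels),
            class = "qmr_schedule")
}

#' Write the text files of a schedule (bval/bvec/TE/TI lists)
#' @param schedule an \code{\link{acquisition_schedule}}.
#' @param dir output directory; files named bvals, bvecs, TEs, TIs.
#' @return invisibly, the paths written.
#' @export
write_schedule <- function(schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put_row <- function(x, name) {
    p <- file.path(dir, name)
    writeLines(paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = "\t"), p)
    p
  }
  if (!is.null(schedule$te_ms)) paths <- c(paths, put_row(schedule$te_ms, "TEs"))
  if (!is.null(schedule$ti_ms)) paths <- c(paths, put_row(schedule$ti_ms, "TIs"))
  if (!is.null(schedule$bvals_s_per_mm2)) {
    paths <- c(paths, put_row(schedule$bvals_s_per_mm2, "bvals"))
  }
  if (!is.null(schedule$bvecs)) {
    p <- file.path(dir, "bvecs")
    writeLines(apply(t(schedule$bvecs), 1, function(r) {
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t")
    }), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write the standard voxelwise fit outputs as NIfTI
#'
#' Writes any of the four standard outputs: the multi-parameter map (mcmap,
#' P along dim 4), the residual map (resmap, 3D), the parameter error map
#' (P(P+3)/2 volumes: variances then covariances) and the synthetic series
#' (syn, T volumes re-simulated from the fitted parameters). Output headers
#' copy the source geometry.
#'
#' @param outputs list with any of \code{mcmap}, \code{resmap}, \code{error},
#'   \code{syn} arrays (as returned by the fitting drivers).
#' @param reference RNifti image (or NULL) whose geometry the outputs take.
#' @param paths named list/character vector mapping output names to file
#'   paths; only named outputs are written.
#' @return invisibly, the paths written.
#' @export
write_fit_outputs <- function(outputs, reference, paths) {
  written <- character(0)
  for (nm in intersect(names(paths), c("mcmap", "resmap", "error", "syn"))) {
    arr <- outputs[[nm]]
    if (is.null(arr)) next
    img <- if (is.null(reference)) RNifti::asNifti(arr) else
      RNifti::asNifti(arr, reference = reference)
    RNifti::writeNifti(img, paths[[nm]])
    written <- c(written, paths[[nm]])
  }
  invisible(written)
}
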