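#' Ordinary least squares via the normal equations
#'
#' Solves \code{A b = y} in the least-squares sense using the pseudo-inverse
#' \code{(A'A)^-1 A'y}. This is the linear solver every modality-specific fit
#' in the package is built on.
#'
#' @param design numeric matrix, m observations x n parameters.
#' @param observations numeric vector of length m.
#' @return numeric parameter vector of length n.
#' @export
solve_ls <- function(design, observations) {
  design <- as.matrix(design)
  y <- as.numeric(observations)
  check_linear_system(design, y)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop(sprintf(
      "singular system: design has %d columns but rank %d",
      ncol(design), qrd$rank
    ))
  }
  ata <- crossprod(design)
  as.numeric(solve(ata, crossprod(design, y)))
}

#' Weighted least squares
#'
#' Solves \code{b = (A'WA)^-1 A'Wy} with \code{W = diag(weights)}, the
#' per-observation precisions.
#'
#' @inheritParams solve_ls
#' @param weights non-negative precision vector of length m (diagonal of W).
#' @return numeric parameter vector of length n.
#' @export
solve_wls <- function(design, observations, weights) {
  design <- as.matrix(design)
  y <- as.numeric(observations)
  check_linear_system(design, y)
  w <- as.numeric(weights)
  if (length(w) != length(y)) stop("weights must have one entry per observation")
  if (any(!is.finite(w))) stop("weights must be finite")
  if (any(w < 0)) stop("negative weight supplied")
  if (all(w == 0)) stop("all weights are zero")
  aw <- design * w      # row-scale: W A
  atwa <- crossprod(design, aw)
  as.numeric(solve(atwa, crossprod(aw, y)))
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimises \code{||A b - y||^2} subject to \code{b >= 0} elementwise.
#' Entering variables are chosen by largest gradient; ties break to the
#' lowest index. Used for multi-exponential T1/T2 spectrum fitting.
#'
#' @inheritParams solve_ls
#' @param tol dual-feasibility tolerance on the gradient A'(y - Ab).
#' @return non-negative parameter vector of length n.
#' @export
solve_nnls <- function(design, observations, tol = NULL) {
  a <- as.matrix(design)
  y <- as.numeric(observations)
  if (nrow(a) != length(y)) stop("design rows must match observation length")
  n <- ncol(a)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(a)) * max(nrow(a), n)

  passive <- rep(FALSE, n)
  b <- rep(0, n)
  w <- as.numeric(crossprod(a, y - a %*% b))
  iter_max <- 3L * n + 30L
  outer <- 0L
  while (any(!passive) && max(w[!passive]) > tol && outer < iter_max) {
    outer <- outer + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]   # which.max returns lowest index on ties
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- rep(0, n)
      zp <- tryCatch(solve_ls(a[, idx, drop = FALSE], y),
                     error = function(e) NULL)
      if (is.null(zp)) { # degenerate passive set: back the entering var out
        passive[j] <- FALSE
        w[j] <- 0
        break
      }
      z[idx] <- zp
      if (all(zp > 0)) {
        b <- z
        break
      }
      neg <- idx[zp <= 0]
      alpha <- min(b[neg] / (b[neg] - z[neg]))
      b <- b + alpha * (z - b)
      passive[b <= tol & passive] <- FALSE
      b[!passive] <- 0
    }
    w <- as.numeric(crossprod(a, y - a %*% b))
  }
  b
}

#' Solver configuration for the nonlinear least-squares engine
#'
#' @param lm_lambda0 initial Levenberg-Marquardt damping (0 = pure
#'   Gauss-Newton).
#' @param lm_rate damping divisor r > 1; lambda is divided by r after every
#'   accepted step and multiplied by r when a step is rejected.
#' @param max_iterations iteration cap.
#' @param residual_tolerance relative change in the total squared residual
#'   below which iteration stops.
#' @return a \code{qmr_solver_config} list.
#' @export
solver_config <- function(lm_lambda0 = 1.0, lm_rate = 10,
                          max_iterations = 100, residual_tolerance = 1e-8) {
  stopifnot(lm_lambda0 >= 0, lm_rate > 1, max_iterations >= 1,
            residual_tolerance >= 0)
  structure(list(lm_lambda0 = lm_lambda0, lm_rate = lm_rate,
                 max_iterations = as.integer(max_iterations),
                 residual_tolerance = residual_tolerance),
            class = "qmr_solver_config")
}

#' Describe a nonlinear least-squares problem
#'
#' @param model function(params) -> predicted signal vector (the fixed
#'   acquisition variables are captured in the closure).
#' @param initial_params starting parameter vector.
#' @param jacobian optional function(params) -> m x n matrix of partial
#'   derivatives; when NULL, central finite differences with relative step
#'   1e-6 are used.
#' @param lower,upper optional per-parameter bounds, enforced by clipping
#'   after each step.
#' @param project optional function(params) -> params applied after
#'   clipping, for joint constraints such as a simplex.
#' @return a \code{qmr_nl_problem} list.
#' @export
nonlinear_problem <- function(model, initial_params, jacobian = NULL,
                              lower = NULL, upper = NULL, project = NULL) {
  structure(list(model = model, initial_params = as.numeric(initial_params),
                 jacobian = jacobian, lower = lower, upper = upper,
                 project = project),
            class = "qmr_nl_problem")
}

fd_jacobian <- function(model, params, rel_step = 1e-6) {
  n <- length(params)
  f0 <- model(params)
  jac <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(params[j]), 1e-4)
    up <- params; up[j] <- up[j] + h
    dn <- params; dn[j] <- dn[j] - h
    jac[, j] <- (model(up) - model(dn)) / (2 * h)
  }
  jac
}

clip_params <- function(b, lower, upper) {
  if (!is.null(lower)) b <- pmax(b, lower)
  if (!is.null(upper)) b <- pmin(b, upper)
  b
}

#' Levenberg-Marquardt / Gauss-Newton nonlinear least squares
#'
#' Iterates \code{b <- b + (A'A + lambda diag(A'A))^-1 A' dy} where A is the
#' Jacobian of the model and dy the current residual. With
#' \code{lm_lambda0 = 0} this is pure Gauss-Newton. After each accepted step
#' lambda is divided by \code{lm_rate}; a step that increases the total
#' squared residual R is rejected and lambda multiplied by \code{lm_rate}.
#' Iteration stops when the relative change in R falls below
#' \code{residual_tolerance} or \code{max_iterations} is reached.
#'
#' @param problem a \code{\link{nonlinear_problem}}.
#' @param observations measured signal vector.
#' @param config a \code{\link{solver_config}}.
#' @return list with \code{params}, total squared residual \code{residual},
#'   \code{param_errors} (n variances then the n(n-1)/2 upper-triangle
#'   covariances, NA when m <= n), \code{iterations_used}, \code{converged},
#'   and the final damping \code{lambda}.
#' @export
fit_nonlinear <- function(problem, observations, config = solver_config()) {
  y <- as.numeric(observations)
  b <- clip_params(problem$initial_params, problem$lower, problem$upper)
  if (!is.null(problem$project)) b <- problem$project(b)
  n <- length(b)
  model <- problem$model
  jac_fun <- if (is.null(problem$jacobian)) {
    function(p) fd_jacobian(model, p)
  } else problem$jacobian

  f <- model(b)
  if (any(!is.finite(f))) {
    stop(sprintf("non-finite model output at initial parameters [%s]",
                 paste(signif(b, 6), collapse = ", ")))
  }
  r_tot <- sum((y - f)^2)
  lambda <- config$lm_lambda0
  # absolute floor: residual at rounding level of the data counts as converged
  r_floor <- 1e-20 * max(sum(y^2), .Machine$double.xmin)
  converged <- r_tot <= r_floor
  iters <- 0L
  accepted <- 0L
  r_history <- r_tot

  while (!converged && iters < config$max_iterations) {
    iters <- iters + 1L
    jac <- jac_fun(b)
    dy <- y - f
    jtj <- crossprod(jac)
    damp <- diag(jtj)
    damp[damp == 0] <- 1e-12
    lhs <- jtj + lambda * diag(damp, nrow = n)
    step <- tryCatch(solve(lhs, crossprod(jac, dy)),
                     error = function(e) NULL)
    if (is.null(step)) {
      lambda <- max(lambda, 1e-8) * config$lm_rate
      if (lambda > 1e14) { converged <- accepted > 0L; break }
      next
    }
    b_new <- clip_params(b + as.numeric(step), problem$lower, problem$upper)
    if (!is.null(problem$project)) b_new <- problem$project(b_new)
    f_new <- model(b_new)
    if (any(!is.finite(f_new))) {
      stop(sprintf("non-finite model output at parameters [%s]",
                   paste(signif(b_new, 6), collapse = ", ")))
    }
    r_new <- sum((y - f_new)^2)
    if (r_new <= r_tot) {
      rel_change <- (r_tot - r_new) / max(r_tot, .Machine$double.xmin)
      b <- b_new; f <- f_new; r_tot <- r_new
      accepted <- accepted + 1L
      r_history <- c(r_history, r_tot)
      lambda <- lambda / config$lm_rate
      if (rel_change < config$residual_tolerance || r_tot <= r_floor) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- max(lambda, 1e-8) * config$lm_rate
      # damping this large means the step size is numerically zero: the fit
      # has stalled at a minimum within the precision of the Jacobian
      if (lambda > 1e14) { converged <- accepted > 0L || r_tot <= r_floor; break }
    }
  }

  m <- length(y)
  errors <- rep(NA_real_, n * (n + 1) / 2)
  if (m > n) {
    jac <- jac_fun(b)
    errors <- tryCatch(compute_param_errors(jac, r_tot),
                       error = function(e) errors)
  }
  list(params = b, residual = r_tot, param_errors = errors,
       iterations_used = iters, accepted_steps = accepted,
       converged = converged, lambda = lambda, r_history = r_history)
}

#' Parameter variance/covariance estimate for a fit
#'
#' Estimates the parameter covariance as \code{sigma^2 (A'A)^-1} with
#' \code{sigma^2 = R / (m - n)}, A being the design matrix (linear fits) or
#' the final Jacobian (nonlinear fits), and serialises it as the n variances
#' followed by the n(n-1)/2 upper-triangle covariances in row-major order,
#' n(n+1)/2 values in total (e.g. 3 volumes for a 2-parameter fit).
#'
#' @param design design matrix or final Jacobian (m x n).
#' @param residual total squared residual R of the fit.
#' @param m,n observation and parameter counts (default: taken from the
#'   design).
#' @return numeric vector of length n(n+1)/2.
#' @export
compute_param_errors <- function(design, residual, m = nrow(design),
                                 n = ncol(design)) {
  if (m <= n) stop("cannot estimate parameter errors with m <= n")
  sigma2 <- residual / (m - n)
  covm <- sigma2 * solve(crossprod(as.matrix(design)))
  ut <- which(upper.tri(covm), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  as.numeric(c(diag(covm), covm[ut]))
}

check_linear_system <- function(design, y) {
  if (nrow(design) != length(y)) {
    stop("design rows must match observation length")
  }
  if (nrow(design) < ncol(design)) {
    stop("underdetermined system: fewer observations than parameters")
  }
  invisible(TRUE)
}
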