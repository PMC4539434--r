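#' @title Two-point boundary value solving and prediction error
#' @name ode-solve
#' @description Solves the fitted second-order linear ODE
#'   \eqn{x'' + w_1(t) x' + w_0(t) x = U(t)} as a two-point boundary value
#'   problem (homogeneous \eqn{U \equiv 0} or unit-step \eqn{U \equiv 1})
#'   by Chebyshev spectral collocation, predicts held-out expression
#'   curves from their boundary values, and scores predictions by RMSPE
#'   under stratified k-fold cross-validation.
NULL

#' Boundary conditions for the two-point problem
#'
#' @param t_left,t_right domain endpoints, \code{t_left < t_right}.
#' @param x_left,x_right finite state values at the endpoints.
#' @return a \code{"boundary_conditions"} object.
#' @export
boundary_conditions <- function(t_left, t_right, x_left, x_right) {
  if (!is.finite(t_left) || !is.finite(t_right) || t_left >= t_right)
    stop("need finite t_left < t_right")
  if (!is.finite(x_left) || !is.finite(x_right))
    stop("boundary values must be finite")
  structure(list(t_left = t_left, t_right = t_right,
                 x_left = x_left, x_right = x_right),
            class = "boundary_conditions")
}

# Chebyshev differentiation matrix and nodes on [-1, 1] (descending nodes)
cheb_diff <- function(N) {
  x <- cos(pi * (0:N) / N)
  c0 <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- outer(c0, 1 / c0) / (dX + diag(N + 1))
  D <- D - diag(rowSums(D))
  list(x = x, D = D)
}

# barycentric interpolation from Chebyshev nodes xk (descending, [-1,1])
bary_interp <- function(xk, fk, xout) {
  N <- length(xk) - 1L
  wk <- c(0.5, rep(1, N - 1), 0.5) * (-1)^(0:N)
  vapply(xout, function(x) {
    d <- x - xk
    hit <- which(abs(d) < 1e-14)
    if (length(hit)) return(fk[hit[1]])
    num <- sum(wk * fk / d)
    den <- sum(wk / d)
    num / den
  }, 0)
}

# normalize coefficient specifications to a pair of vectorized functions
coef_funs <- function(coeffs) {
  if (inherits(coeffs, "ode_coefficients")) {
    force(coeffs)
    list(w0 = function(t) eval_coefficients(coeffs, t)$w0,
         w1 = function(t) eval_coefficients(coeffs, t)$w1)
  } else if (is.list(coeffs) && all(c("w0", "w1") %in% names(coeffs))) {
    mk <- function(w) {
      if (is.function(w)) w
      else if (is.numeric(w) && length(w) == 1L) function(t) rep(w, length(t))
      else stop("coefficient entries must be functions or scalars")
    }
    list(w0 = mk(coeffs$w0), w1 = mk(coeffs$w1))
  } else stop("coeffs must be ode_coefficients or list(w0=, w1=)")
}

#' Solve the ODE as a two-point boundary value problem
#'
#' Spectral collocation: the solution is represented by its values at
#' Chebyshev nodes on \code{[t_left, t_right]}; the differential operator
#' becomes \eqn{D^2 + \mathrm{diag}(w_1) D + \mathrm{diag}(w_0)} with
#' Chebyshev differentiation matrices, boundary rows are replaced by the
#' two boundary conditions, and the dense linear system is solved
#' directly.  A near-singular collocation matrix (the homogeneous BVP
#' admits a nontrivial solution, i.e. near-resonance) raises an error
#' rather than silently returning one of many solutions.
#'
#' @param coeffs \code{ode_coefficients}, or \code{list(w0=, w1=)} of
#'   vectorized functions/scalars.
#' @param bc a \code{\link{boundary_conditions}} object.
#' @param forcing \code{"none"} (\eqn{U \equiv 0}) or \code{"unit_step"}
#'   (\eqn{U \equiv 1}).
#' @param grid number of equispaced output points (default 201) or a
#'   numeric vector of output positions.
#' @param n_colloc number of Chebyshev collocation nodes (default 65).
#' @return a \code{"solution_curve"}: \code{t}, \code{x}, \code{forcing},
#'   \code{residual} (max interior collocation residual
#'   \eqn{|L(\hat x) - U|}), plus the raw node values for reuse.
#' @examples
#' sol <- solve_ode_bvp(list(w0 = 1, w1 = 0),
#'                      boundary_conditions(0, pi / 2, 0, 1))
#' max(abs(sol$x - sin(sol$t)))  # ~ 1e-13
#' @export
solve_ode_bvp <- function(coeffs, bc, forcing = c("none", "unit_step"),
                          grid = 201, n_colloc = 65) {
  forcing <- match.arg(forcing)
  stopifnot(inherits(bc, "boundary_conditions"))
  funs <- coef_funs(coeffs)
  N <- as.integer(n_colloc) - 1L
  if (N < 4) stop("n_colloc must be at least 5")
  cd <- cheb_diff(N)
  a <- bc$t_left; b <- bc$t_right
  tn <- (a + b) / 2 + (b - a) / 2 * cd$x     # descending: tn[1]=b, tn[N+1]=a
  D1 <- (2 / (b - a)) * cd$D
  D2 <- D1 %*% D1
  w0 <- funs$w0(tn); w1 <- funs$w1(tn)
  if (!all(is.finite(w0)) || !all(is.finite(w1)))
    stop("coefficient functions not finite on the solution domain")
  A <- D2 + w1 * D1 + diag(w0)
  u <- if (forcing == "unit_step") rep(1, N + 1) else rep(0, N + 1)
  Abc <- A; rhs <- u
  Abc[1, ] <- 0; Abc[1, 1] <- 1; rhs[1] <- bc$x_right
  Abc[N + 1, ] <- 0; Abc[N + 1, N + 1] <- 1; rhs[N + 1] <- bc$x_left
  rc <- rcond(Abc)
  if (!is.finite(rc) || rc < 1e-13)
    stop("singular or near-resonant boundary value problem ",
         "(collocation matrix reciprocal condition ", signif(rc, 3),
         "); the homogeneous BVP admits a nontrivial solution")
  xn <- drop(solve(Abc, rhs))
  resid <- max(abs((A %*% xn - u)[2:N]))
  tout <- if (length(grid) == 1L) seq(a, b, length.out = grid) else
    as.numeric(grid)
  xi <- 2 * (tout - (a + b) / 2) / (b - a)
  xout <- bary_interp(cd$x, xn, xi)
  structure(list(t = tout, x = xout, forcing = forcing, residual = resid,
                 nodes = tn, node_values = xn, bc = bc),
            class = "solution_curve")
}

#' @export
print.solution_curve <- function(x, ...) {
  cat(sprintf("solution_curve on [%g, %g] (%d points), forcing %s, residual %.2e\n",
              min(x$t), max(x$t), length(x$t), x$forcing, x$residual))
  invisible(x)
}

#' Predict a held-out expression curve from a trained operator
#'
#' The test curve is smoothed with the trained operator penalty; the
#' smooth is evaluated at the two domain endpoints to supply boundary
#' values, and the homogeneous ODE with the trained coefficient functions
#' is solved between them.
#'
#' @param coeffs_train \code{ode_coefficients} from the training fit.
#' @param test_curve an \code{expression_curve} covering the full domain.
#' @param bs the basis (defaults to the one in \code{coeffs_train}).
#' @param lambda smoothing weight used for the boundary-value smooth
#'   (default: 1, or supply the training value).
#' @param grid output resolution passed to \code{\link{solve_ode_bvp}}.
#' @return a \code{solution_curve} over the basis domain.
#' @export
predict_curve <- function(coeffs_train, test_curve, bs = coeffs_train$basis,
                          lambda = 1, grid = 201) {
  stopifnot(inherits(test_curve, "expression_curve"))
  fit <- smooth_states(list(test_curve), bs, coeffs_train, lambda)
  ends <- drop(fitted_states(fit, bs$domain))
  bc <- boundary_conditions(bs$domain[1], bs$domain[2], ends[1], ends[2])
  solve_ode_bvp(coeffs_train, bc, forcing = "none", grid = grid)
}

#' Root mean square prediction error of a fold
#'
#' Per sample, the root of the mean squared difference between predicted
#' and observed expression over the observed positions; these per-sample
#' roots are then averaged over the samples of the fold.
#'
#' @param observed list of \code{expression_curve}s (one fold), or plain
#'   numeric vectors of observed values.
#' @param predicted matched list of \code{solution_curve}s (interpolated
#'   onto each observed grid) or numeric vectors of predictions at the
#'   observed positions.
#' @return the fold RMSPE (scalar).
#' @export
rmspe <- function(observed, predicted) {
  if (inherits(observed, "expression_curve") || is.numeric(observed))
    observed <- list(observed)
  if (inherits(predicted, "solution_curve") || is.numeric(predicted))
    predicted <- list(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must match in length")
  per_sample <- mapply(function(obs, pred) {
    y <- if (is.numeric(obs)) obs else obs$y
    yhat <- if (inherits(pred, "solution_curve")) {
      if (is.numeric(obs))
        stop("solution-curve predictions need expression-curve observations")
      stats::approx(pred$t, pred$x, xout = obs$t)$y
    } else as.numeric(pred)
    if (length(yhat) != length(y))
      stop("prediction length ", length(yhat),
           " does not match observation length ", length(y))
    sqrt(mean((yhat - y)^2))
  }, observed, predicted)
  mean(per_sample)
}

#' Stratified k-fold cross-validated prediction error
#'
#' Samples are partitioned into k folds within each group (seeded).  For
#' every fold and group, the operator is fitted on that group's training
#' samples and each held-out curve is predicted from its boundary values;
#' the fold RMSPE is reported per group.
#'
#' @param curves list of \code{expression_curve}s with \code{group}
#'   labels (a single unlabeled collection is treated as one group).
#' @param k number of folds (default 5).
#' @param K odd basis size.
#' @param lambda smoothing weight used throughout.
#' @param seed integer seed for the fold assignment.
#' @return data.frame with columns \code{fold}, \code{group},
#'   \code{rmspe}; attribute \code{"folds"} carries the assignment.
#' @export
kfold_cv <- function(curves, k = 5, K = 11, lambda = 1, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  groups <- vapply(curves, function(cv)
    if (is.null(cv$group) || is.na(cv$group)) "all" else cv$group, "")
  fold_id <- stratified_folds(groups, k, seed)
  bs <- fourier_basis(K)
  out <- do.call(rbind, lapply(seq_len(k), function(f) {
    do.call(rbind, lapply(unique(groups), function(g) {
      tr <- curves[groups == g & fold_id != f]
      te <- curves[groups == g & fold_id == f]
      pf <- fit_pda(tr, lambda = lambda, bs = bs)
      preds <- lapply(te, function(cv)
        predict_curve(pf$coeffs, cv, bs, lambda = lambda))
      data.frame(fold = f, group = g, rmspe = rmspe(te, preds),
                 stringsAsFactors = FALSE)
    }))
  }))
  attr(out, "folds") <- fold_id
  out
}
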