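#' @title Principal differential analysis for a second-order operator
#' @name pda-core
#' @description Estimation of the location-varying coefficient functions
#'   \eqn{w_0(t), w_1(t)} of the annihilating operator
#'   \eqn{L(x) = x'' + w_1(t) x' + w_0(t) x} from a collection of noisy
#'   expression curves, by alternating (i) penalized basis smoothing with
#'   the ODE-defined roughness penalty \eqn{\lambda \int L(\hat x)^2 dt}
#'   and (ii) a closed-form least-squares update of the operator
#'   coefficients.
NULL

#' Construct an ODE coefficient object
#'
#' Bundles the basis-expansion vectors of the two coefficient functions:
#' \eqn{w_0(t) = h_0^\top \phi(t)}, \eqn{w_1(t) = h_1^\top \phi(t)}.
#'
#' @param h0,h1 numeric vectors of length \code{bs$K}.
#' @param bs the \code{fourier_basis} the expansions refer to.
#' @return an object of class \code{"ode_coefficients"}.
#' @export
ode_coefficients <- function(h0, h1, bs) {
  stopifnot(inherits(bs, "fourier_basis"),
            length(h0) == bs$K, length(h1) == bs$K,
            all(is.finite(h0)), all(is.finite(h1)))
  structure(list(h0 = as.numeric(h0), h1 = as.numeric(h1), basis = bs),
            class = "ode_coefficients")
}

#' Evaluate coefficient functions w0(t), w1(t)
#'
#' @param coeffs an \code{ode_coefficients} object.
#' @param t evaluation points.
#' @return list with numeric vectors \code{w0} and \code{w1}.
#' @export
eval_coefficients <- function(coeffs, t) {
  P <- eval_basis(coeffs$basis, t)
  list(w0 = drop(P %*% coeffs$h0), w1 = drop(P %*% coeffs$h1))
}

#' @export
print.ode_coefficients <- function(x, ...) {
  w <- eval_coefficients(x, x$basis$grid)
  cat(sprintf("ode_coefficients (K = %d): w0 in [%.4g, %.4g], w1 in [%.4g, %.4g]\n",
              x$basis$K, min(w$w0), max(w$w0), min(w$w1), max(w$w1)))
  invisible(x)
}

# evaluate the coefficient basis theta on the state basis quadrature grid,
# reusing the cached evaluation when the two bases coincide
theta_on_grid <- function(bs, coeffs) {
  bsw <- coeffs$basis
  if (bsw$K == bs$K && identical(bsw$domain, bs$domain)) bs$Phi0
  else eval_basis(bsw, bs$grid)
}

# Psi(t) = phi''(t) + G(t) h evaluated on the quadrature grid (n_quad x K),
# where G(t) = [phi'(t) theta(t)^T, phi(t) theta(t)^T] and h = (h1, h0);
# theta is the (possibly lower-dimensional) coefficient-function basis.
psi_matrix <- function(bs, coeffs) {
  Th <- theta_on_grid(bs, coeffs)
  s1 <- drop(Th %*% coeffs$h1)
  s0 <- drop(Th %*% coeffs$h0)
  bs$Phi2 + bs$Phi1 * s1 + bs$Phi0 * s0
}

#' ODE roughness penalty matrix
#'
#' \eqn{J_{\phi h} = \int \Psi(t) \Psi^\top(t)\,dt} with
#' \eqn{\Psi(t) = \phi''(t) + G(t)h}, so that the smoothing penalty
#' \eqn{C_i^\top J_{\phi h} C_i} equals \eqn{\int L(\hat x_i)^2 dt}.
#' With \eqn{h = 0} this is the usual squared-second-derivative penalty.
#'
#' @param bs a \code{fourier_basis}.
#' @param coeffs an \code{ode_coefficients} object (or \code{NULL} for
#'   \eqn{h = 0}).
#' @return symmetric positive semidefinite \code{K x K} matrix.
#' @export
ode_penalty_matrix <- function(bs, coeffs = NULL) {
  if (is.null(coeffs))
    coeffs <- ode_coefficients(numeric(bs$K), numeric(bs$K), bs)
  Psi <- psi_matrix(bs, coeffs)
  J <- crossprod(Psi, bs$weights * Psi)
  (J + t(J)) / 2
}

# solve A x = b, falling back to the Moore-Penrose pseudo-inverse when A is
# numerically singular; returns list(x, pseudo)
solve_or_pinv <- function(A, b, kappa_max = 1e12) {
  ok <- TRUE
  x <- tryCatch({
    if (rcond(A) < 1 / kappa_max) ok <- FALSE
    if (ok) solve(A, b) else NULL
  }, error = function(e) { ok <<- FALSE; NULL })
  if (!ok) {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    x <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  }
  list(x = x, pseudo = !ok)
}

#' Penalized smoothing of expression curves for a fixed operator
#'
#' For each sample \eqn{i}, solves the penalized least-squares problem
#' \eqn{\min_{C_i} \sum_j (y_i(t_j) - C_i^\top\phi(t_j))^2 +
#' \lambda C_i^\top J_{\phi h} C_i}, giving
#' \eqn{C_i = (\tilde\Phi^\top\tilde\Phi + \lambda J_{\phi h})^{-1}
#' \tilde\Phi^\top Y_i}.  Samples decouple (block-diagonal design), so
#' each is solved on its own observation grid.
#'
#' @param curves list of \code{expression_curve} objects.
#' @param bs a \code{fourier_basis}.
#' @param coeffs \code{ode_coefficients} defining the penalty
#'   (\code{NULL} for the curvature penalty \eqn{h = 0}).
#' @param lambda penalty weight \eqn{\lambda \ge 0}.
#' @return object of class \code{"state_fit"}: coefficient matrix \code{C}
#'   (n samples x K), \code{lambda}, per-sample residual sum of squares,
#'   the basis and the penalty used.
#' @export
smooth_states <- function(curves, bs, coeffs = NULL, lambda = 0) {
  stopifnot(inherits(bs, "fourier_basis"), lambda >= 0)
  if (inherits(curves, "expression_curve")) curves <- list(curves)
  if (!length(curves)) stop("no curves supplied")
  J <- ode_penalty_matrix(bs, coeffs)
  n <- length(curves)
  C <- matrix(0, n, bs$K)
  rss <- numeric(n)
  # curves often share one observation grid; factor the normal matrix once
  tkey <- vapply(curves, function(cv) paste(signif(cv$t, 12), collapse = ","), "")
  for (key in unique(tkey)) {
    idx <- which(tkey == key)
    tt <- curves[[idx[1]]]$t
    Phi <- eval_basis(bs, tt)
    A <- crossprod(Phi) + lambda * J
    if (lambda == 0 && length(tt) < bs$K)
      stop("normal matrix singular: fewer observations (", length(tt),
           ") than basis functions (", bs$K,
           ") with lambda = 0; raise lambda or lower K")
    Y <- vapply(curves[idx], function(cv) cv$y, numeric(length(tt)))
    sol <- solve_or_pinv(A, crossprod(Phi, Y))
    if (sol$pseudo)
      warning("ill-conditioned smoothing system; pseudo-inverse used")
    C[idx, ] <- t(sol$x)
    res <- Y - Phi %*% sol$x
    rss[idx] <- colSums(res^2)
  }
  structure(list(C = C, lambda = lambda, rss = rss, basis = bs,
                 penalty = J,
                 sample_ids = vapply(curves, function(cv) cv$sample_id, ""),
                 groups = vapply(curves, function(cv)
                   if (is.null(cv$group)) NA_character_ else cv$group, "")),
            class = "state_fit")
}

#' Fitted state curves from a state_fit
#'
#' @param fit a \code{state_fit}.
#' @param t evaluation points (default: the basis quadrature grid).
#' @return matrix, samples in rows, \code{length(t)} columns.
#' @export
fitted_states <- function(fit, t = fit$basis$grid) {
  fit$C %*% t(eval_basis(fit$basis, t))
}

#' Closed-form update of the ODE coefficient functions
#'
#' Given smoothed states with coefficient matrix \eqn{C_*} (samples in
#' rows), minimizes \eqn{SSE_p = \int \Psi^\top C_*^\top C_* \Psi\,dt}
#' over \eqn{h = (h_1, h_0)}:
#' \deqn{h = -\Big[\int G^\top C_*^\top C_* G\,dt\Big]^{-1}
#'            \int G^\top C_*^\top C_* \phi''\,dt.}
#' The \eqn{2K \times 2K} system is solved with a pseudo-inverse fallback
#' (flagged) when rank-deficient — unavoidable when the curves span too
#' small a subspace to identify both coefficient functions.
#'
#' @param fit a \code{state_fit}.
#' @param bs basis of the state expansion (defaults to the fit's basis).
#' @param bs_w basis of the coefficient-function expansion; defaults to
#'   \code{bs}, but a lower-dimensional system may be supplied.
#' @return an \code{ode_coefficients} object with attribute
#'   \code{"pseudo_inverse_used"}.
#' @export
estimate_coefficients <- function(fit, bs = fit$basis, bs_w = bs) {
  M <- crossprod(fit$C)            # C*^T C*, K x K
  if (all(M == 0)) stop("all-zero state coefficients: no signal to fit")
  P0 <- bs$Phi0; P1 <- bs$Phi1; P2 <- bs$Phi2
  w <- bs$weights
  Th <- if (bs_w$K == bs$K && identical(bs_w$domain, bs$domain)) P0
        else eval_basis(bs_w, bs$grid)
  # G^T M G has the Kronecker-like block structure
  #   [ q11 th th^T, q10 th th^T ; q10 th th^T, q00 th th^T ]
  # with scalars q11 = phi'^T M phi', q10 = phi'^T M phi, q00 = phi^T M phi
  MP0 <- P0 %*% M
  q11 <- rowSums((P1 %*% M) * P1)
  q10 <- rowSums(MP0 * P1)
  q00 <- rowSums(MP0 * P0)
  A11 <- crossprod(Th, (w * q11) * Th)
  A10 <- crossprod(Th, (w * q10) * Th)
  A00 <- crossprod(Th, (w * q00) * Th)
  A <- rbind(cbind(A11, A10), cbind(A10, A00))
  r1 <- rowSums((P1 %*% M) * P2)   # phi'^T M phi''
  r0 <- rowSums(MP0 * P2)          # phi^T  M phi''
  b <- c(crossprod(Th, w * r1), crossprod(Th, w * r0))
  sol <- solve_or_pinv((A + t(A)) / 2, -b)
  h <- drop(sol$x)
  Kw <- bs_w$K
  out <- ode_coefficients(h0 = h[(Kw + 1):(2 * Kw)], h1 = h[1:Kw], bs_w)
  attr(out, "pseudo_inverse_used") <- sol$pseudo
  out
}

# SSE_p = int Psi^T C*^T C* Psi dt for the current (C, h)
sse_p <- function(fit, coeffs, bs = fit$basis) {
  Psi <- psi_matrix(bs, coeffs)
  M <- crossprod(fit$C)
  sum(bs$weights * rowSums((Psi %*% M) * Psi))
}

#' Fit the varying-coefficient ODE by principal differential analysis
#'
#' Alternates \code{\link{smooth_states}} (penalized smoothing with the
#' current operator penalty; initialized at \eqn{h = 0}, i.e. a pure
#' curvature penalty) and \code{\link{estimate_coefficients}}
#' (closed-form operator update) until the relative change in \eqn{h}
#' drops below \code{tol} or \code{max_iter} is reached.
#'
#' @param curves list of \code{expression_curve}s (a single curve is
#'   allowed but two or more linearly independent curves materially
#'   stabilize the coefficient estimates).
#' @param K odd number of Fourier basis functions for the state
#'   expansion (default 11).
#' @param K_w odd basis size for the coefficient functions
#'   \eqn{w_0, w_1} (default: same as \code{K}).
#' @param lambda smoothing weight (default 1; see
#'   \code{\link{select_lambda}} for a cross-validated choice).
#' @param tol relative-change convergence threshold on \eqn{h}
#'   (default 1e-6); \code{tol = Inf} performs exactly one
#'   smooth-then-estimate pass.
#' @param max_iter iteration cap (default 50).
#' @param bs optionally a prebuilt \code{fourier_basis} (overrides
#'   \code{K}).
#' @return list of class \code{"pda_fit"}: \code{fit} (the final
#'   \code{state_fit}), \code{coeffs} (\code{ode_coefficients}),
#'   \code{diagnostics} (per-iteration \code{sse_p}, \code{h} change,
#'   \code{converged}, \code{sse_monotone}, \code{pseudo_inverse_used}).
#' @export
fit_pda <- function(curves, K = 11, lambda = 1, tol = 1e-6, max_iter = 50,
                    bs = NULL, K_w = NULL) {
  if (inherits(curves, "expression_curve")) curves <- list(curves)
  if (!length(curves)) stop("no curves supplied")
  if (!is.infinite(tol) && tol <= 0) stop("tol must be positive")
  if (is.null(bs)) bs <- fourier_basis(K)
  bs_w <- if (is.null(K_w) || K_w == bs$K) bs else fourier_basis(K_w)
  coeffs <- ode_coefficients(numeric(bs_w$K), numeric(bs_w$K), bs_w)
  h_old <- c(coeffs$h1, coeffs$h0)
  sse_path <- numeric(0)
  dh_path <- numeric(0)
  converged <- FALSE
  pseudo <- FALSE
  fit <- NULL
  for (it in seq_len(max(1, max_iter))) {
    fit <- smooth_states(curves, bs, coeffs, lambda)
    coeffs <- estimate_coefficients(fit, bs, bs_w)
    pseudo <- pseudo || isTRUE(attr(coeffs, "pseudo_inverse_used"))
    sse_path[it] <- sse_p(fit, coeffs, bs)
    h_new <- c(coeffs$h1, coeffs$h0)
    dh <- sqrt(sum((h_new - h_old)^2)) / (1 + sqrt(sum(h_old^2)))
    dh_path[it] <- dh
    h_old <- h_new
    if (is.infinite(tol) || dh < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("PDA iteration did not converge in ", max_iter,
            " iterations (last relative change ",
            signif(dh_path[length(dh_path)], 3), "); best iterate returned")
  structure(list(
    fit = fit, coeffs = coeffs,
    diagnostics = list(sse_p = sse_path, h_change = dh_path,
                       iterations = length(sse_path), converged = converged,
                       sse_monotone = !is.unsorted(rev(sse_path), strictly = FALSE),
                       pseudo_inverse_used = pseudo),
    lambda = lambda), class = "pda_fit")
}

#' @export
print.pda_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("pda_fit: %d sample(s), K = %d, lambda = %g; ",
                     "%d iteration(s), %sconverged, final SSE_p = %.4g\n"),
              nrow(x$fit$C), x$coeffs$basis$K, x$lambda, d$iterations,
              if (d$converged) "" else "NOT ", d$sse_p[d$iterations]))
  invisible(x)
}

#' Cross-validated choice of the smoothing weight
#'
#' Sample-level k-fold cross-validation: for each candidate
#' \eqn{\lambda}, the operator is fitted on the training samples and each
#' held-out curve is reconstructed by solving the fitted ODE from its own
#' smoothed boundary values (\code{\link{predict_curve}}); the
#' \eqn{\lambda} minimizing mean held-out squared reconstruction error
#' wins.  Held-out samples whose prediction problem is singular
#' (near-resonant trained operator) are dropped; a fold with no
#' predictable sample scores \code{Inf}, and ties resolve to the
#' smallest candidate.
#'
#' @param curves list of \code{expression_curve}s.
#' @param K odd basis size.
#' @param lambda_grid non-empty numeric grid of candidate weights.
#' @param folds number of folds (default 5).
#' @param seed integer seed making the fold assignment reproducible.
#' @return the selected \eqn{\lambda^*} with attribute \code{"cv_error"}
#'   (mean held-out error per grid value).
#' @export
select_lambda <- function(curves, K = 11, lambda_grid = 10^seq(-2, 6, by = 2),
                          folds = 5, seed = 1) {
  if (!length(lambda_grid)) stop("lambda_grid must be non-empty")
  n <- length(curves)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("fewer samples (", n, ") than folds (", folds, ")")
  lambda_grid <- sort(lambda_grid)
  if (length(lambda_grid) == 1L) {
    out <- lambda_grid
    attr(out, "cv_error") <- NA_real_
    return(out)
  }
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  bs <- fourier_basis(K)
  err <- vapply(lambda_grid, function(lam) {
    fe <- vapply(seq_len(folds), function(f) {
      tr <- curves[fold_id != f]; te <- curves[fold_id == f]
      pf <- suppressWarnings(fit_pda(tr, lambda = lam, bs = bs))
      # a near-resonant trained operator cannot predict held-out curves;
      # such samples drop out, and a fold with none scores Inf
      se <- vapply(te, function(cv) {
        tryCatch({
          pr <- predict_curve(pf$coeffs, cv, bs, lambda = lam)
          xhat <- stats::approx(pr$t, pr$x, xout = cv$t)$y
          mean((xhat - cv$y)^2)
        }, error = function(e) NA_real_)
      }, 0)
      if (all(is.na(se))) Inf else mean(se, na.rm = TRUE)
    }, 0)
    mean(fe)
  }, 0)
  # ties (including the all-Inf degenerate case) resolve to the smallest
  out <- lambda_grid[which.min(err)]
  attr(out, "cv_error") <- stats::setNames(err, signif(lambda_grid, 6))
  out
}
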