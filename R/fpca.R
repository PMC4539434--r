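#' @title Functional principal component analysis on a common grid
#' @name fpca
#' @description FPCA of curve collections (ODE coefficient curves or
#'   unit-step response curves): eigenfunctions of the quadrature-weighted
#'   sample covariance operator around the mean function, and score
#'   features obtained by projecting centered curves onto them.
NULL

# trapezoid quadrature weights for an arbitrary strictly increasing grid
trapezoid_weights <- function(t) {
  m <- length(t)
  if (m < 2 || any(diff(t) <= 0)) stop("grid must be strictly increasing")
  w <- numeric(m)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[m] <- dt[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (dt[-1] + dt[-(m - 1)]) / 2
  w
}

#' Fit an FPCA model to curves on a common grid
#'
#' Curves are centered by the pointwise mean function; the
#' quadrature-weighted sample covariance operator is eigendecomposed via
#' the symmetrized matrix \eqn{W^{1/2} \hat C W^{1/2}}, giving
#' eigenfunctions orthonormal under the grid quadrature.  Each
#' eigenfunction's sign is fixed so its quadrature integral is
#' non-negative (first non-negligible grid value positive as the
#' tie-break), making scores reproducible.
#'
#' @param X numeric matrix, one curve per row, evaluated on \code{t}.
#' @param t common grid (strictly increasing).
#' @param K_pc number of components to retain; default: smallest number
#'   explaining at least \code{var_target} of variance, capped at 10.
#' @param var_target variance fraction target used when \code{K_pc} is
#'   \code{NULL} (default 0.9).
#' @return an object of class \code{"fpca_model"}: \code{mean},
#'   \code{efuns} (grid x K_pc), \code{evalues} (descending, all
#'   components), \code{varprop}, \code{t}, \code{weights}, \code{K_pc}.
#' @export
fit_fpca <- function(X, t, K_pc = NULL, var_target = 0.9) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("FPCA needs at least 2 curves")
  if (ncol(X) != length(t)) stop("curves and grid differ in length")
  w <- trapezoid_weights(t)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sw <- sqrt(w)
  A <- crossprod(Xc) / (n - 1)                 # sample covariance, m x m
  A <- (sw %o% sw) * A
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  evalues <- pmax(eg$values, 0)
  if (is.null(K_pc)) {
    tot <- sum(evalues)
    K_pc <- if (tot <= 0) 1L else
      min(10L, which(cumsum(evalues) / tot >= var_target)[1])
  }
  K_pc <- min(as.integer(K_pc), length(evalues))
  efuns <- eg$vectors[, seq_len(K_pc), drop = FALSE] / sw
  # sign convention: quadrature integral >= 0, tie-break on first
  # non-negligible value
  for (j in seq_len(K_pc)) {
    s <- sum(w * efuns[, j])
    if (abs(s) < 1e-8) {
      nz <- which(abs(efuns[, j]) > 1e-8)
      s <- if (length(nz)) efuns[nz[1], j] else 1
    }
    if (s < 0) efuns[, j] <- -efuns[, j]
  }
  tot <- sum(evalues)
  structure(list(mean = mu, efuns = efuns, evalues = evalues,
                 varprop = if (tot > 0) evalues / tot else
                   rep(0, length(evalues)),
                 t = t, weights = w, K_pc = K_pc),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("fpca_model: %d component(s) on a %d-point grid; var explained %s\n",
              x$K_pc, length(x$t),
              paste(sprintf("%.1f%%", 100 * x$varprop[seq_len(x$K_pc)]),
                    collapse = ", ")))
  invisible(x)
}

#' Project curves onto FPCA eigenfunctions
#'
#' Scores are quadrature inner products of mean-centered curves with the
#' eigenfunctions: \eqn{z_{ij} = \int \beta_j(t)(w_i(t) - \bar w(t))dt}.
#'
#' @param model an \code{fpca_model}.
#' @param X curves on the model grid, one per row.
#' @return numeric matrix of scores, \code{nrow(X)} x \code{model$K_pc}.
#' @export
project_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$t))
    stop("curves are not on the model grid (", length(model$t), " points)")
  sweep(X, 2, model$mean) %*% (model$weights * model$efuns)
}

#' Reconstruct curves from scores
#'
#' @param model an \code{fpca_model}.
#' @param scores matrix of scores (columns = components, possibly fewer
#'   than \code{model$K_pc}).
#' @return matrix of reconstructed curves on the model grid.
#' @export
reconstruct_curves <- function(model, scores) {
  scores <- as.matrix(scores)
  J <- ncol(scores)
  rec <- scores %*% t(model$efuns[, seq_len(J), drop = FALSE])
  sweep(rec, 2, model$mean, "+")
}

#' Assemble the interleaved score feature matrix
#'
#' FPCA is run separately on the two coefficient-function collections;
#' the selected scores are interleaved per component
#' (\eqn{z^{(0)}_{i1}, z^{(1)}_{i1}, z^{(0)}_{i2}, z^{(1)}_{i2}, \dots})
#' into one feature matrix for classification or clustering.
#'
#' @param model_w0,model_w1 \code{fpca_model}s fitted to the w0 and w1
#'   curve collections.
#' @param w0_curves,w1_curves per-sample coefficient curves on the
#'   respective model grids (rows = samples, aligned across the two).
#' @param sample_ids optional row names.
#' @return numeric matrix \code{n x (2 K)} with labeled columns, where
#'   \code{K = min(model_w0$K_pc, model_w1$K_pc)}.
#' @export
score_features <- function(model_w0, model_w1, w0_curves, w1_curves,
                           sample_ids = NULL) {
  if (nrow(as.matrix(w0_curves)) != nrow(as.matrix(w1_curves)))
    stop("w0 and w1 curve collections differ in sample count")
  z0 <- project_scores(model_w0, w0_curves)
  z1 <- project_scores(model_w1, w1_curves)
  K <- min(ncol(z0), ncol(z1))
  Z <- matrix(0, nrow(z0), 2 * K)
  Z[, 2 * seq_len(K) - 1] <- z0[, seq_len(K)]
  Z[, 2 * seq_len(K)] <- z1[, seq_len(K)]
  colnames(Z) <- as.vector(rbind(paste0("w0_pc", seq_len(K)),
                                 paste0("w1_pc", seq_len(K))))
  if (!is.null(sample_ids)) rownames(Z) <- sample_ids
  Z
}
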