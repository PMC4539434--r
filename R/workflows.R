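#' @title Per-sample workflow helpers
#' @name workflows
#' @description Convenience layers composing the estimator with the BVP
#'   solver: per-sample operator fits, their coefficient curves (the
#'   classification/clustering features before FPCA), and per-sample
#'   unit-step response curves (the input of the Hotelling test).
NULL

#' Per-sample ODE fits, coefficient curves and unit-step responses
#'
#' Fits the varying-coefficient operator to each curve individually
#' (the per-individual mode of the model), evaluates the fitted
#' \eqn{w_0(t)}, \eqn{w_1(t)} on an output grid, and solves the fitted
#' ODE under unit-step forcing from the smoothed boundary values of the
#' same sample.
#'
#' @param curves list of \code{expression_curve}s.
#' @param K odd basis size (default 11).
#' @param lambda smoothing weight (default 1).
#' @param grid number of equispaced output positions on the basis domain
#'   (default 201).
#' @param responses also compute unit-step response curves (default
#'   TRUE; set FALSE to save the BVP solves when only coefficient
#'   features are needed).
#' @return list with \code{t} (output grid), \code{w0}, \code{w1}
#'   (sample x grid matrices), \code{response} (sample x grid matrix or
#'   NULL), \code{groups}, \code{sample_ids}, \code{fits} (list of
#'   \code{pda_fit}s).
#' @export
fit_per_sample <- function(curves, K = 11, lambda = 1, grid = 201,
                           responses = TRUE) {
  if (inherits(curves, "expression_curve")) curves <- list(curves)
  bs <- fourier_basis(K)
  tout <- seq(bs$domain[1], bs$domain[2], length.out = grid)
  n <- length(curves)
  W0 <- W1 <- matrix(0, n, grid)
  R <- if (responses) matrix(0, n, grid) else NULL
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    pf <- suppressWarnings(fit_pda(curves[[i]], lambda = lambda, bs = bs))
    fits[[i]] <- pf
    w <- eval_coefficients(pf$coeffs, tout)
    W0[i, ] <- w$w0; W1[i, ] <- w$w1
    if (responses) {
      ends <- drop(fitted_states(pf$fit, bs$domain))
      bc <- boundary_conditions(bs$domain[1], bs$domain[2], ends[1], ends[2])
      R[i, ] <- solve_ode_bvp(pf$coeffs, bc, forcing = "unit_step",
                              grid = tout)$x
    }
  }
  list(t = tout, w0 = W0, w1 = W1, response = R,
       groups = vapply(curves, function(cv)
         if (is.null(cv$group)) NA_character_ else cv$group, ""),
       sample_ids = vapply(curves, function(cv) cv$sample_id, ""),
       fits = fits)
}

#' FPCA score features from per-sample coefficient curves
#'
#' Runs FPCA separately on the \eqn{w_0} and \eqn{w_1} curve collections
#' of a \code{\link{fit_per_sample}} result and assembles the interleaved
#' feature matrix.
#'
#' @param ps a \code{\link{fit_per_sample}} result.
#' @param K_pc components per coefficient function (default: 90\%
#'   variance, capped at 10).
#' @return list with \code{Z} (feature matrix), \code{model_w0},
#'   \code{model_w1}, \code{groups}.
#' @export
coefficient_features <- function(ps, K_pc = NULL) {
  m0 <- fit_fpca(ps$w0, ps$t, K_pc = K_pc)
  m1 <- fit_fpca(ps$w1, ps$t, K_pc = K_pc)
  Z <- score_features(m0, m1, ps$w0, ps$w1, sample_ids = ps$sample_ids)
  list(Z = Z, model_w0 = m0, model_w1 = m1, groups = ps$groups)
}
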