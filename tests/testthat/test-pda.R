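test_that("ODE penalty matrix reduces to curvature penalty at h = 0", {
  bs <- fourier_basis(7)
  J <- ode_penalty_matrix(bs)
  # constant basis function has zero second derivative: zero row/column
  expect_equal(J[1, ], rep(0, 7))
  expect_equal(J[, 1], rep(0, 7))
  # diagonal entries are (2 pi r / 100)^4 for the orthonormal trig pairs
  for (r in 1:3) {
    om4 <- (2 * pi * r / 100)^4
    expect_equal(J[2 * r, 2 * r], om4, tolerance = 1e-8 * om4)
    expect_equal(J[2 * r + 1, 2 * r + 1], om4, tolerance = 1e-8 * om4)
  }
})

test_that("ODE penalty matrix is PSD for random coefficient vectors", {
  bs <- fourier_basis(7)
  with_test_seed(21, {
    for (rep in 1:100) {
      h <- stats::rnorm(14, sd = 0.05)
      J <- ode_penalty_matrix(bs, ode_coefficients(h[1:7], h[8:14], bs))
      expect_gt(min(eigen(J, symmetric = TRUE,
                          only.values = TRUE)$values), -1e-10)
    }
  })
})

test_that("penalty quadratic form equals the integrated squared operator", {
  # lambda * C' J C must equal lambda * int L(xhat)^2 dt (identity used by
  # the smoothing objective)
  bs <- fourier_basis(11)
  curves <- inspan_curves(3, seed = 8)
  with_test_seed(9, {
    h <- stats::rnorm(22, sd = 0.02)
    coeffs <- ode_coefficients(h[1:11], h[12:22], bs)
    fit <- smooth_states(curves, bs, coeffs, lambda = 5)
    w <- eval_coefficients(coeffs, bs$grid)
    for (i in seq_along(curves)) {
      Ci <- fit$C[i, ]
      quad <- drop(t(Ci) %*% ode_penalty_matrix(bs, coeffs) %*% Ci)
      Lx <- drop(bs$Phi2 %*% Ci) + w$w1 * drop(bs$Phi1 %*% Ci) +
        w$w0 * drop(bs$Phi0 %*% Ci)
      expect_equal(quad, sum(bs$weights * Lx^2), tolerance = 1e-8)
    }
  })
})

test_that("unpenalized smoothing reproduces in-span curves exactly", {
  bs <- fourier_basis(11)
  curves <- inspan_curves(2, seed = 3)
  fit <- smooth_states(curves, bs, lambda = 0)
  expect_lt(max(fit$rss), 1e-20)
  xh <- fitted_states(fit, curves[[1]]$t)
  expect_equal(xh[1, ], curves[[1]]$y, tolerance = 1e-10)
  # a pure fundamental sine projects onto a single coefficient
  tt <- seq(0, 100, length.out = 200)
  s <- expression_curve("g", "s", tt, sin(2 * pi * tt / 100))
  C <- smooth_states(list(s), bs, lambda = 0)$C[1, ]
  expect_lt(max(abs(C[-2])), 1e-8)
  expect_gt(abs(C[2]), 1)
})

test_that("lambda -> Inf with h = 0 drives the fit to vanishing curvature", {
  bs <- fourier_basis(11)
  tt <- seq(0, 100, length.out = 150)
  cv <- expression_curve("g", "s", tt, 2 + sin(2 * pi * tt / 100))
  fit <- smooth_states(list(cv), bs, lambda = 1e10)
  # within the Fourier span, zero curvature means a constant: the mean
  xh <- drop(fitted_states(fit, tt))
  expect_lt(max(abs(xh - mean(cv$y))), 1e-3)
})

test_that("smoothing with too few observations and lambda 0 errors", {
  tt <- seq(0, 100, length.out = 5)
  cv <- expression_curve("g", "s", tt, sin(tt / 20))
  expect_error(smooth_states(list(cv), fourier_basis(11), lambda = 0),
               "raise lambda or lower K")
})

test_that("coefficient estimation recovers the operator of in-span families", {
  # sin(wt), cos(wt) both solve x'' + w^2 x = 0
  bs <- fourier_basis(11)
  tt <- seq(0, 100, length.out = 200)
  om <- 2 * pi / 100
  curves <- list(expression_curve("g", "a", tt, sin(om * tt)),
                 expression_curve("g", "b", tt, cos(om * tt)))
  fit <- smooth_states(curves, bs, lambda = 0)
  coeffs <- estimate_coefficients(fit)
  w <- eval_coefficients(coeffs, seq(1, 99, length.out = 99))
  expect_lt(max(abs(w$w0 - om^2)), 1e-3 * om^2)
  expect_lt(max(abs(w$w1)), 1e-3 * om^2)
  expect_error(estimate_coefficients(
    structure(list(C = matrix(0, 2, 11), basis = bs), class = "state_fit")),
    "no signal")
})

test_that("a single constant curve yields the minimum-norm operator w0 = 0", {
  bs <- fourier_basis(11)
  tt <- seq(0, 100, length.out = 120)
  cv <- expression_curve("g", "s", tt, rep(3.5, length(tt)))
  fit <- smooth_states(list(cv), bs, lambda = 0)
  coeffs <- estimate_coefficients(fit)
  expect_true(isTRUE(attr(coeffs, "pseudo_inverse_used")))
  w <- eval_coefficients(coeffs, tt)
  expect_lt(max(abs(w$w0)), 1e-8)
})

test_that("fit_pda converges on noiseless in-span data from a known ODE", {
  curves <- inspan_curves(4, seed = 12)
  pf <- fit_pda(curves, lambda = 1)
  expect_true(pf$diagnostics$converged)
  expect_lte(pf$diagnostics$iterations, 10)
  expect_lt(tail(pf$diagnostics$sse_p, 1), 1e-6)
  om <- 2 * pi / 100
  err <- coeff_rel_err(pf$coeffs, function(t) rep(om^2, length(t)),
                       function(t) rep(0, length(t)))
  expect_lt(err, 0.01)
})

test_that("tol = Inf performs exactly one smooth-then-estimate pass", {
  curves <- inspan_curves(3, seed = 5)
  one <- fit_pda(curves, lambda = 2, tol = Inf)
  expect_equal(one$diagnostics$iterations, 1L)
  fit1 <- smooth_states(curves, one$fit$basis, NULL, lambda = 2)
  ref <- estimate_coefficients(fit1)
  expect_equal(one$coeffs$h0, ref$h0, tolerance = 1e-12)
  expect_equal(one$coeffs$h1, ref$h1, tolerance = 1e-12)
})

test_that("equivariance: adding a constant shifts fits by that constant", {
  bs <- fourier_basis(11)
  curves <- inspan_curves(3, seed = 6)
  shifted <- lapply(curves, function(cv) {
    cv$y <- cv$y + 2.5
    cv
  })
  f0 <- smooth_states(curves, bs, lambda = 0)
  f1 <- smooth_states(shifted, bs, lambda = 0)
  expect_equal(fitted_states(f1, curves[[1]]$t),
               fitted_states(f0, curves[[1]]$t) + 2.5, tolerance = 1e-9)
})

test_that("select_lambda honors contracts and is deterministic", {
  curves <- inspan_curves(6, seed = 14)
  expect_identical(as.numeric(select_lambda(curves, lambda_grid = 3)), 3)
  expect_error(select_lambda(curves, lambda_grid = numeric(0)), "non-empty")
  expect_error(select_lambda(curves[1:3], folds = 5), "folds")
  grid <- c(1e-2, 1e2, 1e6)
  l1 <- suppressWarnings(select_lambda(curves, lambda_grid = grid, seed = 9))
  l2 <- suppressWarnings(select_lambda(curves, lambda_grid = grid, seed = 9))
  expect_identical(as.numeric(l1), as.numeric(l2))
  # noiseless in-span data needs no smoothing: smallest grid value wins
  expect_equal(as.numeric(l1), 1e-2)
})
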