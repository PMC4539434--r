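#' Fourier basis system with analytic derivatives and quadrature
#'
#' Constructs an orthonormal Fourier basis on a closed interval, the
#' workhorse function system used to expand expression curves and the
#' location-varying ODE coefficient functions.  The first basis function is
#' the constant \eqn{1/\sqrt{b-a}}; subsequent functions come in
#' sine/cosine pairs \eqn{\sqrt{2/(b-a)}\sin(2\pi r t'/(b-a))},
#' \eqn{\sqrt{2/(b-a)}\cos(2\pi r t'/(b-a))} with \eqn{t' = t - a}, so the
#' system is orthonormal under the \eqn{L^2} inner product on
#' \eqn{[a, b]}.
#'
#' The basis carries a composite-Simpson quadrature rule on a dense
#' equispaced grid; all integrals in the package (penalty matrices,
#' functional PCA, score features) are evaluated against this rule.
#'
#' @param K odd integer \eqn{\ge 3}; number of basis functions (one
#'   constant plus \code{(K-1)/2} sine/cosine pairs).
#' @param domain numeric length-2, the interval \eqn{[a, b]} (default the
#'   canonical rescaled gene coordinate \code{c(0, 100)}).
#' @param n_quad odd integer, number of quadrature grid points (default
#'   1001; composite Simpson requires an odd count).
#' @return An object of class \code{"fourier_basis"} with elements
#'   \code{K}, \code{domain}, \code{grid} (quadrature abscissae),
#'   \code{weights} (Simpson weights) and cached basis evaluations.
#' @examples
#' bs <- fourier_basis(11)
#' P <- eval_basis(bs, bs$grid)
#' range(crossprod(P, bs$weights * P) - diag(11))  # ~ 1e-12: orthonormal
#' @export
fourier_basis <- function(K, domain = c(0, 100), n_quad = 1001L) {
  if (length(K) != 1L || !is.finite(K) || K != round(K) || K < 3)
    stop("K must be an integer >= 3")
  K <- as.integer(K)
  if (K %% 2L == 0L)
    stop("K must be odd for a Fourier basis (constant + sin/cos pairs); ",
         "got K = ", K)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[2] <= domain[1])
    stop("domain must be an increasing pair (a, b)")
  n_quad <- as.integer(n_quad)
  if (n_quad < 3L || n_quad %% 2L == 0L)
    stop("n_quad must be an odd integer >= 3 (composite Simpson)")
  grid <- seq(domain[1], domain[2], length.out = n_quad)
  h <- (domain[2] - domain[1]) / (n_quad - 1L)
  w <- rep(c(2, 4), length.out = n_quad)
  w[1] <- 1; w[n_quad] <- 1
  w <- w * h / 3
  bs <- structure(
    list(kind = "fourier", K = K, domain = domain,
         grid = grid, weights = w),
    class = "fourier_basis")
  # cache evaluations on the quadrature grid; used by every integral
  bs$Phi0 <- eval_basis(bs, grid, deriv = 0L)
  bs$Phi1 <- eval_basis(bs, grid, deriv = 1L)
  bs$Phi2 <- eval_basis(bs, grid, deriv = 2L)
  bs
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat(sprintf("Fourier basis: K = %d on [%g, %g], %d-point Simpson grid\n",
              x$K, x$domain[1], x$domain[2], length(x$grid)))
  invisible(x)
}

#' Evaluate a basis system (or its derivatives) at arbitrary points
#'
#' Derivatives are analytic, never finite-differenced.
#'
#' @param bs a \code{fourier_basis} object.
#' @param t numeric vector of evaluation points inside the basis domain.
#' @param deriv derivative order: 0, 1 or 2.
#' @return numeric matrix, \code{length(t)} rows by \code{bs$K} columns.
#' @export
eval_basis <- function(bs, t, deriv = 0L) {
  stopifnot(inherits(bs, "fourier_basis"))
  deriv <- as.integer(deriv)
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  a <- bs$domain[1]; b <- bs$domain[2]; L <- b - a
  tol <- 1e-9 * L
  if (any(t < a - tol | t > b + tol))
    stop("evaluation points outside basis domain [", a, ", ", b, "]")
  tp <- t - a
  K <- bs$K
  out <- matrix(0, length(t), K)
  amp <- sqrt(2 / L)
  if (deriv == 0L) out[, 1] <- 1 / sqrt(L)
  npair <- (K - 1L) %/% 2L
  for (r in seq_len(npair)) {
    om <- 2 * pi * r / L
    s <- sin(om * tp); cc <- cos(om * tp)
    j <- 2L * r
    if (deriv == 0L) {
      out[, j]      <- amp * s
      out[, j + 1L] <- amp * cc
    } else if (deriv == 1L) {
      out[, j]      <- amp * om * cc
      out[, j + 1L] <- -amp * om * s
    } else {
      out[, j]      <- -amp * om^2 * s
      out[, j + 1L] <- -amp * om^2 * cc
    }
  }
  out
}

#' Quadrature inner products of function matrices
#'
#' Computes \eqn{\int F^\top(t) G(t)\,dt} by the basis system's composite
#' Simpson rule, for matrices of function values evaluated column-wise on
#' the quadrature grid.  Symmetric and positive semidefinite when
#' \code{F} and \code{G} are the same matrix.
#'
#' @param bs a \code{fourier_basis} object supplying the grid and weights.
#' @param F,G numeric matrices (or vectors) with one row per quadrature
#'   grid point; \code{G} defaults to \code{F}.
#' @return numeric matrix \code{ncol(F)} by \code{ncol(G)}.
#' @examples
#' bs <- fourier_basis(5)
#' inner_product_matrix(bs, bs$grid, rep(1, length(bs$grid)))  # = 5000
#' @export
inner_product_matrix <- function(bs, F, G = F) {
  stopifnot(inherits(bs, "fourier_basis"))
  F <- as.matrix(F); G <- as.matrix(G)
  n <- length(bs$grid)
  if (nrow(F) != n || nrow(G) != n)
    stop("F and G must be evaluated on the basis quadrature grid (",
         n, " rows); got ", nrow(F), " and ", nrow(G))
  M <- crossprod(F, bs$weights * G)
  if (identical(dim(F), dim(G)) && isTRUE(all.equal(F, G)))
    M <- (M + t(M)) / 2
  M
}
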