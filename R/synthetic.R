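#' @title Synthetic expression curves from a known varying-coefficient ODE
#' @name synthetic
#' @description Generates per-base expression curves with exactly the
#'   statistical structure the model assumes: noise-free states solving a
#'   known second-order ODE \eqn{x'' + w_1(t)x' + w_0(t)x = 0} with
#'   random boundary values, observed under additive iid Gaussian
#'   measurement error.  Every downstream stage (PDA fitting, BVP
#'   prediction, FPCA features, classification, the Hotelling response
#'   test) is testable against the known truth without external data.
NULL

#' Default true coefficient functions
#'
#' A smooth, in-span, non-resonant truth on \code{[0, 100]}:
#' \eqn{w_0(t) = (2\pi/100)^2 (1 + 0.5\sin(2\pi t/100))} and
#' \eqn{w_1(t) = 0.01\cos(2\pi t/100)}.
#'
#' @param t positions in \code{[0, 100]}.
#' @return numeric vector of coefficient values.
#' @export
default_w0 <- function(t) (2 * pi / 100)^2 * (1 + 0.5 * sin(2 * pi * t / 100))

#' @rdname default_w0
#' @export
default_w1 <- function(t) 0.01 * cos(2 * pi * t / 100)

#' Specify a simulation
#'
#' Defaults state the world the generator emulates: log-scale expression
#' with O(1) boundary values at both gene ends
#' (\eqn{N(1, 0.3^2)} at each endpoint, independently), 200 observed
#' positions, measurement noise sd 0.1, 20 samples.
#'
#' @param w0,w1 true coefficient functions (vectorized) or scalars.
#' @param bv_mean,bv_sd length-2 numeric: mean and sd of the random
#'   boundary value at the left and right endpoint.
#' @param noise_sd measurement noise standard deviation (\eqn{\ge 0}).
#' @param n_samples samples per call.
#' @param n_positions equispaced observation positions (\eqn{\ge 10}).
#' @param domain curve domain (default \code{c(0, 100)}).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return an object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(w0 = default_w0, w1 = default_w1,
                            bv_mean = c(1, 1), bv_sd = c(0.3, 0.3),
                            noise_sd = 0.1, n_samples = 20,
                            n_positions = 200, domain = c(0, 100),
                            seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_positions < 10) stop("n_positions must be >= 10")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(w0 = w0, w1 = w1, bv_mean = bv_mean, bv_sd = bv_sd,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 n_positions = as.integer(n_positions), domain = domain,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate expression curves from a simulation spec
#'
#' Per sample, boundary values are drawn, the true ODE is solved as a
#' two-point BVP (by superposition of the two boundary basis solutions,
#' exact for this linear homogeneous equation), the state is read off at
#' \code{n_positions} equispaced points, and iid Gaussian noise is added.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param group optional group label attached to every curve.
#' @param gene_id gene identifier for the curves (default
#'   \code{"synthetic"}).
#' @return list with \code{curves} (list of \code{expression_curve}s),
#'   \code{truth} (noise-free state matrix, samples in rows), \code{t}
#'   (observation grid), \code{boundary_values} and \code{spec}.
#' @export
generate_curves <- function(spec, group = NA_character_,
                            gene_id = "synthetic") {
  stopifnot(inherits(spec, "simulation_spec"))
  a <- spec$domain[1]; b <- spec$domain[2]
  t_obs <- seq(a, b, length.out = spec$n_positions)
  cfs <- list(w0 = spec$w0, w1 = spec$w1)
  # boundary basis solutions; superposition is exact for the homogeneous
  # linear ODE, so each sample costs only a linear combination
  u_left <- solve_ode_bvp(cfs, boundary_conditions(a, b, 1, 0),
                          grid = t_obs)$x
  u_right <- solve_ode_bvp(cfs, boundary_conditions(a, b, 0, 1),
                           grid = t_obs)$x
  n <- spec$n_samples
  sim <- with_seed(spec$seed, {
    bv <- cbind(stats::rnorm(n, spec$bv_mean[1], spec$bv_sd[1]),
                stats::rnorm(n, spec$bv_mean[2], spec$bv_sd[2]))
    noise <- matrix(stats::rnorm(n * length(t_obs), 0, spec$noise_sd),
                    n, length(t_obs))
    list(bv = bv, noise = noise)
  })
  truth <- sim$bv[, 1] %o% u_left + sim$bv[, 2] %o% u_right
  obs <- truth + sim$noise
  ids <- sprintf("s%03d", seq_len(n))
  curves <- lapply(seq_len(n), function(i)
    new_expression_curve(gene_id, ids[i], t_obs, obs[i, ], group = group))
  list(curves = curves, truth = truth, t = t_obs,
       boundary_values = sim$bv, spec = spec)
}

#' Generate labeled two-group curves
#'
#' Group 1 follows \code{spec_base}; group 2 follows the same spec with
#' the coefficient functions shifted by \code{delta} (functions or
#' scalars added to \eqn{w_0} and \eqn{w_1}).  \code{delta = 0} yields an
#' exchangeable null for test calibration.  The two groups use seeds
#' derived deterministically from the base seed.
#'
#' @param spec_base a \code{\link{simulation_spec}} for group 1.
#' @param delta list with elements \code{w0} and/or \code{w1}
#'   (vectorized functions or scalars) added to the group-2 coefficient
#'   functions; default: constant \code{+0.5 * (2*pi/100)^2} on
#'   \eqn{w_0}, roughly a 22 percent oscillation-frequency shift.
#' @param labels length-2 character group labels.
#' @param gene_id gene identifier.
#' @return list with \code{curves} (group-labeled, group 1 first),
#'   \code{truth}, \code{t}, \code{groups} and the two specs.
#' @export
generate_two_group <- function(spec_base,
                               delta = list(w0 = 0.5 * (2 * pi / 100)^2,
                                            w1 = 0),
                               labels = c("normal", "tumor"),
                               gene_id = "synthetic") {
  stopifnot(inherits(spec_base, "simulation_spec"))
  add_fun <- function(f, d) {
    if (is.null(d)) return(f)
    if (is.numeric(d)) { dv <- d; d <- function(t) rep(dv, length(t)) }
    base_f <- if (is.numeric(f)) { fv <- f; function(t) rep(fv, length(t)) } else f
    function(t) base_f(t) + d(t)
  }
  spec2 <- spec_base
  spec2$w0 <- add_fun(spec_base$w0, delta$w0)
  spec2$w1 <- add_fun(spec_base$w1, delta$w1)
  spec2$seed <- spec_base$seed + 1000L
  g1 <- generate_curves(spec_base, group = labels[1], gene_id = gene_id)
  g2 <- generate_curves(spec2, group = labels[2], gene_id = gene_id)
  # distinct sample ids across groups
  for (i in seq_along(g2$curves))
    g2$curves[[i]]$sample_id <- sprintf("s%03d", spec_base$n_samples + i)
  list(curves = c(g1$curves, g2$curves),
       truth = rbind(g1$truth, g2$truth),
       t = g1$t,
       groups = rep(labels, times = c(length(g1$curves), length(g2$curves))),
       spec_group1 = spec_base, spec_group2 = spec2)
}
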