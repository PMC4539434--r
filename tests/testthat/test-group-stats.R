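test_that("identical group score sets give T2 = 0, p = 1", {
  tt <- seq(0, 100, length.out = 101)
  R <- with_test_seed(1, matrix(stats::rnorm(10 * 101), 10)) +
    matrix(sin(tt / 9), 10, 101, byrow = TRUE)
  ht <- hotelling_response_test(R, R, k = 2, t = tt)
  expect_equal(ht$statistic, 0, tolerance = 1e-16)
  expect_equal(ht$p_value, 1)
})

test_that("k = 1 Hotelling equals the squared pooled two-sample t", {
  tt <- seq(0, 100, length.out = 101)
  mk <- function(seed, shift)
    with_test_seed(seed, matrix(stats::rnorm(12 * 101, sd = 0.3), 12)) +
      matrix(sin(2 * pi * tt / 100) * shift, 12, 101, byrow = TRUE)
  R1 <- mk(2, 1); R2 <- mk(3, 1.4)
  ht <- hotelling_response_test(R1, R2, k = 1, t = tt)
  m <- fit_fpca(rbind(R1, R2), tt, K_pc = 1)
  z <- drop(project_scores(m, rbind(R1, R2)))
  tstat <- stats::t.test(z[1:12], z[13:24], var.equal = TRUE)$statistic
  expect_equal(ht$statistic, unname(tstat^2), tolerance = 1e-10)
})

test_that("T2 is invariant under invertible linear score reparameterization", {
  # affine invariance of the Mahalanobis form, checked on raw score sets
  with_test_seed(4, {
    xi <- matrix(stats::rnorm(15 * 3), 15)
    eta <- matrix(stats::rnorm(18 * 3, mean = 0.4), 18)
    A <- matrix(stats::rnorm(9), 3)
    while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(9), 3)
    t2 <- function(x, e) {
      d <- colMeans(x) - colMeans(e)
      S <- (crossprod(sweep(x, 2, colMeans(x))) +
              crossprod(sweep(e, 2, colMeans(e)))) / (nrow(x) + nrow(e) - 2)
      drop(crossprod(d, solve((1 / nrow(x) + 1 / nrow(e)) * S, d)))
    }
    expect_equal(t2(xi %*% A, eta %*% A), t2(xi, eta), tolerance = 1e-8)
  })
})

test_that("singular pooled covariance falls back to a flagged pseudo-inverse", {
  tt <- seq(0, 100, length.out = 101)
  # rank-deficient scores: both groups vary along a single function
  g <- sin(2 * pi * tt / 100)
  R1 <- with_test_seed(5, stats::rnorm(6)) %o% g
  R2 <- with_test_seed(6, stats::rnorm(6) + 1) %o% g
  expect_warning(ht <- hotelling_response_test(R1, R2, k = 3, t = tt),
                 "inflate the false positive")
  expect_true(ht$pseudo_inverse_used)
  expect_gte(ht$statistic, 0)
})

test_that("Hotelling power increases with the group separation", {
  tt <- seq(0, 100, length.out = 101)
  base <- sin(2 * pi * tt / 100)
  bump <- cos(2 * pi * tt / 100)
  # 60 reps per effect size (scaled down from larger Monte-Carlo runs to
  # fit the test budget; the 3-point monotonicity is stable at this size)
  rej <- vapply(c(0, 0.08, 0.2), function(delta) {
    with_test_seed(40 + round(100 * delta), {
      mean(replicate(60, {
        R1 <- matrix(base, 12, 101, byrow = TRUE) +
          matrix(stats::rnorm(12 * 101, sd = 0.25), 12)
        R2 <- matrix(base + delta * bump, 12, 101, byrow = TRUE) +
          matrix(stats::rnorm(12 * 101, sd = 0.25), 12)
        hotelling_response_test(R1, R2, k = 3, t = tt)$p_value < 0.05
      }))
    })
  }, 0)
  expect_true(all(diff(rej) >= 0))
  expect_gt(rej[3], rej[1])
})

test_that("lasso path is sparse, monotone in lambda, and KKT-consistent", {
  with_test_seed(7, {
    X <- matrix(stats::rnorm(80 * 8), 80)
    y <- stats::rbinom(80, 1, stats::plogis(X[, 1] - 0.7 * X[, 4]))
  })
  grid <- c(0, 0.5, 1, 2, 4, 8, 16, 1e4)
  nnz <- vapply(grid, function(l) {
    m <- lasso_logistic_fit(X, y, lambda = l)
    Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
    pi_hat <- stats::plogis(m$intercept_std + drop(Xs %*% m$beta_std))
    g <- drop(crossprod(Xs, y - pi_hat))
    zero <- m$beta_std == 0
    if (any(zero)) expect_lt(max(abs(g[zero])) - l, 1e-6)
    if (any(!zero))
      expect_lt(max(abs(g[!zero] - l * sign(m$beta_std[!zero]))), 1e-6)
    sum(!zero)
  }, 0)
  expect_true(all(diff(nnz) <= 0))
  # large-lambda null model is exact
  mL <- lasso_logistic_fit(X, y, lambda = 1e4)
  expect_equal(mL$beta, rep(0, 8))
  expect_equal(mL$intercept, stats::qlogis(mean(y)), tolerance = 1e-10)
})

test_that("lambda = 0 matches the unpenalized Newton-Raphson solution", {
  with_test_seed(8, {
    X <- matrix(stats::rnorm(60 * 4), 60)
    y <- stats::rbinom(60, 1, stats::plogis(0.3 + 0.8 * X[, 2]))
  })
  m <- lasso_logistic_fit(X, y, lambda = 0)
  ref <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
  expect_equal(c(m$intercept, m$beta), unname(ref$coefficients),
               tolerance = 1e-5)
  expect_error(lasso_logistic_fit(X, rep(1, 60), 0), "single class")
})

test_that("classification metrics follow their definitions", {
  # deterministic fabricated confusion: perfect classifier
  with_test_seed(9, {
    Z <- cbind(c(stats::rnorm(20, -3), stats::rnorm(20, 3)), stats::rnorm(40))
  })
  y <- rep(c("normal", "tumor"), each = 20)
  rep_ <- classify_cv(Z, factor(y), k_folds = 5, lambda_grid = 0.5, seed = 2)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$counts), c(20, 0, 20, 0))
  # sensitivity granularity: counts over 72 positives
  expect_equal(65 / 72, 0.903, tolerance = 5e-4)
})

test_that("label-independent features classify at chance level", {
  # 60 permutations (scaled down from the larger nominal run to fit the
  # test budget; the chance-level band is comfortably wide)
  with_test_seed(10, {
    Z <- matrix(stats::rnorm(40 * 4), 40)
    acc <- replicate(60, {
      y <- sample(rep(0:1, each = 20))
      classify_cv(Z, y, k_folds = 4, lambda_grid = c(0.5, 2),
                  seed = sample.int(1e6, 1))$accuracy
    })
  })
  expect_gt(mean(acc), 0.4)
  expect_lt(mean(acc), 0.6)
})

test_that("hierarchical clustering separates blobs and keeps contracts", {
  with_test_seed(11, {
    Z <- rbind(matrix(stats::rnorm(20 * 2, mean = 0), 20),
               matrix(stats::rnorm(20 * 2, mean = 8), 20))
  })
  rownames(Z) <- paste0("g", 1:40)
  cl <- cluster_features(Z, "euclidean", n_groups = 2)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:40])), 1)
  expect_false(cl$labels[1] == cl$labels[40])
  expect_match(cl$newick, "^\\(")
  # n_groups = n puts every item in its own cluster
  cl_n <- cluster_features(Z[1:6, ], "euclidean", n_groups = 6)
  expect_equal(sort(unname(cl_n$labels)), 1:6)
  # duplicating rows leaves the cut partition intact (pairs co-cluster)
  Zd <- rbind(Z, Z)
  cld <- cluster_features(Zd, "euclidean", n_groups = 2)
  expect_equal(unname(cld$labels[1:40]), unname(cld$labels[41:80]))
  # correlation metric refuses constant rows, naming them
  Zc <- Z; Zc[3, ] <- 5
  expect_error(cluster_features(Zc, "correlation", n_groups = 2), "g3")
  expect_error(cluster_features(Z[1:3, ], n_groups = 5), "fewer items")
})
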