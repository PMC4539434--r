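#' @title Group-difference testing, classification and clustering
#' @name group-stats
#' @description Hotelling T-squared test on FPCA scores of unit-step
#'   response curves, L1-penalized logistic regression (IRLS + coordinate
#'   descent) with cross-validated classification metrics, and
#'   hierarchical clustering of score features with Newick export.
NULL

# generalized (Moore-Penrose) inverse via SVD
ginv_svd <- function(A) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Hotelling T-squared test on response-curve FPCA scores
#'
#' Both groups' response curves are expanded in a common set of
#' eigenfunctions fitted to the pooled collection; the first \code{k}
#' scores per sample feed a two-sample Hotelling statistic
#' \eqn{T^2 = (\bar\xi - \bar\eta)^\top \Lambda^{-1} (\bar\xi - \bar\eta)}
#' with pooled covariance \eqn{S} and
#' \eqn{\Lambda = (1/N_1 + 1/N_2) S}, referred to a \eqn{\chi^2_k} null
#' (optionally the finite-sample F law).
#'
#' @param responses_group1,responses_group2 numeric matrices of response
#'   curves on a common grid, one sample per row.
#' @param k number of leading FPCA components to test (default 3).
#' @param t the common grid (default: equispaced on \code{[0, 100]}).
#' @param use_f if \code{TRUE}, use the finite-sample Hotelling F
#'   reference instead of the \eqn{\chi^2_k} default.
#' @return object of class \code{"hotelling_result"}: \code{statistic},
#'   \code{k}, \code{p_value}, group mean score vectors \code{xi_bar}
#'   and \code{eta_bar}, pooled covariance \code{S}, \code{Lambda},
#'   and \code{pseudo_inverse_used}.
#' @export
hotelling_response_test <- function(responses_group1, responses_group2,
                                    k = 3, t = NULL, use_f = FALSE) {
  R1 <- as.matrix(responses_group1); R2 <- as.matrix(responses_group2)
  N1 <- nrow(R1); N2 <- nrow(R2)
  if (N1 < 2 || N2 < 2) stop("each group needs at least 2 response curves")
  if (ncol(R1) != ncol(R2)) stop("response grids differ between groups")
  if (is.null(t)) t <- seq(0, 100, length.out = ncol(R1))
  model <- fit_fpca(rbind(R1, R2), t, K_pc = k)
  Zs <- project_scores(model, rbind(R1, R2))
  xi <- Zs[seq_len(N1), , drop = FALSE]
  eta <- Zs[N1 + seq_len(N2), , drop = FALSE]
  xi_bar <- colMeans(xi); eta_bar <- colMeans(eta)
  S <- (crossprod(sweep(xi, 2, xi_bar)) +
        crossprod(sweep(eta, 2, eta_bar))) / (N1 + N2 - 2)
  Lambda <- (1 / N1 + 1 / N2) * S
  d <- xi_bar - eta_bar
  pseudo <- FALSE
  Tsq <- tryCatch({
    if (rcond(Lambda) < 1e-12) stop("singular")
    drop(crossprod(d, solve(Lambda, d)))
  }, error = function(e) {
    pseudo <<- TRUE
    warning("Lambda is singular; generalized inverse used -- ",
            "this will inflate the false positive rates")
    drop(crossprod(d, ginv_svd(Lambda) %*% d))
  })
  Tsq <- max(Tsq, 0)
  m <- N1 + N2 - 2
  p <- if (use_f) {
    fstat <- Tsq * (m - k + 1) / (k * m)
    stats::pf(fstat, k, m - k + 1, lower.tail = FALSE)
  } else stats::pchisq(Tsq, df = k, lower.tail = FALSE)
  structure(list(statistic = Tsq, k = k, p_value = p,
                 xi_bar = xi_bar, eta_bar = eta_bar, S = S,
                 Lambda = Lambda, pseudo_inverse_used = pseudo,
                 reference = if (use_f) "hotelling_f" else "chisq",
                 fpca = model),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Hotelling T^2 = %.4g on k = %d components; p = %.4g (%s null)%s\n",
              x$statistic, x$k, x$p_value, x$reference,
              if (x$pseudo_inverse_used) " [pseudo-inverse]" else ""))
  invisible(x)
}

#' L1-penalized logistic regression
#'
#' Maximizes the penalized log-likelihood
#' \eqn{\sum_i [y_i(\beta_0 + x_i^\top\beta) - \log(1 + e^{\beta_0 +
#' x_i^\top\beta})] - \lambda \|\beta\|_1} (intercept unpenalized,
#' covariates standardized internally) by iteratively reweighted least
#' squares with an inner coordinate-descent loop and soft-thresholding.
#' At convergence the solution satisfies the subgradient conditions
#' \eqn{|x_j^\top(y - \pi)| \le \lambda} for zero coefficients and
#' \eqn{x_j^\top(y - \pi) = \lambda\,\mathrm{sign}(\beta_j)} for active
#' ones (in standardized coordinates).
#'
#' @param Z numeric feature matrix (samples in rows).
#' @param y binary response (0/1, logical, or 2-level factor; the second
#'   level is the positive class).
#' @param lambda penalty weight \eqn{\lambda \ge 0} on the scale of the
#'   unscaled log-likelihood.
#' @param standardize center and scale columns before fitting (default
#'   TRUE; coefficients are returned on both scales).
#' @param max_iter,tol outer-loop iteration cap and coefficient-change
#'   tolerance.
#' @return object of class \code{"classifier_model"}: intercept and
#'   coefficients on the original scale, standardized coefficients,
#'   standardization parameters, \code{lambda}, convergence info.
#' @export
lasso_logistic_fit <- function(Z, y, lambda = 0, standardize = TRUE,
                               max_iter = 500, tol = 1e-10) {
  Z <- as.matrix(Z)
  y <- encode_binary(y)$y
  if (length(unique(y)) < 2) stop("response has a single class")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(Z); p <- ncol(Z)
  if (standardize) {
    ctr <- colMeans(Z)
    scl <- apply(Z, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  X <- sweep(sweep(Z, 2, ctr), 2, scl, "/")
  b0 <- stats::qlogis(mean(y))
  beta <- numeric(p)
  xsq <- colSums(X^2)
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(b0 + X %*% beta)
    pi_hat <- stats::plogis(eta)
    w <- pmax(pi_hat * (1 - pi_hat), 1e-6)
    z <- eta + (y - pi_hat) / w
    b_old <- c(b0, beta)
    # coordinate descent on the weighted quadratic approximation
    for (inner in seq_len(200)) {
      b_in <- c(b0, beta)
      r <- z - b0 - drop(X %*% beta)
      b0 <- b0 + sum(w * r) / sum(w)
      r <- r - (b0 - b_in[1])
      for (j in seq_len(p)) {
        r <- r + X[, j] * beta[j]
        g <- sum(w * X[, j] * r)
        beta[j] <- soft_threshold(g, lambda) / sum(w * X[, j]^2)
        r <- r - X[, j] * beta[j]
      }
      if (max(abs(c(b0, beta) - b_in)) < tol) break
    }
    if (max(abs(c(b0, beta) - b_old)) < tol) break
    if (max(abs(drop(b0 + X %*% beta))) > 30 && lambda == 0) {
      separated <- TRUE
      warning("near-complete separation at lambda = 0; ",
              "coefficients capped by iteration limit")
      break
    }
  }
  beta_orig <- beta / scl
  structure(list(intercept = b0 - sum(beta * ctr / scl),
                 beta = beta_orig,
                 intercept_std = b0, beta_std = beta,
                 center = ctr, scale = scl, lambda = lambda,
                 iterations = it, separated = separated),
            class = "classifier_model")
}

soft_threshold <- function(g, lambda) sign(g) * max(abs(g) - lambda, 0)

encode_binary <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) > 2) stop("response must be binary")
    list(y = as.numeric(as.character(y) == lev[length(lev)]),
         positive = lev[length(lev)])
  } else {
    yv <- as.numeric(y)
    if (!all(yv %in% c(0, 1))) stop("numeric response must be 0/1")
    list(y = yv, positive = "1")
  }
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("lasso logistic model: lambda = %g, %d/%d nonzero coefficients\n",
              x$lambda, sum(x$beta_std != 0), length(x$beta_std)))
  invisible(x)
}

#' @param object a \code{classifier_model}.
#' @param newdata feature matrix.
#' @param type \code{"response"} (probabilities) or \code{"class"}
#'   (0/1 at threshold 0.5).
#' @param ... unused.
#' @rdname lasso_logistic_fit
#' @export
predict.classifier_model <- function(object, newdata, type = "response", ...) {
  eta <- drop(object$intercept + as.matrix(newdata) %*% object$beta)
  pr <- stats::plogis(eta)
  if (identical(type, "class")) as.numeric(pr > 0.5) else pr
}

#' Cross-validated classification metrics
#'
#' Stratified outer k-fold cross-validation of the lasso logistic
#' classifier; within each training fold, \eqn{\lambda} is chosen by an
#' inner stratified CV minimizing held-out binomial deviance.  Test
#' predictions at the 0.5 probability threshold are aggregated into a
#' confusion table.  Sensitivity is the fraction of positive (e.g.
#' tumor) samples classified positive; specificity the fraction of
#' negative (normal) samples classified negative; accuracy the overall
#' fraction correct.
#'
#' @param Z feature matrix.
#' @param y binary labels (second factor level / value 1 = positive).
#' @param k_folds outer folds (default 5).
#' @param lambda_grid candidate penalties for the inner CV.
#' @param seed integer seed (fold assignments).
#' @return object of class \code{"classification_report"}: sensitivity,
#'   specificity, accuracy, confusion counts (TP, FP, TN, FN), per-fold
#'   chosen \eqn{\lambda}.
#' @export
classify_cv <- function(Z, y, k_folds = 5,
                        lambda_grid = c(0.1, 0.5, 1, 2, 5, 10), seed = 1) {
  Z <- as.matrix(Z)
  enc <- encode_binary(y)
  yv <- enc$y
  fold_id <- stratified_folds(yv, k_folds, seed)
  tp <- fp <- tn <- fn <- 0
  lam_used <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold_id != f
    lam <- if (length(lambda_grid) > 1) {
      inner <- stratified_folds(yv[tr], min(k_folds, min(table(yv[tr]))),
                                seed + 1000 + f)
      dev <- vapply(lambda_grid, function(l) {
        sum(vapply(unique(inner), function(g) {
          m <- lasso_logistic_fit(Z[tr, , drop = FALSE][inner != g, ,
                                                        drop = FALSE],
                                  yv[tr][inner != g], lambda = l)
          pr <- predict(m, Z[tr, , drop = FALSE][inner == g, , drop = FALSE])
          pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
          -2 * sum(yv[tr][inner == g] * log(pr) +
                     (1 - yv[tr][inner == g]) * log(1 - pr))
        }, 0))
      }, 0)
      lambda_grid[which.min(dev)]
    } else lambda_grid
    lam_used[f] <- lam
    m <- lasso_logistic_fit(Z[tr, , drop = FALSE], yv[tr], lambda = lam)
    pred <- predict(m, Z[!tr, , drop = FALSE], type = "class")
    truth <- yv[!tr]
    tp <- tp + sum(pred == 1 & truth == 1)
    fp <- fp + sum(pred == 1 & truth == 0)
    tn <- tn + sum(pred == 0 & truth == 0)
    fn <- fn + sum(pred == 0 & truth == 1)
  }
  structure(list(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 lambda_per_fold = lam_used,
                 positive_class = enc$positive),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification (positive = %s): sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$positive_class, x$sensitivity, x$specificity, x$accuracy))
  print(x$counts)
  invisible(x)
}

#' Hierarchical clustering of score features
#'
#' Agglomerative clustering of feature-matrix rows under Euclidean or
#' correlation (\eqn{1 - r}) distance, cut into a requested number of
#' groups, with the dendrogram exportable as a Newick string.
#'
#' @param Z feature matrix (rows = items, e.g. genes; row names used as
#'   labels).
#' @param metric \code{"euclidean"} or \code{"correlation"}.
#' @param linkage agglomeration method for \code{\link[stats]{hclust}}
#'   (default \code{"average"}).
#' @param n_groups number of clusters to cut the tree into.
#' @return list with \code{labels} (named integer cluster ids),
#'   \code{hclust} (the tree) and \code{newick} (character).
#' @export
cluster_features <- function(Z, metric = c("euclidean", "correlation"),
                             linkage = "average", n_groups) {
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  if (nrow(Z) < n_groups)
    stop("fewer items (", nrow(Z), ") than requested groups (", n_groups, ")")
  if (is.null(rownames(Z))) rownames(Z) <- paste0("item", seq_len(nrow(Z)))
  if (metric == "euclidean") {
    d <- stats::dist(Z)
  } else {
    sds <- apply(Z, 1, stats::sd)
    if (any(sds == 0))
      stop("constant feature row(s) under correlation metric: ",
           paste(rownames(Z)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(Z)))
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = n_groups)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(labels = labels, hclust = hc, newick = nwk)
}
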