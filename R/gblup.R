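# GBLUP: spectral (eigen-decomposition) profile REML for the model
#   y = 1 mu + u + e,  u ~ N(0, s2u K),  e ~ N(0, s2e I),
# genomic heritability, prediction into unobserved individuals, and the
# k-fold cross-validation accuracy scheme.

# Restricted log-likelihood evaluated through an eigendecomposition of K.
# Standard REML convention: -0.5 [ log|V| + log|X'V^-1 X| + r'V^-1 r
#                                  + (n - 1) log 2pi ]  with X = 1.
reml_loglik_eigen <- function(eK, yt, xt, s2u, s2e) {
  w <- s2u * eK$values + s2e
  if (any(w <= 0)) return(-Inf)
  xvx <- sum(xt^2 / w)
  beta <- sum(xt * yt / w) / xvx
  rt <- yt - xt * beta
  -0.5 * (sum(log(w)) + log(xvx) + sum(rt^2 / w) +
          (length(yt) - 1) * log(2 * pi))
}

# Profile REML over delta = s2e / s2u on the eigenbasis of K.
# Returns components, intercept, BLUPs and the restricted log-likelihood.
reml_profile <- function(y, eK, log_delta_bounds = c(-10, 10), tol = 1e-8) {
  n <- length(y)
  U <- eK$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  prof <- function(ld) {
    delta <- exp(ld)
    w0 <- eK$values + delta
    xvx <- sum(xt^2 / w0)
    beta <- sum(xt * yt / w0) / xvx
    rt <- yt - xt * beta
    s2u <- sum(rt^2 / w0) / (n - 1)
    if (s2u <= 0) return(list(ll = -Inf, s2u = 0, s2e = 0, beta = beta))
    list(ll = reml_loglik_eigen(eK, yt, xt, s2u, s2u * delta),
         s2u = s2u, s2e = s2u * delta, beta = beta)
  }
  opt <- optimize(function(ld) -prof(ld)$ll, interval = log_delta_bounds,
                  tol = tol)
  # guard the interval ends: optimize() can miss a boundary optimum
  cand <- c(opt$minimum, log_delta_bounds)
  lls <- vapply(cand, function(ld) prof(ld)$ll, numeric(1))
  best <- cand[which.max(lls)]
  sol <- prof(best)
  w <- sol$s2u * eK$values + sol$s2e
  rt <- yt - xt * sol$beta
  u <- drop(U %*% (sol$s2u * eK$values * rt / w))
  names(u) <- names(y)
  list(mu = sol$beta, s2u = sol$s2u, s2e = sol$s2e, u = u,
       loglik = sol$ll, lambda = exp(best),
       h2 = sol$s2u / (sol$s2u + sol$s2e),
       boundary = best %in% log_delta_bounds)
}

check_kernel <- function(K, tol = 1e-6) {
  K <- unclass(K)
  if (!isSymmetric(K, tol = 1e-8, check.attributes = FALSE))
    stop("kernel matrix must be symmetric")
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -tol * max(abs(eK$values), 1))
    stop("kernel matrix is not positive semi-definite")
  eK$values <- pmax(eK$values, 0)
  eK
}

#' Fit GBLUP by spectral REML
#'
#' Estimates `(s2u, s2e)` of `y = 1 mu + u + e`, `u ~ N(0, s2u K)`, by
#' profiling the restricted likelihood over `lambda = s2e/s2u` on the
#' eigenbasis of `K` (EMMA-style), with `log(lambda)` searched on
#' `[-10, 10]`. Returns BLUPs of `u` and the genomic heritability
#' `h2 = s2u / (s2u + s2e)`, the variance explained by the model.
#'
#' @param y numeric response (typically non-centered family BLUP values).
#' @param K positive semi-definite relationship matrix, `dim = length(y)`.
#' @return object of class `gblup_fit`: `mu`, `s2u`, `s2e`, `h2`, `u`,
#'   `loglik`, `lambda`, plus the data (`y`) for downstream prediction.
#' @export
fit_gblup <- function(y, K) {
  y <- drop(y)
  if (length(y) != nrow(K)) stop("length(y) must equal dim(K)")
  if (is.null(names(y)) && !is.null(rownames(K))) names(y) <- rownames(K)
  eK <- check_kernel(K)
  if (var(y) < 1e-12) {
    warning("constant response: boundary fit with s2u = 0")
    fit <- list(mu = mean(y), s2u = 0, s2e = var(y), u = setNames(rep(0, length(y)), names(y)),
                loglik = NA_real_, lambda = Inf, h2 = 0, boundary = TRUE)
  } else {
    fit <- reml_profile(y, eK)
  }
  fit$y <- y
  fit$n <- length(y)
  class(fit) <- "gblup_fit"
  fit
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit: n =", x$n,
      sprintf("\n  mu = %.4f  s2u = %.4f  s2e = %.4f  h2 = %.3f",
              x$mu, x$s2u, x$s2e, x$h2),
      sprintf("\n  restricted loglik = %.4f\n", x$loglik))
  invisible(x)
}

#' Predict GEBVs for unobserved individuals
#'
#' Conditional-expectation (joint mixed-model-equation) form:
#' `u_test = K[test, train] (K[train, train] + lambda I)^-1 (y - mu)`,
#' with `lambda = s2e/s2u` from the training fit. An individual with a zero
#' kernel row against the training set collapses to the mean (GEBV 0).
#'
#' @param fit a `gblup_fit` (or `mpm_fit`) trained on `train_idx`.
#' @param K_full kernel over training + test individuals. For a mixed
#'   population Matern fit this is the product kernel `H`.
#' @param train_idx,test_idx row indices of `K_full`.
#' @return named numeric vector of predicted GEBVs for `test_idx`.
#' @export
predict_gebv <- function(fit, K_full, train_idx, test_idx) {
  K_full <- unclass(K_full)
  if (length(train_idx) != length(fit$y))
    stop("train_idx must match the fitted response")
  if (fit$s2u <= 0) {
    out <- rep(0, length(test_idx))
    names(out) <- rownames(K_full)[test_idx]
    return(out)
  }
  lambda <- fit$s2e / fit$s2u
  Ktt <- K_full[train_idx, train_idx, drop = FALSE]
  rhs <- fit$y - fit$mu
  alpha <- solve(Ktt + diag(lambda, length(train_idx)), rhs)
  out <- drop(K_full[test_idx, train_idx, drop = FALSE] %*% alpha)
  names(out) <- rownames(K_full)[test_idx]
  out
}

#' k-fold cross-validation of GBLUP accuracy
#'
#' Per replicate, individuals are partitioned uniformly at random into `k`
#' folds of sizes differing by at most one; each fold is predicted from a
#' GBLUP fit on the remaining folds (kernel rows of the full `K`).
#' Replicate accuracy is the Pearson correlation between `y` and the
#' assembled out-of-fold GEBVs. Both the mean per-replicate accuracy and
#' the accuracy of the replicate-averaged GEBVs are reported.
#'
#' @param y response vector.
#' @param K relationship matrix.
#' @param k number of folds (default 5).
#' @param reps number of replicates (default 20).
#' @param seed optional seed for fold assignment.
#' @return object of class `cv_result`: `acc` (per replicate, NA when
#'   predictions are degenerate), `mean_acc`, `acc_avg_gebv`, `pred`
#'   (n x reps), `avg_gebv`, `folds`, `k`, `reps`.
#' @export
cross_validate <- function(y, K, k = 5, reps = 20, seed = NULL) {
  n <- length(y)
  if (n < 2 * k) stop("need n >= 2k")
  if (!is.null(seed)) set.seed(seed)
  K <- unclass(K)
  pred <- matrix(NA_real_, n, reps)
  folds <- vector("list", reps)
  acc <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
    folds[[r]] <- fold
    for (f in seq_len(k)) {
      test <- which(fold == f); train <- which(fold != f)
      fit <- fit_gblup(y[train], K[train, train, drop = FALSE])
      pred[test, r] <- predict_gebv(fit, K, train, test)
    }
    if (sd(pred[, r]) > 1e-12) acc[r] <- cor(y, pred[, r])
  }
  avg <- rowMeans(pred)
  structure(list(
    acc = acc, mean_acc = mean(acc, na.rm = TRUE),
    acc_avg_gebv = if (sd(avg) > 1e-12) cor(y, avg) else NA_real_,
    pred = pred, avg_gebv = avg, folds = folds, k = k, reps = reps
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d reps: mean accuracy %.3f (averaged-GEBV %.3f)\n",
              x$k, x$reps, x$mean_acc, x$acc_avg_gebv))
  invisible(x)
}
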