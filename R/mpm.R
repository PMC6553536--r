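# Mixed-population Matern model (GBLUP-MPM): a Matern kernel over
# marker-derived principal-component distances, combined elementwise with
# the genomic relationship, with (v, h) estimated by constrained REML.
# Following the source parameterization the two Matern parameters are
# called v and h; their standard roles are v = smoothness, h = range.

#' Matern kernel on a distance matrix
#'
#' `K(d) = (2^(1-v) / Gamma(v)) (sqrt(2v) d / h)^v BesselK_v(sqrt(2v) d / h)`
#' with `K(0) = 1`. Computed in log space with exponent-scaled Bessel
#' functions; where the Bessel term overflows (very large `v`) the Gaussian
#' limit `exp(-d^2 / (2 h^2))` is used, which the kernel approaches as
#' `v -> Inf`. `v = 0.5` gives the exponential kernel `exp(-d/h)`.
#'
#' @param D symmetric matrix (or vector) of non-negative distances.
#' @param v smoothness parameter (> 0).
#' @param h range parameter (> 0).
#' @return matrix (or vector) of kernel values in `(0, 1]`.
#' @export
matern_kernel <- function(D, v, h) {
  if (v <= 0 || h <= 0) stop("v and h must be positive")
  if (any(!is.finite(D)) || any(D < 0)) stop("distances must be finite and >= 0")
  x <- sqrt(2 * v) * D / h
  out <- D
  tiny <- x < 1e-8
  out[tiny] <- 1
  if (any(!tiny)) {
    xs <- x[!tiny]
    bk <- besselK(xs, v, expon.scaled = TRUE)
    logk <- (1 - v) * log(2) - lgamma(v) + v * log(xs) + log(bk) - xs
    val <- exp(logk)
    bad <- !is.finite(val)
    if (any(bad)) val[bad] <- exp(-(D[!tiny][bad])^2 / (2 * h^2))
    out[!tiny] <- val
  }
  out
}

#' Elementwise product kernel
#'
#' `H = Omega o G`. By the Schur product theorem H is positive
#' semi-definite whenever both factors are.
#'
#' @param Omega population-differentiation kernel (diagonal 1).
#' @param G genomic relationship matrix.
#' @return `kernel_matrix` of kind `"product"`.
#' @export
build_product_kernel <- function(Omega, G) {
  Omega <- unclass(Omega); G <- unclass(G)
  if (!all(dim(Omega) == dim(G))) stop("Omega and G must be conformable")
  new_kernel(Omega * G, rownames(G), "product")
}

#' Choose the number of principal components
#'
#' Default rule: the number of leading components each explaining more than
#' `threshold` of the variance (at least 1).
#'
#' @param var_explained vector of variance-explained fractions (or a
#'   `pc_scores` object).
#' @param threshold variance-explained cutoff, default 0.05.
#' @return integer `d >= 1`.
#' @export
choose_num_pcs <- function(var_explained, threshold = 0.05) {
  if (inherits(var_explained, "pc_scores"))
    var_explained <- var_explained$var_explained
  above <- var_explained > threshold
  d <- if (all(above)) length(above) else which.min(above) - 1L
  max(1L, as.integer(d))
}

#' Fit the mixed-population Matern model
#'
#' Outer bounded quasi-Newton optimization of the restricted likelihood
#' over `(v, h)` on the log scale (box `v` in `[0.05, 50]`, `h` in
#' `[1e-3, 1e3]`, start `(0.5, 0.5)`), with inner spectral REML for
#' `(s2u, s2e)` given the product kernel `H(v, h) = Omega(v, h) o G`.
#' `Omega` is the Matern kernel on Euclidean distances between
#' standardized principal-component scores (computed on the combined
#' calibration + validation genotypes). Additional deterministic restarts
#' are tried whenever the first run fails to reach the plain-GBLUP
#' likelihood, which is the nested `h -> Inf` limit (`Omega -> 1`); when
#' the restricted likelihood is maximized at that population-homogeneous
#' boundary the fit reduces to GBLUP exactly and `h` is reported as `Inf`.
#'
#' @param y response vector over the training individuals.
#' @param G genomic relationship matrix; may cover training plus
#'   to-be-predicted individuals (see `train_idx`).
#' @param pcs a `pc_scores` object from [pca_genotypes()] on the same
#'   individuals as `G` — for independent validation, computed on the
#'   combined calibration + validation genotypes.
#' @param train_idx rows of `G`/`pcs` carrying the response; default all.
#'   The PC geometry (standardization, distances) always uses every row so
#'   that held-out individuals live in the same coordinate system.
#' @param d number of components for the population-distance geometry;
#'   default [choose_num_pcs()] on `pcs`.
#' @param v0,h0 starting values, default (0.5, 0.5).
#' @param v_bounds,h_bounds box constraints.
#' @return object of class `mpm_fit` (extends `gblup_fit`): adds `v`, `h`,
#'   `Omega` and `H` (over all rows of `G`), `loglik_gblup`, `d`,
#'   `train_idx`. Predict held-out GEBVs with
#'   `predict_gebv(fit, fit$H, fit$train_idx, test_idx)`.
#' @export
fit_mpm <- function(y, G, pcs, train_idx = NULL, d = NULL, v0 = 0.5,
                    h0 = 0.5, v_bounds = c(0.05, 50), h_bounds = c(1e-3, 1e3)) {
  stopifnot(inherits(pcs, "pc_scores"))
  G <- unclass(G)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(G))
  if (length(y) != length(train_idx))
    stop("length(y) must equal length(train_idx)")
  if (is.null(d)) d <- choose_num_pcs(pcs)
  S <- pcs$scores[, seq_len(d), drop = FALSE]
  if (nrow(S) != nrow(G)) stop("pcs and G must cover the same individuals")
  sds <- apply(S, 2, sd)
  if (all(sds < 1e-12)) {
    warning("degenerate PC geometry (all distances 0): model reduces to GBLUP")
    D <- matrix(0, nrow(S), nrow(S))
  } else {
    S <- sweep(sweep(S, 2, colMeans(S)), 2, pmax(sds, 1e-12), "/")
    D <- as.matrix(dist(S))
  }
  Dtt <- D[train_idx, train_idx, drop = FALSE]
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  gfit <- fit_gblup(y, Gtt)
  gll <- if (is.finite(gfit$loglik)) gfit$loglik else -Inf
  obj <- function(par) {
    Om <- matern_kernel(Dtt, exp(par[1]), exp(par[2]))
    H <- Om * Gtt
    eH <- tryCatch(check_kernel(H, tol = 1e-4), error = function(e) NULL)
    if (is.null(eH)) return(1e10)
    -reml_profile(y, eH)$loglik
  }
  lower <- log(c(v_bounds[1], h_bounds[1]))
  upper <- log(c(v_bounds[2], h_bounds[2]))
  starts <- list(c(v0, h0), c(1, 50), c(2 * v0, 10 * h0), c(0.5, 5))
  best <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      optim(log(pmin(pmax(s0, exp(lower)), exp(upper))), obj,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    # stop early once the nested GBLUP limit has been reached or beaten
    if (!is.null(best) && -best$value >= gll - 1e-8) break
  }
  if (is.null(best)) stop("Matern REML optimization failed from every start")
  if (-best$value >= gll) {
    v <- exp(best$par[1]); h <- exp(best$par[2])
    Omega <- matern_kernel(D, v, h)
  } else {
    # the restricted likelihood is maximized at the population-homogeneous
    # boundary of the model family (h -> Inf, Omega -> 1): the fit is GBLUP
    v <- exp(best$par[1]); h <- Inf
    Omega <- matrix(1, nrow(D), ncol(D))
  }
  H <- build_product_kernel(Omega, G)
  fit <- reml_profile(y, check_kernel(unclass(H)[train_idx, train_idx],
                                      tol = 1e-4))
  fit$y <- y; fit$n <- length(y)
  fit$v <- v; fit$h <- h
  fit$Omega <- Omega; fit$H <- H
  fit$loglik_gblup <- gfit$loglik
  fit$d <- d
  fit$train_idx <- train_idx
  class(fit) <- c("mpm_fit", "gblup_fit")
  fit
}

#' @export
print.mpm_fit <- function(x, ...) {
  cat(sprintf("GBLUP-MPM fit: n = %d, d = %d PCs\n  v = %.4g  h = %.4g\n",
              x$n, x$d, x$v, x$h),
      sprintf(" mu = %.4f  s2u = %.4f  s2e = %.4f  h2 = %.3f\n",
              x$mu, x$s2u, x$s2e, x$h2),
      sprintf(" restricted loglik = %.4f (GBLUP: %.4f)\n",
              x$loglik, x$loglik_gblup))
  invisible(x)
}
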