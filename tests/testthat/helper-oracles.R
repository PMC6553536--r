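# Independent oracles and small fixture builders shared across test files.
# These deliberately use naive dense linear algebra (solve, double loops)
# so they share no code path with the package implementations they check.

# dense restricted log-likelihood of y = 1*mu + u + e, u ~ N(0, s2u K),
# e ~ N(0, s2e I); same constant convention as the package (X = 1 column)
dense_reml_loglik <- function(y, K, s2u, s2e) {
  n <- length(y)
  V <- s2u * K + s2e * diag(n)
  Vi <- solve(V)
  one <- rep(1, n)
  xvx <- drop(crossprod(one, Vi %*% one))
  beta <- drop(crossprod(one, Vi %*% y)) / xvx
  r <- y - beta
  q <- drop(crossprod(r, Vi %*% r))
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (ld + log(xvx) + q + (n - 1) * log(2 * pi))
}

# Hudson FST estimator (ratio of averages) between two dosage matrices
hudson_fst <- function(X1, X2) {
  p1 <- colMeans(X1, na.rm = TRUE) / 2
  p2 <- colMeans(X2, na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(X1))
  n2 <- 2 * colSums(!is.na(X2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# random dosage matrix and the VanRaden kernel built from it by brute force
rand_dosage <- function(n, m, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
         dimnames = list(paste0("i", seq_len(n)), paste0("m", seq_len(m))))
}

naive_grm <- function(X) {
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(X); m <- ncol(X)
  W <- X - matrix(2 * p, n, m, byrow = TRUE)
  cc <- 2 * sum(p * (1 - p))
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(W[i, ] * W[j, ]) / cc
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# GBLUP-model data generator: y = 5 + u + e with u ~ N(0, s2u K),
# K the VanRaden kernel of a random dosage matrix
sim_gblup_data <- function(n, m, s2u, s2e, seed) {
  X <- rand_dosage(n, m, seed = seed)
  K <- unclass(grm(X))
  eK <- eigen(K, symmetric = TRUE)
  u <- drop(eK$vectors %*% (sqrt(pmax(eK$values, 0) * s2u) * rnorm(n)))
  y <- 5 + u + rnorm(n, 0, sqrt(s2e))
  names(y) <- rownames(X)
  list(X = X, K = K, y = y, u = u)
}

# simple mean silhouette of a 1-d embedding for a 2-group labelling
silhouette_1d <- function(x, grp) {
  grp <- as.integer(factor(grp))
  s <- vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[grp == grp[i]])
    a <- sum(own) / (length(own) - 1)
    b <- mean(abs(x[i] - x[grp != grp[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
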