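# Genome-wide relatedness summaries: VanRaden genomic relationship matrix,
# identity-by-state, principal components, LD decay and MAF spectra.

new_kernel <- function(K, ids, kind) {
  dimnames(K) <- list(ids, ids)
  attr(K, "kind") <- kind
  class(K) <- c("kernel_matrix", class(K))
  K
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers each marker by twice its in-sample allele frequency and scales
#' the cross-product by `2 * sum(p (1 - p))`:
#' `K = W W' / (2 sum p(1-p))` with `W = X - 2p`. With in-sample
#' frequencies rows and columns sum to ~0. Monomorphic markers contribute
#' nothing and are dropped.
#'
#' @param G imputed [geno_matrix()] or dosage matrix (no missing calls).
#' @return n x n `kernel_matrix` of kind `"GRM"`.
#' @export
grm <- function(G) {
  X <- as_dosage(G)
  if (anyNA(X)) stop("GRM requires an imputed (complete) genotype matrix")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(X, 2, 2 * p)
  cc <- 2 * sum(p * (1 - p))
  new_kernel(tcrossprod(W) / cc, rownames(X), "GRM")
}

#' Identity-by-state matrix
#'
#' Pairwise proportion of shared alleles: per marker the dosage pair
#' contributes 1 when identical, 0.5 when one allele is shared
#' (|di - dj| = 1), 0 for opposite homozygotes; averaged over markers.
#' With missing data, each pair is averaged over its jointly observed
#' markers; a pair with none is an error.
#'
#' @param G [geno_matrix()] or dosage matrix with values 0/1/2 (NA allowed).
#' @return n x n `kernel_matrix` of kind `"IBS"` with entries in `[0, 1]`.
#' @export
ibs <- function(G) {
  X <- as_dosage(G)
  n <- nrow(X); m <- ncol(X)
  if (!anyNA(X) && all(X %in% c(0, 1, 2))) {
    A <- (X == 0) + 0; B <- (X == 1) + 0; C <- (X == 2) + 0
    AB <- tcrossprod(A, B); AC <- tcrossprod(A, C); BC <- tcrossprod(B, C)
    D <- AB + t(AB) + 2 * (AC + t(AC)) + BC + t(BC)
    K <- 1 - D / (2 * m)
  } else {
    K <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      for (j in i:n) {
        ok <- !is.na(X[i, ]) & !is.na(X[j, ])
        if (!any(ok)) stop("individuals ", i, " and ", j,
                           " share no non-missing markers")
        K[i, j] <- K[j, i] <- 1 - mean(abs(X[i, ok] - X[j, ok])) / 2
      }
    }
  }
  new_kernel(K, rownames(X), "IBS")
}

#' Principal components of the marker matrix
#'
#' Scores of the top-d principal components of the column-centered dosage
#' matrix (unscaled), deterministic up to sign.
#'
#' @param G imputed [geno_matrix()] or dosage matrix.
#' @param d number of components to retain.
#' @return object of class `pc_scores`: `scores` (n x d), `eigenvalues`
#'   (all), `var_explained` (fractions, non-increasing), `d`.
#' @export
pca_genotypes <- function(G, d = 10) {
  X <- as_dosage(G)
  if (anyNA(X)) stop("PCA requires an imputed (complete) genotype matrix")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  rk <- sum(ev > max(ev) * 1e-10)
  if (d > rk) stop("d exceeds the rank of the centered matrix (", rk, ")")
  structure(list(scores = pr$x[, seq_len(d), drop = FALSE],
                 eigenvalues = ev, var_explained = ev / sum(ev), d = d),
            class = "pc_scores")
}

#' LD decay profile
#'
#' Squared Pearson correlation of dosages for intra-chromosome marker
#' pairs, binned by physical distance into `n_bins` half-open intervals
#' `[lo, hi)` over `[0, max_dist]`; pairs beyond `max_dist` are skipped.
#'
#' @param G [geno_matrix()] with a marker map.
#' @param max_dist maximum pair distance (bp).
#' @param n_bins number of distance bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_r2`, `n_pairs`
#'   (empty when no chromosome has two markers).
#' @export
ld_decay <- function(G, max_dist = 1e6, n_bins = 20) {
  stopifnot(inherits(G, "geno_matrix"))
  X <- G$dosage
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  dists <- numeric(0); r2 <- numeric(0)
  for (ch in unique(G$map$chrom)) {
    ix <- which(G$map$chrom == ch)
    if (length(ix) < 2) next
    pos <- G$map$pos[ix]
    cc <- suppressWarnings(cor(X[, ix, drop = FALSE],
                               use = "pairwise.complete.obs"))
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dd)
    keep <- ut & dd <= max_dist & !is.na(cc)
    dists <- c(dists, dd[keep]); r2 <- c(r2, cc[keep]^2)
  }
  if (!length(dists))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  bin <- findInterval(dists, breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  bin[bin > n_bins] <- n_bins  # distance exactly max_dist joins the last bin
  agg_m <- tapply(r2, factor(bin, levels = seq_len(n_bins)), mean)
  agg_n <- tapply(r2, factor(bin, levels = seq_len(n_bins)), length)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             mean_r2 = as.numeric(agg_m),
             n_pairs = ifelse(is.na(agg_n), 0L, as.integer(agg_n)))
}

#' Per-group minor-allele-frequency spectra
#'
#' MAF percentiles computed within each group from that group's own allele
#' frequencies, the summary used to contrast diverged subpopulations'
#' site-frequency spectra.
#'
#' @param G [geno_matrix()] or dosage matrix.
#' @param group_labels factor of group labels per individual.
#' @param percentiles percentiles to report (default 5, 10, ..., 95).
#' @return data.frame with `group`, `percentile`, `maf`.
#' @export
maf_spectrum <- function(G, group_labels, percentiles = seq(5, 95, by = 5)) {
  X <- as_dosage(G)
  group_labels <- factor(group_labels)
  if (any(table(group_labels) == 0)) stop("empty group")
  out <- lapply(levels(group_labels), function(g) {
    sub <- X[group_labels == g, , drop = FALSE]
    freq <- colMeans(sub, na.rm = TRUE) / 2
    maf <- pmin(freq, 1 - freq)
    maf <- maf[!is.na(maf)]
    data.frame(group = g, percentile = percentiles,
               maf = as.numeric(quantile(maf, percentiles / 100)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
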