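# Marker quality control: per-marker statistics, Hardy-Weinberg test,
# the three-rule filter (missingness < 20%, MAF > 1/2N, HWE p > 1e-4),
# and mean imputation.

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the p^2 / 2pq / q^2 expectation, with the allele frequency
#' estimated from the observed counts. No continuity correction is applied;
#' monomorphic samples return `chi2 = 0`, `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors are recycled jointly).
#' @return data.frame with columns `chi2` and `p`.
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: chi2 = 0
#' hwe_test(10, 10, 10)   # chi2 = 3.333
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("total count must be >= 1")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  chi2 <- numeric(k)
  poly <- p > 0 & p < 1
  chi2[poly] <- (n_AA[poly] - eAA[poly])^2 / eAA[poly] +
    (n_Aa[poly] - eAa[poly])^2 / eAa[poly] +
    (n_aa[poly] - eaa[poly])^2 / eaa[poly]
  pval <- ifelse(poly, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(chi2 = chi2, p = pval)
}

#' Per-marker statistics
#'
#' Missingness, minor allele frequency (from non-missing calls), the HWE
#' chi-squared test, and the non-missing count per marker. Markers with no
#' non-missing calls get `maf = NA` and are flagged for removal by
#' [filter_markers()].
#'
#' @param G a [geno_matrix()] or dosage matrix with values 0/1/2/NA.
#' @return data.frame with columns `marker`, `n_obs`, `missingness`, `maf`,
#'   `hwe_chi2`, `hwe_p`.
#' @export
compute_marker_stats <- function(G) {
  X <- as_dosage(G)
  if (!length(X)) stop("empty genotype matrix")
  n <- nrow(X)
  n_obs <- colSums(!is.na(X))
  miss <- (n - n_obs) / n
  n0 <- colSums(X == 0, na.rm = TRUE)
  n1 <- colSums(X == 1, na.rm = TRUE)
  n2 <- colSums(X == 2, na.rm = TRUE)
  alt <- ifelse(n_obs > 0, (2 * n2 + n1) / (2 * n_obs), NA_real_)
  maf <- pmin(alt, 1 - alt)
  chi2 <- rep(NA_real_, ncol(X)); pval <- rep(NA_real_, ncol(X))
  ok <- n_obs > 0
  if (any(ok)) {
    h <- hwe_test(n0[ok], n1[ok], n2[ok])
    chi2[ok] <- h$chi2; pval[ok] <- h$p
  }
  data.frame(marker = colnames(X), n_obs = n_obs, missingness = miss,
             maf = maf, hwe_chi2 = chi2, hwe_p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on missingness, MAF and HWE
#'
#' A marker is kept iff (strict inequalities throughout) its missingness is
#' below `miss_max`, its minor allele frequency exceeds `1/(2N)` with N the
#' total number of individuals in the panel, and its HWE p-value exceeds
#' `hwe_p_min`. Markers with no non-missing calls are always removed.
#'
#' @param G a [geno_matrix()] or dosage matrix.
#' @param miss_max maximum missingness fraction (exclusive), default 0.20.
#' @param maf_rule `"gt_1_over_2N"` (default) or a numeric threshold used as
#'   `maf > maf_rule`.
#' @param hwe_p_min minimum HWE p-value (exclusive), default 1e-4.
#' @return list with `geno` (filtered), `report` (removal counts per
#'   criterion; a marker may count against several), and `stats`.
#' @export
filter_markers <- function(G, miss_max = 0.20, maf_rule = "gt_1_over_2N",
                           hwe_p_min = 1e-4) {
  X <- as_dosage(G)
  st <- compute_marker_stats(X)
  maf_min <- if (identical(maf_rule, "gt_1_over_2N")) 1 / (2 * nrow(X))
             else as.numeric(maf_rule)
  no_calls <- is.na(st$maf)
  fail_miss <- st$missingness >= miss_max
  fail_maf <- no_calls | st$maf <= maf_min
  fail_hwe <- no_calls | st$hwe_p <= hwe_p_min
  keep <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep)) warning("no markers pass the filters")
  report <- data.frame(
    criterion = c("missingness", "maf", "hwe", "no_calls", "removed", "kept"),
    n = c(sum(fail_miss), sum(fail_maf), sum(fail_hwe), sum(no_calls),
          sum(!keep), sum(keep))
  )
  out <- if (inherits(G, "geno_matrix")) {
    geno_matrix(G$dosage[, keep, drop = FALSE],
                G$map[keep, , drop = FALSE], G$pop)
  } else X[, keep, drop = FALSE]
  list(geno = out, report = report, stats = st)
}

#' Impute missing dosages by the mean
#'
#' Replaces each missing call by the per-marker mean dosage, either over the
#' whole panel (default: the training panel is analysed as one merged
#' population) or within population labels; a population with no observed
#' call at a marker falls back to the panel mean. Imputed values are
#' fractional; per-marker mean dosage is preserved exactly.
#'
#' @param G a [geno_matrix()] (population scope requires labels) or matrix.
#' @param scope `"panel"` or `"population"`.
#' @return object of the same type with no missing calls.
#' @export
impute_missing <- function(G, scope = c("panel", "population")) {
  scope <- match.arg(scope)
  X <- as_dosage(G)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0))
    stop("marker(s) with no non-missing calls; filter before imputing")
  panel_mean <- colMeans(X, na.rm = TRUE)
  if (scope == "panel") {
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- panel_mean[idx[, 2]]
  } else {
    if (!inherits(G, "geno_matrix") || is.null(G$pop))
      stop("population-scope imputation requires a geno_matrix with pop labels")
    for (lev in levels(G$pop)) {
      rows <- which(G$pop == lev)
      sub <- X[rows, , drop = FALSE]
      gm <- colMeans(sub, na.rm = TRUE)
      gm[is.nan(gm)] <- panel_mean[is.nan(gm)]
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- gm[idx[, 2]]
      X[rows, ] <- sub
    }
  }
  if (inherits(G, "geno_matrix")) geno_matrix(X, G$map, G$pop) else X
}
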