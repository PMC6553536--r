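# Ploidy inference from reference-allele read-depth fractions at
# heterozygous calls: tetraploid heterozygotes cluster at 0.5, octoploid
# heterozygous calls split into 0.25 / 0.5 / 0.75 dosage classes.

#' Reference-allele fractions at heterozygous sites
#'
#' Per individual, the ratio of reference read depth to total read depth at
#' heterozygous calls with total depth at least `min_depth`.
#'
#' @param ad data.frame with columns `sample`, `ref_depth`, `total_depth`
#'   and logical `het` (as produced by [simulate_allelic_depths()] or
#'   [read_vcf()]).
#' @param min_depth minimum total depth for a site to qualify (default 10).
#' @return named list of numeric fraction vectors, one per sample
#'   (possibly empty).
#' @export
ref_allele_fractions <- function(ad, min_depth = 10) {
  need <- c("sample", "ref_depth", "total_depth", "het")
  if (!all(need %in% names(ad)))
    stop("ad must have columns ", paste(need, collapse = ", "))
  if (any(ad$ref_depth > ad$total_depth, na.rm = TRUE))
    stop("ref_depth cannot exceed total_depth")
  keep <- ad$het & !is.na(ad$total_depth) & ad$total_depth >= min_depth &
    ad$total_depth > 0
  sub <- ad[keep, , drop = FALSE]
  fr <- split(sub$ref_depth / sub$total_depth, sub$sample)
  # keep samples that lost every site
  empty <- setdiff(unique(ad$sample), names(fr))
  fr[empty] <- list(numeric(0))
  fr[unique(ad$sample)]
}

# smoothed probability mass of `x` inside (lo, hi): Gaussian-kernel CDF
window_mass <- function(x, lo, hi, bw) {
  mean(pnorm((hi - x) / bw) - pnorm((lo - x) / bw))
}

#' Classify ploidy from read-fraction distributions
#'
#' Compares the kernel-smoothed mass of the reference-allele fraction
#' distribution near the octoploid heterozygote classes (windows
#' `0.25 +- w` and `0.75 +- w`) against the mass near the tetraploid class
#' (`0.5 +- w`). An individual is called octoploid when the side mass
#' exceeds `ratio` times the central mass, tetraploid in the reverse case,
#' and ambiguous otherwise or when fewer than `min_sites` qualifying sites
#' are available. Smoothing (bandwidth `bw`) absorbs the binomial
#' quantization of read fractions at moderate depth.
#'
#' @param fractions numeric vector of fractions for one individual, or a
#'   named list of such vectors (from [ref_allele_fractions()]).
#' @param w window half-width (default 0.08).
#' @param ratio decision ratio between side and central mass (default 1).
#' @param min_sites minimum number of sites for a call (default 200).
#' @param bw Gaussian smoothing bandwidth (default 0.05).
#' @return data.frame with columns `sample`, `label` (`"tetraploid"`,
#'   `"octoploid"` or `"ambiguous"`), `centre_mass`, `side_mass`, `n_sites`.
#' @export
classify_ploidy <- function(fractions, w = 0.08, ratio = 1.0,
                            min_sites = 200, bw = 0.05) {
  if (!is.list(fractions)) fractions <- list(sample1 = fractions)
  if (is.null(names(fractions)))
    names(fractions) <- paste0("sample", seq_along(fractions))
  rows <- lapply(names(fractions), function(id) {
    x <- fractions[[id]]
    n <- length(x)
    if (n < min_sites)
      return(data.frame(sample = id, label = "ambiguous",
                        centre_mass = NA_real_, side_mass = NA_real_,
                        n_sites = n, stringsAsFactors = FALSE))
    centre <- window_mass(x, 0.5 - w, 0.5 + w, bw)
    side <- window_mass(x, 0.25 - w, 0.25 + w, bw) +
      window_mass(x, 0.75 - w, 0.75 + w, bw)
    label <- if (side > ratio * centre) "octoploid"
             else if (centre > ratio * side) "tetraploid"
             else "ambiguous"
    data.frame(sample = id, label = label, centre_mass = centre,
               side_mass = side, n_sites = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
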