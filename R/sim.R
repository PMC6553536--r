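# Synthetic structured-population generator: Balding-Nichols subpopulation
# divergence, half-sib trial phenotypes on the 0-20 winter-survival scale,
# geography-linked breeding values, and binomial allelic read depths.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults emulate a
#' desk-scale version of a multi-population lowland switchgrass training
#' panel: a few strongly diverged subpopulations (FST 0.3), a polygenic
#' winter-survival trait with family-mean heritability 0.6 scored 0-20 in a
#' two-location, three-block trial, and exome-capture-like read depths.
#'
#' @param n_subpops number of diverged subpopulations.
#' @param n_per_subpop maternal parents (= half-sib families) per subpopulation.
#' @param n_markers number of biallelic markers.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`; 0 = panmixia.
#' @param ancestral_maf_range range of the ancestral allele frequency draw.
#' @param n_qtl number of causal markers.
#' @param h2_target target narrow-sense heritability of family means in `[0, 1]`.
#' @param n_locations,n_blocks trial dimensions (blocks are nested in location).
#' @param missing_rate per-call missing-data rate, at most 0.2.
#' @param geo_gradient length-2 numeric: breeding-value change per degree
#'   latitude (north positive) and per degree longitude. Longitude is stored
#'   in positive degrees West, so an eastward-increasing trait has a negative
#'   second element.
#' @param mean_depth mean sequencing depth (reads/site) for read-depth simulation.
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param genetic_sd standard deviation of breeding values on the 0-20 score
#'   scale (before any geographic shift).
#' @param loc_sd,block_sd standard deviations of location and
#'   block-within-location effects on the score scale.
#' @param score_center grand mean of the latent score before clipping to `[0, 20]`.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subpops = 3, n_per_subpop = 60, n_markers = 2000,
                       fst = 0.3, ancestral_maf_range = c(0.05, 0.5),
                       n_qtl = 50, h2_target = 0.6, n_locations = 2,
                       n_blocks = 3, missing_rate = 0.05,
                       geo_gradient = c(0.5, -0.3), mean_depth = 20,
                       seed = 1L, genetic_sd = 2, loc_sd = 2, block_sd = 1,
                       score_center = 10) {
  counts <- c(n_subpops = n_subpops, n_per_subpop = n_per_subpop,
              n_markers = n_markers, n_locations = n_locations,
              n_blocks = n_blocks)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (n_qtl < 0) stop("n_qtl must be >= 0")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must lie in [0, 0.2]")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0)
    stop("ancestral_maf_range must be an increasing interval within (0, 0.5]")
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  if (length(geo_gradient) != 2) stop("geo_gradient must have length 2")
  structure(list(
    n_subpops = as.integer(n_subpops), n_per_subpop = as.integer(n_per_subpop),
    n_markers = as.integer(n_markers), fst = fst,
    ancestral_maf_range = ancestral_maf_range, n_qtl = as.integer(n_qtl),
    h2_target = h2_target, n_locations = as.integer(n_locations),
    n_blocks = as.integer(n_blocks), missing_rate = missing_rate,
    geo_gradient = geo_gradient, mean_depth = mean_depth,
    seed = as.integer(seed), genetic_sd = genetic_sd, loc_sd = loc_sd,
    block_sd = block_sd, score_center = score_center
  ), class = "sim_config")
}

# deterministic child seed per pipeline stage, kept inside 32-bit range
child_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Genotype matrix container
#'
#' Light S3 container: a dosage matrix (individuals x markers, values
#' 0/1/2 or NA, fractional after imputation), a marker map and optional
#' population labels.
#'
#' @param dosage numeric matrix, individuals in rows.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based).
#' @param pop optional factor of population labels per individual.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map = NULL, pop = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(map)) {
    map <- data.frame(marker = paste0("m", seq_len(ncol(dosage))),
                      chrom = "chr1", pos = seq_len(ncol(dosage)),
                      stringsAsFactors = FALSE)
  }
  if (nrow(map) != ncol(dosage)) stop("map rows must match dosage columns")
  if (anyDuplicated(map$marker)) stop("marker ids must be unique")
  if (anyDuplicated(rownames(dosage))) stop("individual ids must be unique")
  if (any(map$pos < 0)) stop("positions must be non-negative")
  colnames(dosage) <- map$marker
  if (!is.null(pop)) {
    pop <- factor(pop)
    if (length(pop) != nrow(dosage)) stop("pop labels must match individuals")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, map = map, pop = pop), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "markers;", sum(is.na(x$dosage)), "missing calls\n")
  if (!is.null(x$pop)) cat("populations:",
                           paste(levels(x$pop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

# accept either a geno_matrix or a bare dosage matrix
as_dosage <- function(G) {
  if (inherits(G, "geno_matrix")) G$dosage else as.matrix(G)
}

#' Simulate structured genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `config$ancestral_maf_range`; each subpopulation's frequency is a Beta
#' draw with mean the ancestral frequency and divergence governed by
#' `config$fst`; dosages are Binomial(2, freq), so Hardy-Weinberg holds
#' within subpopulations by construction. QTL positions and effects are
#' drawn and breeding values scaled so that `sd(BV) = config$genetic_sd`.
#'
#' @param config a [sim_config()].
#' @return list with `geno` (a [geno_matrix()]) and `truth` (QTL indices and
#'   effects, per-individual breeding values, subpopulation allele
#'   frequencies, ploidy labels).
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1))
  S <- config$n_subpops; n_s <- config$n_per_subpop; m <- config$n_markers
  n <- S * n_s
  p_anc <- runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  F <- config$fst
  freqs <- matrix(NA_real_, S, m)
  for (s in seq_len(S)) {
    if (F == 0) {
      freqs[s, ] <- p_anc
    } else {
      a <- p_anc * (1 - F) / F
      b <- (1 - p_anc) * (1 - F) / F
      freqs[s, ] <- rbeta(m, a, b)
    }
  }
  dosage <- matrix(NA_real_, n, m)
  pop <- factor(rep(paste0("pop", seq_len(S)), each = n_s),
                levels = paste0("pop", seq_len(S)))
  for (s in seq_len(S)) {
    rows <- ((s - 1) * n_s + 1):(s * n_s)
    dosage[rows, ] <- matrix(rbinom(n_s * m, 2, rep(freqs[s, ], each = n_s)),
                             n_s, m)
  }
  # QTL drawn on the complete matrix before masking
  qtl_idx <- integer(0); qtl_eff <- numeric(0)
  bv <- rep(0, n)
  if (config$n_qtl >= 1) {
    qtl_idx <- sort(sample.int(m, min(config$n_qtl, m)))
    qtl_eff <- rnorm(length(qtl_idx))
    raw <- drop(dosage[, qtl_idx, drop = FALSE] %*% qtl_eff)
    s_raw <- sd(raw)
    if (s_raw > 0) {
      qtl_eff <- qtl_eff * config$genetic_sd / s_raw
      bv <- drop(dosage[, qtl_idx, drop = FALSE] %*% qtl_eff)
      bv <- bv - mean(bv)
    }
  }
  if (config$missing_rate > 0) {
    mask <- matrix(runif(n * m) < config$missing_rate, n, m)
    dosage[mask] <- NA_real_
  }
  n_chr <- 9L
  chrom <- sort(rep(seq_len(n_chr), length.out = m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(2e7, length(ix)))), use.names = FALSE)
  map <- data.frame(marker = paste0("m", seq_len(m)),
                    chrom = paste0("chr", chrom), pos = pos,
                    stringsAsFactors = FALSE)
  rownames(dosage) <- paste0("fam", seq_len(n))
  geno <- geno_matrix(dosage, map, pop)
  names(bv) <- rownames(dosage)
  truth <- structure(list(
    qtl_indices = qtl_idx, qtl_effects = qtl_eff,
    breeding_values = bv, subpop_freqs = freqs,
    ploidy = setNames(rep("tetraploid", n), rownames(dosage))
  ), class = "sim_truth")
  list(geno = geno, truth = truth)
}

#' Assign geography and climate to populations
#'
#' Each population receives a latitude (28-45 degrees N), a longitude in
#' positive degrees West (75-100, so smaller = further east), and a 30-yr
#' minimum temperature generated as a linear function of latitude plus
#' noise (collinearity with latitude about -0.95). The implied
#' breeding-value shift `geo_gradient[1]*(lat - mean) +
#' geo_gradient[2]*(lonW - mean)` is returned per population; apply it to
#' simulated truth with [apply_geography()].
#'
#' @param pops character vector of population ids.
#' @param config a [sim_config()].
#' @return data.frame (class `population_meta`) with columns `population`,
#'   `latitude`, `longitude` (degrees West, positive), `min_temp`,
#'   `bv_shift`, `group`, `ploidy`.
#' @export
assign_geography <- function(pops, config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- as.character(unique(pops))
  set.seed(child_seed(config$seed, 3))
  n_p <- length(pops)
  lat <- runif(n_p, 28, 45)
  lon <- runif(n_p, 75, 100)  # degrees West, positive
  min_temp <- 25 - 0.9 * lat + rnorm(n_p, 0, 1.5)
  g <- config$geo_gradient
  shift <- g[1] * (lat - mean(lat)) + g[2] * (lon - mean(lon))
  structure(data.frame(
    population = pops, latitude = lat, longitude = lon,
    min_temp = min_temp, bv_shift = shift, group = pops,
    ploidy = "tetraploid", stringsAsFactors = FALSE
  ), class = c("population_meta", "data.frame"))
}

#' Shift breeding values along the assigned geographic gradient
#'
#' Adds each population's `bv_shift` from [assign_geography()] to the
#' breeding values of its members, producing the south-to-north /
#' west-to-east cline in population means that the downstream geographic
#' validation expects to recover.
#'
#' @param truth a `sim_truth` from [simulate_structured_genotypes()].
#' @param meta a `population_meta` from [assign_geography()].
#' @param pop factor of population labels per individual.
#' @return the updated `sim_truth`.
#' @export
apply_geography <- function(truth, meta, pop) {
  stopifnot(inherits(truth, "sim_truth"))
  pop <- as.character(pop)
  if (!all(pop %in% meta$population)) stop("unknown population label")
  shift <- setNames(meta$bv_shift, meta$population)[pop]
  truth$breeding_values <- truth$breeding_values + shift
  truth$breeding_values <- truth$breeding_values - mean(truth$breeding_values)
  truth
}

#' Simulate plot-level trial phenotypes
#'
#' Generates one winter-survival score per family x location x block plot:
#' a latent value (grand mean + location + block-within-location + breeding
#' value + family-x-location deviation + plot residual) clipped to the 0-20
#' scoring scale and rounded to whole scores. Non-genetic variances are set
#' so the narrow-sense heritability of family means matches
#' `config$h2_target`: the family-mean non-genetic variance
#' `var(BV) (1 - h2) / h2` is split 30% to family-x-location (scaled by the
#' number of locations) and 70% to the plot residual (scaled by plots per
#' family).
#'
#' @param G a [geno_matrix()] of family (maternal parent) genotypes.
#' @param truth matching `sim_truth` (possibly after [apply_geography()]).
#' @param config a [sim_config()].
#' @return data.frame with columns `location`, `block`, `family`, `score`.
#' @export
simulate_trial_phenotypes <- function(G, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(child_seed(config$seed, 2))
  bv <- truth$breeding_values
  fam <- names(bv)
  L <- config$n_locations; R <- config$n_blocks
  var_g <- var(bv)
  h2 <- config$h2_target
  if (h2 >= 1)
    stop("h2_target = 1 implies zero non-genetic variance at the family-mean level; not supported")
  if (var_g > 0 && h2 <= 0)
    stop("h2_target = 0 with non-zero genetic variance requires infinite noise")
  if (var_g == 0) {
    var_fl <- 0; var_e <- 1
  } else {
    nongen <- var_g * (1 - h2) / h2
    var_fl <- 0.3 * nongen * L
    var_e <- 0.7 * nongen * L * R
  }
  loc_eff <- rnorm(L, 0, config$loc_sd)
  blk_eff <- matrix(rnorm(L * R, 0, config$block_sd), L, R)
  fl_eff <- matrix(rnorm(length(fam) * L, 0, sqrt(var_fl)), length(fam), L)
  rec <- expand.grid(family = seq_along(fam), block = seq_len(R),
                     location = seq_len(L))
  latent <- config$score_center +
    loc_eff[rec$location] +
    blk_eff[cbind(rec$location, rec$block)] +
    bv[rec$family] +
    fl_eff[cbind(rec$family, rec$location)] +
    rnorm(nrow(rec), 0, sqrt(var_e))
  score <- round(pmin(20, pmax(0, latent)))
  data.frame(
    location = factor(paste0("loc", rec$location)),
    block = factor(paste0("loc", rec$location, ".b", rec$block)),
    family = factor(fam[rec$family], levels = fam),
    score = score,
    stringsAsFactors = FALSE
  )
}

#' Simulate allelic read depths at heterozygous sites
#'
#' For every heterozygous call (dosage 1) the total depth is
#' Poisson(`mean_depth`) and the reference read count is Binomial(total,
#' class fraction). Tetraploids have a single heterozygote dosage class with
#' reference fraction 0.5; octoploid heterozygous calls are a mixture of
#' dosage classes with fractions 0.25, 0.5 and 0.75 (weights
#' `octo_weights`), which is what shifts their read-fraction distribution
#' peaks to 0.25/0.75.
#'
#' @param G a [geno_matrix()].
#' @param ploidy_labels character vector per individual, values
#'   `"tetraploid"` or `"octoploid"`.
#' @param mean_depth mean reads per site (>= 1).
#' @param octo_weights mixture weights of the 0.25/0.5/0.75 classes.
#' @param seed optional seed.
#' @return data.frame with columns `sample`, `marker`, `ref_depth`,
#'   `total_depth`, `het`.
#' @export
simulate_allelic_depths <- function(G, ploidy_labels, mean_depth,
                                    octo_weights = c(1, 1, 1) / 3,
                                    seed = NULL) {
  X <- as_dosage(G)
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  ploidy_labels <- rep(ploidy_labels, length.out = nrow(X))
  bad <- setdiff(unique(ploidy_labels), c("tetraploid", "octoploid"))
  if (length(bad)) stop("unknown ploidy label: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(X))
  ids <- rownames(X)
  mk <- colnames(X)
  for (i in seq_len(nrow(X))) {
    het <- which(!is.na(X[i, ]) & X[i, ] == 1)
    if (!length(het)) { out[[i]] <- NULL; next }
    k <- length(het)
    frac <- if (ploidy_labels[i] == "tetraploid") rep(0.5, k)
            else sample(c(0.25, 0.5, 0.75), k, replace = TRUE,
                        prob = octo_weights)
    total <- rpois(k, mean_depth)
    ref <- rbinom(k, total, frac)
    out[[i]] <- data.frame(sample = ids[i], marker = mk[het],
                           ref_depth = ref, total_depth = total, het = TRUE,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a complete study
#'
#' Convenience wrapper chaining genotype simulation, geography assignment
#' (with the breeding-value cline applied), and trial phenotypes, i.e. the
#' full synthetic analogue of a structured training panel with
#' geography-linked winter survival.
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `truth`, `meta`, `records`.
#' @export
simulate_study <- function(config) {
  sim <- simulate_structured_genotypes(config)
  meta <- assign_geography(levels(sim$geno$pop), config)
  truth <- apply_geography(sim$truth, meta, sim$geno$pop)
  records <- simulate_trial_phenotypes(sim$geno, truth, config)
  list(geno = sim$geno, truth = truth, meta = meta, records = records)
}
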