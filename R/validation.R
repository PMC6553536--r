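# Independent-set validation: population-adjusted GEBVs, correlations with
# geographic/climatic gradients (with t-based critical values), multiple
# regression of GEBV on latitude and longitude, and phenotype-based
# prediction accuracies.

#' Population-adjusted GEBVs
#'
#' One-way linear model `GEBV ~ population`: the adjusted GEBV of a
#' population is its least-squares mean, i.e. the within-population mean
#' GEBV (exactly, balanced or not, for the one-way layout).
#'
#' @param gebv numeric GEBVs per individual.
#' @param pop population label per individual.
#' @return data.frame with columns `population`, `adj_gebv`, `n`.
#' @export
adjust_gebv <- function(gebv, pop) {
  if (!is.factor(pop)) pop <- factor(pop)
  if (length(gebv) != length(pop)) stop("gebv and pop lengths differ")
  if (any(table(pop) == 0)) stop("empty population level")
  fit <- lm(gebv ~ 0 + pop)
  cf <- coef(fit)
  data.frame(population = levels(pop), adj_gebv = unname(cf),
             n = as.integer(table(pop)), stringsAsFactors = FALSE)
}

#' Critical correlation at significance level alpha
#'
#' Two-sided t-based threshold: `r_crit = t / sqrt(t^2 + n - 2)` with `t`
#' the `1 - alpha/2` quantile of the t-distribution on `n - 2` df.
#'
#' @param n sample size.
#' @param alpha two-sided significance level (default 0.01).
#' @return critical absolute correlation.
#' @export
critical_r <- function(n, alpha = 0.01) {
  tq <- qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Correlations of adjusted GEBVs with geographic/climatic variables
#'
#' Pearson correlations of the population-adjusted GEBVs with minimum
#' temperature, latitude and longitude, alongside the two-sided t-based
#' critical |r| at level `alpha`. With longitude recorded in positive
#' degrees West, a trait increasing south-to-north and west-to-east shows
#' r(latitude) > 0, r(longitude) < 0 and r(min_temp) < 0.
#'
#' @param adjusted data.frame from [adjust_gebv()].
#' @param meta `population_meta` with `population`, `latitude`,
#'   `longitude`, `min_temp`.
#' @param alpha significance level for the critical value (default 0.01).
#' @return data.frame with `variable`, `r`, `n`, `r_crit`, `significant`.
#' @export
geo_correlations <- function(adjusted, meta, alpha = 0.01) {
  d <- merge(adjusted, meta, by = "population")
  if (nrow(d) < 4) stop("need at least 4 populations")
  vars <- c("min_temp", "latitude", "longitude")
  rc <- critical_r(nrow(d), alpha)
  rows <- lapply(vars, function(v) {
    x <- d[[v]]
    r <- if (sd(x) < 1e-12 || sd(d$adj_gebv) < 1e-12) NA_real_
         else cor(d$adj_gebv, x)
    data.frame(variable = v, r = r, n = nrow(d), r_crit = rc,
               significant = !is.na(r) & abs(r) > rc,
               stringsAsFactors = FALSE)
  })
  if (anyNA(vapply(rows, function(z) z$r, numeric(1))))
    warning("zero-variance variable: correlation undefined")
  do.call(rbind, rows)
}

#' Multiple regression of adjusted GEBVs on latitude and longitude
#'
#' Ordinary least squares `adj_gebv ~ latitude + longitude`. Minimum
#' temperature is deliberately excluded from the design because of its
#' collinearity with latitude.
#'
#' @param adjusted data.frame from [adjust_gebv()].
#' @param meta `population_meta`.
#' @return list with `coefficients` (estimate, t, p per term), `r2`,
#'   `adj_r2`, `n`, and the underlying `lm` fit.
#' @export
geo_regression <- function(adjusted, meta) {
  d <- merge(adjusted, meta, by = "population")
  if (nrow(d) < 4) stop("need at least 4 populations")
  fit <- lm(adj_gebv ~ latitude + longitude, data = d)
  if (any(is.na(coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  cf <- sm$coefficients
  list(coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, 1], t = cf[, 3],
                                 p = cf[, 4], row.names = NULL,
                                 stringsAsFactors = FALSE),
       r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, n = nrow(d), fit = fit)
}

#' Prediction accuracy against phenotypes
#'
#' Pearson correlation of predicted GEBVs with observed phenotype values,
#' either per individual or at the population level (both vectors averaged
#' within population first, the population-basis accuracy used for
#' location-wise validation).
#'
#' @param pred named numeric vector of predicted GEBVs.
#' @param obs named numeric vector of phenotype values (ids must match
#'   `pred` at the individual level).
#' @param level `"individual"` or `"population"`.
#' @param pop population label per element of `pred`/`obs`
#'   (required for `level = "population"`).
#' @return Pearson correlation.
#' @export
prediction_accuracy <- function(pred, obs,
                                level = c("individual", "population"),
                                pop = NULL) {
  level <- match.arg(level)
  if (!is.null(names(pred)) && !is.null(names(obs))) {
    unmatched <- union(setdiff(names(pred), names(obs)),
                       setdiff(names(obs), names(pred)))
    if (length(unmatched))
      stop("unmatched ids: ", paste(head(unmatched, 10), collapse = ", "))
    obs <- obs[names(pred)]
  } else if (length(pred) != length(obs)) {
    stop("pred and obs lengths differ and no ids to match on")
  }
  if (level == "population") {
    if (is.null(pop)) stop("population-level accuracy requires pop labels")
    pred <- tapply(pred, pop, mean)
    obs <- tapply(obs, pop, mean)
  }
  if (length(pred) < 3) stop("need at least 3 values for a correlation")
  cor(as.numeric(pred), as.numeric(obs))
}
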