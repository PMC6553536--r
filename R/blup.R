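# Trial variance components and family/population BLUPs from plot-level
# winter-survival records, fitted by REML with every model term random
# (intercept-only fixed part).

#' Random-term presets for the trial models
#'
#' Term sets for the three analysis designs: the joint multi-location
#' family model, the single-location family model, and the
#' population-by-block model used for independent validation trials
#' (locations analysed separately). With plot-level records the
#' family-x-block interactions are confounded with the plot residual and
#' are pooled into it.
#'
#' @param type one of `"multi_location"`, `"single_location"`,
#'   `"population_block"`.
#' @return character vector of random terms for [fit_random_model()].
#' @export
trial_model_terms <- function(type = c("multi_location", "single_location",
                                       "population_block")) {
  switch(match.arg(type),
    multi_location = c("location", "family", "location:block",
                       "location:family"),
    single_location = c("family", "block"),
    population_block = c("population", "block"))
}

#' Fit an all-random mixed model to trial records
#'
#' REML fit of `score ~ 1 + (1|term) + ...` with every listed term random.
#' Returns variance components, the grand mean, BLUPs per term level and
#' the restricted log-likelihood. Terms may be factor columns or
#' `a:b` interactions of factor columns.
#'
#' @param data data.frame of plot-level records.
#' @param terms character vector of random terms, e.g.
#'   [trial_model_terms()]`("multi_location")`.
#' @param response name of the response column (default `"score"`).
#' @return object of class `ranmod_fit`: `vc` (named variance components
#'   including `"Residual"`), `mu`, `blups` (named list of named vectors),
#'   `loglik`, `converged`, `terms`.
#' @export
fit_random_model <- function(data, terms, response = "score") {
  if (!response %in% names(data)) stop("no column '", response, "' in data")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing factor column(s): ", paste(missing_cols, collapse = ", "))
  for (v in vars) data[[v]] <- factor(data[[v]])
  groupings <- lapply(terms, function(tm) {
    f <- interaction(data[strsplit(tm, ":", fixed = TRUE)[[1]]], drop = TRUE)
    if (nlevels(f) < 2) stop("term '", tm, "' has fewer than 2 levels")
    f
  })
  codes <- vapply(groupings, function(f) paste(as.integer(f), collapse = ","),
                  character(1))
  if (anyDuplicated(codes))
    stop("confounded random terms: identical grouping structures")
  if (any(vapply(groupings, nlevels, integer(1)) == nrow(data)))
    stop("a random term is confounded with the residual (one level per record)")
  form <- reformulate(c("1", paste0("(1|", terms, ")")), response = response)
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged)
    warning("REML fit may not have converged: ",
            paste(unlist(msgs), collapse = "; "))
  vc_df <- as.data.frame(lme4::VarCorr(fit))
  vc <- setNames(vc_df$vcov, vc_df$grp)
  re <- lme4::ranef(fit)
  blups <- lapply(re, function(b) setNames(b[[1]], rownames(b)))
  # lme4 names interaction groupings "a:b" matching the input terms
  structure(list(vc = vc, mu = unname(lme4::fixef(fit)[1]), blups = blups,
                 loglik = as.numeric(logLik(fit)), converged = converged,
                 terms = terms, fit = fit),
            class = "ranmod_fit")
}

#' @export
print.ranmod_fit <- function(x, ...) {
  cat("All-random REML fit: mu =", round(x$mu, 4), "\n")
  print(round(x$vc, 5))
  cat("restricted loglik:", round(x$loglik, 4), "\n")
  invisible(x)
}

#' Non-centered family values
#'
#' The genomic-prediction response: grand mean plus the family BLUP,
#' preserving experiment-wise level differences (hence "non-centered").
#'
#' @param fit a `ranmod_fit`.
#' @param term name of the family term (default `"family"`).
#' @return data.frame with columns `family` and `value`.
#' @export
family_values <- function(fit, term = "family") {
  if (!term %in% names(fit$blups)) stop("no BLUPs for term '", term, "'")
  b <- fit$blups[[term]]
  data.frame(family = names(b), value = fit$mu + unname(b),
             stringsAsFactors = FALSE)
}

#' Family-mean broad-sense heritability
#'
#' Line-mean form: `H2 = s2_f / (s2_f + s2_fl / l + s2_e / (l r))` with
#' `l` locations and `r` blocks per location; the family-x-location
#' component is taken as 0 when absent from the fit.
#'
#' @param fit a `ranmod_fit`.
#' @param n_locations,n_blocks trial dimensions `l` and `r`.
#' @param family,family_location term names in `fit$vc`.
#' @return heritability in `[0, 1]`.
#' @export
family_mean_h2 <- function(fit, n_locations, n_blocks, family = "family",
                           family_location = "location:family") {
  vc <- if (inherits(fit, "ranmod_fit")) fit$vc else fit
  s2f <- if (family %in% names(vc)) vc[[family]] else
    stop("no variance component '", family, "'")
  s2fl <- if (family_location %in% names(vc)) vc[[family_location]] else 0
  s2e <- vc[["Residual"]]
  denom <- s2f + s2fl / n_locations + s2e / (n_locations * n_blocks)
  if (denom <= 0) stop("all variance components are zero: H2 undefined")
  s2f / denom
}

#' Convert 0-20 survival scores to a percentage
#'
#' Two conventions are exposed and neither is privileged:
#' `"score_fraction"` (mean score / 20 x 100) and `"plant_alive"`
#' (percentage of scores above 0).
#'
#' @param scores numeric scores on the 0-20 scale.
#' @param method `"score_fraction"` or `"plant_alive"`.
#' @return percentage in `[0, 100]`.
#' @export
survival_percent <- function(scores, method = c("score_fraction",
                                                "plant_alive")) {
  method <- match.arg(method)
  if (any(scores < 0 | scores > 20)) stop("scores must lie on the 0-20 scale")
  switch(method,
         score_fraction = mean(scores) / 20 * 100,
         plant_alive = 100 * mean(scores > 0))
}
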