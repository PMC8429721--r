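#' Specify a multifunctionality mixed model
#'
#' Three variants of the biodiversity--multifunctionality model are
#' supported:
#' * `"full"` -- the 13-term model: Year + Plant richness + Microbial index
#'   + Plant x Microbial + Aridity + Aridity x Plant + Aridity x Microbial
#'   + BNPP + Soil pH + Clay + Elevation + Latitude + Longitude;
#' * `"simplified"` -- the 7-term model focused on aridity and biodiversity:
#'   Year + Plant + Microbial + Aridity + Aridity x Plant + Aridity x
#'   Microbial + Aridity x Plant x Microbial;
#' * `"region_components"` -- the simplified structure with the microbial
#'   index replaced by the per-taxon richness components (archaea, bacteria,
#'   fungi).
#'
#' Random intercepts for soil type and vegetation type accompany every
#' variant. Terms are entered in the order above; the sequential (type-I)
#' ANOVA depends on it.
#'
#' @param variant model variant.
#' @param response `"multifunctionality"` (computed from the seven
#'   functions), `"multifunctionality_simplified"` (five functions), or the
#'   name of an existing column.
#' @param region fit on all sites or on the subset below/above the split
#'   level `c`.
#' @param c aridity split level; sites with aridity exactly `c` fall in the
#'   "above" group.
#' @param random_terms grouping columns for random intercepts.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(variant = c("full", "simplified", "region_components"),
                       response = "multifunctionality",
                       region = c("all", "below_c", "above_c"),
                       c = 0.80,
                       random_terms = c("soil_type", "vegetation_type")) {
  structure(list(variant = match.arg(variant), response = response,
                 region = match.arg(region), c = c,
                 random_terms = random_terms),
            class = "model_spec")
}

model_terms <- function(variant) {
  switch(variant,
    full = c("year", "plant_richness", "microbial_index",
             "plant_richness_x_microbial_index", "aridity",
             "aridity_x_plant_richness", "aridity_x_microbial_index",
             "bnpp", "soil_pH", "clay", "elevation", "latitude", "longitude"),
    simplified = c("year", "plant_richness", "microbial_index", "aridity",
                   "aridity_x_plant_richness", "aridity_x_microbial_index",
                   "aridity_x_plant_richness_x_microbial_index"),
    region_components = c("year", "plant_richness", "archaeal_richness",
                          "bacterial_richness", "fungal_richness", "aridity",
                          "aridity_x_plant_richness",
                          "aridity_x_archaeal_richness",
                          "aridity_x_bacterial_richness",
                          "aridity_x_fungal_richness"))
}

#' Build a standardized model design from a site table
#'
#' Computes the response and all fixed-term columns for a [model_spec()]:
#' the multifunctionality response, log10 transforms of plant richness and
#' elevation, BNPP from the biomass ratio, and the soil microbial diversity
#' index. After any region subsetting, the response and every continuous
#' main term are z-standardized *within the fitted subset* (so fitted
#' estimates are standardized coefficients comparable across terms and
#' regions), and interaction columns are formed as products of the
#' standardized mains.
#'
#' @param table a site table.
#' @param spec a [model_spec()].
#' @return A list of class `"model_design"`: `data` (response `y`, one
#'   column per fixed term, plus the random-term columns), `terms` (fixed
#'   terms in entry order), `spec`, `n`.
#' @export
build_design <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  needed <- c("aridity", "year", "plant_richness", "archaeal_richness",
              "bacterial_richness", "fungal_richness", spec$random_terms)
  if (spec$variant == "full")
    needed <- c(needed, "agb", "root_biomass", "ndvi", "soil_pH", "clay",
                "elevation", "latitude", "longitude")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  ## response and raw predictors on the full table (multifunctionality and
  ## the microbial index standardize functions across all sites given)
  y <- switch(spec$response,
              multifunctionality = multifunctionality_index(table),
              multifunctionality_simplified =
                multifunctionality_index(table, simplified = TRUE),
              {
                if (!spec$response %in% names(table))
                  stop("missing response column: ", spec$response, call. = FALSE)
                table[[spec$response]]
              })
  raw <- data.frame(
    year = as.numeric(table$year),
    plant_richness = log10(table$plant_richness + 1),
    microbial_index = microbial_diversity_index(table),
    archaeal_richness = as.numeric(table$archaeal_richness),
    bacterial_richness = as.numeric(table$bacterial_richness),
    fungal_richness = as.numeric(table$fungal_richness),
    aridity = table$aridity)
  if (spec$variant == "full") {
    raw$bnpp <- estimate_bnpp(table$agb, table$root_biomass, table$ndvi)
    raw$soil_pH <- table$soil_pH
    raw$clay <- table$clay
    raw$elevation <- log10(table$elevation)
    raw$latitude <- table$latitude
    raw$longitude <- table$longitude
  }

  keep <- switch(spec$region,
                 all = rep(TRUE, nrow(table)),
                 below_c = table$aridity < spec$c,
                 above_c = table$aridity >= spec$c)
  if (sum(keep) < 3L)
    stop("region '", spec$region, "' leaves fewer than 3 sites", call. = FALSE)
  raw <- raw[keep, , drop = FALSE]
  y <- y[keep]

  zscore <- function(v, name) {
    s <- stats::sd(v)
    if (s == 0 || !is.finite(s))
      stop("degenerate (zero-variance) term in fitted subset: ", name,
           call. = FALSE)
    (v - mean(v)) / s
  }
  terms <- model_terms(spec$variant)
  needed_mains <- unique(unlist(strsplit(terms, "_x_", fixed = TRUE)))
  mains <- vapply(needed_mains, function(nm) zscore(raw[[nm]], nm),
                  numeric(nrow(raw)))
  mains <- as.data.frame(mains)
  data <- data.frame(y = zscore(y, "response"))
  for (tm in terms) {
    parts <- strsplit(tm, "_x_", fixed = TRUE)[[1]]
    data[[tm]] <- Reduce(`*`, mains[parts])
  }
  for (rt in spec$random_terms) data[[rt]] <- table[[rt]][keep]

  structure(list(data = data, terms = terms, spec = spec, n = nrow(data)),
            class = "model_design")
}

#' Fit the mixed model and report the sequential ANOVA table
#'
#' Fits a random-intercept linear mixed model by REML (via `lmerTest`),
#' with sequential (type-I) F-tests using Satterthwaite denominator degrees
#' of freedom. When the fit is singular (any random-intercept variance below
#' `1e-8`), the offending random term(s) are dropped and the model refit;
#' with no random terms left the model falls back to ordinary least squares
#' with the classical sequential ANOVA.
#'
#' The report includes the standardized fixed-effect estimates, per-term
#' variance inflation factors computed from the design (`1/(1 - R2_j)` from
#' auxiliary regressions), random-intercept and residual variance
#' components, and Nakagawa marginal/conditional R-squared.
#'
#' @param design a [build_design()] result.
#' @param random_terms random-intercept grouping columns to use.
#' @param drop_singular drop near-zero random terms and refit.
#' @param vif_warn_threshold terms with VIF at or above this value are
#'   flagged.
#' @return A list of class `"mixed_fit_report"`: `table` (term, df, ddf, MS,
#'   F, P, estimate, VIF, vif_flag), `varcomp`, `marginal_R2`,
#'   `conditional_R2`, `singular_flag`, `dropped_random_terms`, `model`,
#'   `design`.
#' @export
fit_mixed <- function(design, random_terms = design$spec$random_terms,
                      drop_singular = TRUE, vif_warn_threshold = 10) {
  stopifnot(inherits(design, "model_design"))
  dat <- design$data
  terms <- design$terms

  # random factors need at least 2 observed levels
  random_terms <- random_terms[vapply(random_terms, function(rt)
    length(unique(dat[[rt]])) >= 2L, logical(1))]

  fixed_part <- paste(terms, collapse = " + ")
  fit_with <- function(rts) {
    if (length(rts) == 0L)
      return(stats::lm(stats::as.formula(paste("y ~", fixed_part)), data = dat))
    fml <- paste("y ~", fixed_part, "+",
                 paste(sprintf("(1 | %s)", rts), collapse = " + "))
    lmerTest::lmer(stats::as.formula(fml), data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))
  }

  model <- fit_with(random_terms)
  dropped <- character(0)
  singular_flag <- FALSE
  if (length(random_terms)) {
    vc <- as.data.frame(lme4::VarCorr(model))
    rvar <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                            vc$grp[vc$grp != "Residual"])
    singular_flag <- any(rvar < 1e-8)
    if (singular_flag && drop_singular) {
      dropped <- names(rvar)[rvar < 1e-8]
      model <- fit_with(setdiff(random_terms, dropped))
    }
  }
  is_mixed <- inherits(model, "merMod")

  ## sequential (type-I) ANOVA
  if (is_mixed) {
    an <- stats::anova(model, type = 1)
    tab <- data.frame(term = rownames(an), df = an$NumDF, ddf = an$DenDF,
                      MS = an$`Mean Sq`, F = an$`F value`,
                      P = an$`Pr(>F)`, row.names = NULL)
    est <- lme4::fixef(model)
  } else {
    an <- stats::anova(model)
    keep <- rownames(an) != "Residuals"
    tab <- data.frame(term = rownames(an)[keep], df = an$Df[keep],
                      ddf = stats::df.residual(model),
                      MS = an$`Mean Sq`[keep], F = an$`F value`[keep],
                      P = an$`Pr(>F)`[keep], row.names = NULL)
    est <- stats::coef(model)
  }
  tab <- tab[match(terms, tab$term), ]
  tab$estimate <- unname(est[terms])
  se <- stats::coef(summary(model))[, "Std. Error"]
  tab$SE <- unname(se[terms])
  tab$VIF <- design_vif(dat[, terms, drop = FALSE])
  tab$vif_flag <- tab$VIF >= vif_warn_threshold

  ## variance components and Nakagawa R2
  if (is_mixed) {
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    sigma2 <- varcomp[["Residual"]]
    re_var <- sum(varcomp[names(varcomp) != "Residual"])
    X <- stats::model.matrix(model)
    fixed_var <- stats::var(as.numeric(X %*% lme4::fixef(model)))
  } else {
    sigma2 <- summary(model)$sigma^2
    re_var <- 0
    varcomp <- c(Residual = sigma2)
    fixed_var <- stats::var(stats::fitted(model))
  }
  total <- fixed_var + re_var + sigma2
  structure(list(table = tab, varcomp = varcomp,
                 marginal_R2 = fixed_var / total,
                 conditional_R2 = (fixed_var + re_var) / total,
                 singular_flag = singular_flag,
                 dropped_random_terms = dropped,
                 model = model, design = design),
            class = "mixed_fit_report")
}

# VIF_j = 1 / (1 - R2_j) from regressing column j on the other columns
design_vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / max(1 - r2, 1e-12)
  }, numeric(1))
}

#' @export
print.mixed_fit_report <- function(x, digits = 3, ...) {
  cat("Linear mixed model (sequential ANOVA,", x$design$spec$variant,
      "variant)\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("Marginal R2 = %.2f, conditional R2 = %.2f%s\n",
              x$marginal_R2, x$conditional_R2,
              if (x$singular_flag)
                paste0(" [singular fit; dropped: ",
                       paste(x$dropped_random_terms, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Region-split OLS regressions of multifunctionality on diversity metrics
#'
#' For each diversity metric and each region (sites below `c`, at/above `c`,
#' and all sites), fits an ordinary least-squares regression of soil
#' multifunctionality on the metric and reports slope, intercept, r-squared,
#' the two-sided P-value and group size. Plant richness enters
#' log10-transformed; other metrics are raw richness values or the microbial
#' diversity index.
#'
#' @param table a site table.
#' @param metrics named list mapping metric labels to column names, or the
#'   default set (plant, microbial index, per-taxon and per-guild richness).
#' @param c aridity split level (sites with aridity exactly `c` go above).
#' @param response `"multifunctionality"` or `"multifunctionality_simplified"`.
#' @param alpha significance level for the flag.
#' @return A data.frame of class `"region_ols_report"`.
#' @export
ols_by_region <- function(table, metrics = NULL, c = 0.80,
                          response = "multifunctionality", alpha = 0.05) {
  if (is.null(metrics))
    metrics <- c("plant_richness", "microbial_index", "archaeal_richness",
                 "bacterial_richness", "fungal_richness",
                 "saprotroph_richness", "pathogen_richness",
                 "symbiont_richness")
  mf <- switch(response,
               multifunctionality = multifunctionality_index(table),
               multifunctionality_simplified =
                 multifunctionality_index(table, simplified = TRUE),
               table[[response]])
  groups <- list(below = table$aridity < c,
                 above = table$aridity >= c,
                 all = rep(TRUE, nrow(table)))
  empty <- names(groups)[vapply(groups, sum, numeric(1)) < 3]
  if (length(empty))
    stop("region group(s) with fewer than 3 sites: ",
         paste(empty, collapse = ", "), call. = FALSE)

  metric_values <- function(mname) {
    if (mname == "plant_richness") log10(table$plant_richness + 1)
    else if (mname == "microbial_index") microbial_diversity_index(table)
    else table[[mname]]
  }
  rows <- list()
  for (mname in metrics) {
    v <- metric_values(mname)
    for (g in names(groups)) {
      sel <- groups[[g]]
      fit <- stats::lm(mf[sel] ~ v[sel])
      sm <- summary(fit)
      p <- sm$coefficients[2, "Pr(>|t|)"]
      rows[[length(rows) + 1L]] <-
        data.frame(metric = mname, region = g,
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = sm$r.squared, P = p, n = sum(sel),
                   significant = p <= alpha)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_ols_report", "data.frame")
  out
}
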