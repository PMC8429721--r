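test_that("designs carry the model terms in entry order, standardized in-subset", {
  tab <- generate_sites(generator_config(seed = 4))
  d <- build_design(tab, model_spec("full"))
  expect_length(d$terms, 13L)
  expect_equal(d$terms[1:4], c("year", "plant_richness", "microbial_index",
                               "plant_richness_x_microbial_index"))
  for (tm in c("year", "aridity", "bnpp", "elevation")) {
    expect_equal(mean(d$data[[tm]]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(d$data[[tm]]), 1, tolerance = 1e-10)
  }
  expect_equal(mean(d$data$y), 0, tolerance = 1e-10)
  # interactions are products of the standardized mains
  expect_equal(d$data$aridity_x_microbial_index,
               d$data$aridity * d$data$microbial_index, tolerance = 1e-12)

  d7 <- build_design(tab, model_spec("simplified"))
  expect_length(d7$terms, 7L)
  # region split standardizes within the subset
  db <- build_design(tab, model_spec("simplified", region = "below_c"))
  expect_equal(db$n, sum(tab$aridity < 0.8))
  expect_equal(stats::sd(db$data$aridity), 1, tolerance = 1e-10)

  tab_bad <- tab; tab_bad$aridity <- NULL
  expect_error(build_design(tab_bad, model_spec("simplified")), "aridity")
})

test_that("zero random-effect data gives a singular flag and OLS-equal estimates", {
  # seed chosen so both boundary variance estimates collapse to zero and the
  # drop-on-singular rule exercises the full fall-back to OLS
  tab <- generate_sites(generator_config(seed = 3, sigma_soil = 0,
                                         sigma_veg = 0))
  d <- build_design(tab, model_spec("simplified"))
  rep <- fit_mixed(d)
  expect_true(rep$singular_flag)
  expect_length(rep$dropped_random_terms, 2L)
  ols <- stats::lm(stats::reformulate(d$terms, "y"), data = d$data)
  expect_equal(rep$table$estimate, unname(stats::coef(ols)[d$terms]),
               tolerance = 1e-6)
  expect_equal(rep$marginal_R2, rep$conditional_R2, tolerance = 1e-8)
  expect_true(all(rep$table$VIF >= 1))
})

test_that("sequential SS decomposes the total in the fixed-effects limit", {
  tab <- generate_sites(generator_config(seed = 6))
  d <- build_design(tab, model_spec("simplified"))
  rep <- fit_mixed(d, random_terms = character(0))
  an <- stats::anova(stats::lm(stats::reformulate(d$terms, "y"),
                               data = d$data))
  term_ss <- sum(rep$table$MS * rep$table$df)
  resid_ss <- an["Residuals", "Sum Sq"]
  total_ss <- sum((d$data$y - mean(d$data$y))^2)
  expect_equal(term_ss + resid_ss, total_ss, tolerance = 1e-6)
})

test_that("uncorrelated fixed terms keep their sequential F when reordered", {
  set.seed(13)
  n <- 120
  x1 <- stats::rnorm(n)
  x2 <- stats::resid(stats::lm(stats::rnorm(n) ~ x1))  # exactly orthogonal
  x2 <- (x2 - mean(x2)) / stats::sd(x2)
  y <- 0.5 * x1 - 0.3 * x2 + stats::rnorm(n)
  soil <- sample(letters[1:5], n, TRUE)
  veg <- sample(LETTERS[1:3], n, TRUE)
  mkdes <- function(terms) {
    # same columns; only the entry ORDER of the fixed terms changes
    dat <- data.frame(y = y, t1 = x1, t2 = x2, soil_type = soil,
                      vegetation_type = veg)
    structure(list(data = dat, terms = terms,
                   spec = model_spec("simplified"), n = n),
              class = "model_design")
  }
  r12 <- fit_mixed(mkdes(c("t1", "t2")), random_terms = character(0))
  r21 <- fit_mixed(mkdes(c("t2", "t1")), random_terms = character(0))
  expect_equal(r12$table$F[r12$table$term == "t1"],
               r21$table$F[r21$table$term == "t1"], tolerance = 1e-8)
  expect_equal(r12$table$F[r12$table$term == "t2"],
               r21$table$F[r21$table$term == "t2"], tolerance = 1e-8)
})

test_that("reported VIF matches auxiliary-regression recomputation", {
  tab <- generate_sites(generator_config(seed = 7))
  d <- build_design(tab, model_spec("full"))
  rep <- fit_mixed(d)
  X <- as.matrix(d$data[, d$terms])
  for (j in seq_along(d$terms)) {
    aux <- stats::lm(X[, j] ~ X[, -j])
    expect_equal(rep$table$VIF[j], 1 / (1 - summary(aux)$r.squared),
                 tolerance = 1e-6)
  }
})

test_that("mixed fits recover variance components and report Nakagawa R2", {
  set.seed(14)
  n <- 400
  soil <- sample(sprintf("s%02d", 1:10), n, TRUE)
  veg <- sample(sprintf("v%d", 1:4), n, TRUE)
  us <- stats::rnorm(10, 0, 0.5); uv <- stats::rnorm(4, 0, 0.3)
  x <- stats::rnorm(n)
  y <- 0.6 * x + us[as.integer(factor(soil))] + uv[as.integer(factor(veg))] +
    stats::rnorm(n, 0, 0.4)
  des <- structure(list(data = data.frame(y = y, x = x, soil_type = soil,
                                          vegetation_type = veg),
                        terms = "x", spec = model_spec("simplified"), n = n),
                   class = "model_design")
  rep <- fit_mixed(des)
  expect_false(rep$singular_flag)
  expect_true(rep$marginal_R2 < rep$conditional_R2)
  expect_true(rep$conditional_R2 <= 1)
  expect_equal(rep$table$estimate, 0.6, tolerance = 0.1)
  expect_gt(rep$varcomp[["soil_type"]], 0.05)
})

test_that("region OLS reports the split structure and trivial identities", {
  tab <- generate_sites(generator_config(seed = 8))
  tab$mf_copy <- multifunctionality_index(tab)
  # metric == response: a perfect fit, so lm's summary warns by design
  r <- suppressWarnings(
    ols_by_region(tab, metrics = "mf_copy", response = "mf_copy"))
  expect_equal(r$r_squared, rep(1, 3), tolerance = 1e-10)
  expect_equal(r$slope, rep(1, 3), tolerance = 1e-10)

  full <- ols_by_region(tab)
  expect_equal(nrow(full), 8 * 3)
  ns <- full$n[full$metric == "plant_richness"]
  expect_equal(ns[1] + ns[2], ns[3])
  expect_equal(ns[3], nrow(tab))
})

test_that("planted regional pattern: plant drives below, microbes above", {
  hits <- vapply(1:10, function(s) {
    tab <- generate_sites(generator_config(seed = 100 + s))
    r <- ols_by_region(tab)
    pick <- function(metric, region)
      r[r$metric == metric & r$region == region, ]
    plant_below <- pick("plant_richness", "below")
    plant_above <- pick("plant_richness", "above")
    mic_above <- pick("microbial_index", "above")
    plant_below$significant && plant_below$slope > 0 &&
      !isTRUE(plant_above$significant && plant_above$slope > 0) &&
      mic_above$significant && mic_above$slope > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
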