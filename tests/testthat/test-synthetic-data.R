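test_that("generator config validation catches impossible settings", {
  expect_error(generator_config(n_sites = 100), "sum to n_sites")
  expect_error(generator_config(aridity_range = c(0.2, 0.9)), "within")
  expect_error(generator_config(changepoint = 0.3), "strictly inside")
  expect_error(generator_config(sigma_resid = -1), "SDs")
  expect_error(generator_config(function_correlation = -0.5),
               "positive-semidefinite")
})

test_that("generated site tables honour subtype counts and invariants", {
  for (s in c(1L, 99L)) {
    tab <- generate_sites(generator_config(seed = s))
    expect_equal(nrow(tab), 130L)
    counts <- table(tab$subtype)
    expect_equal(unname(counts[c("dry-subhumid", "semiarid", "arid",
                                 "hyperarid")]),
                 c(12L, 42L, 56L, 20L), ignore_attr = TRUE)
    expect_true(all(tab$aridity > 0 & tab$aridity < 1))
    rich <- c("plant_richness", "archaeal_richness", "bacterial_richness",
              "fungal_richness", "saprotroph_richness", "pathogen_richness",
              "symbiont_richness")
    for (cl in rich) {
      expect_true(all(tab[[cl]] >= 0))
      expect_true(all(tab[[cl]] == round(tab[[cl]])))
    }
    expect_true(all(tab$saprotroph_richness <= tab$fungal_richness))
    expect_true(all(tab$pathogen_richness <= tab$fungal_richness))
    expect_true(all(tab$symbiont_richness <= tab$fungal_richness))
    expect_true(all(as.matrix(tab[, soil_function_names()]) > 0))
    expect_true(all(tab$perennial_cover >= 0 & tab$perennial_cover <= 1))
    # aridity matches the declared subtype
    expect_equal(as.character(classify_aridity(tab$aridity)), tab$subtype)
  }
})

test_that("generation is deterministic given the seed", {
  a <- generate_sites(generator_config(seed = 42))
  b <- generate_sites(generator_config(seed = 42))
  expect_identical(a, b)
  c <- generate_sites(generator_config(seed = 43))
  expect_false(identical(a$aridity, c$aridity))
})

test_that("coefficient profile returns planted values, high side at the break", {
  cfg <- noise_free_config()  # step profile, flat low side
  prof <- true_coefficient_profile(cfg, c(0.5, 0.8, 0.9))
  expect_equal(prof$beta_plant, c(0.30, 0.02, 0.02))
  expect_equal(prof$beta_mic, c(-0.10, 0.25, 0.25))
  expect_error(true_coefficient_profile(cfg, 0.2), "outside")

  # ramped default profile: low end, break value, and settled high value
  cfg2 <- generator_config()
  prof2 <- true_coefficient_profile(
    cfg2, c(cfg2$aridity_range[1], cfg2$changepoint - 1e-9,
            cfg2$changepoint + cfg2$transition_width_mic))
  expect_equal(prof2$beta_plant[1], cfg2$beta_plant_low)
  expect_equal(prof2$beta_mic[2], cfg2$beta_mic_break, tolerance = 1e-6)
  expect_equal(prof2$beta_mic[3], cfg2$beta_mic_high)
})

test_that("noise-free functions are exact transforms of aridity and diversity", {
  tab <- generate_sites(noise_free_config(seed = 5))
  tr <- attr(tab, "truth")
  a0 <- tr$config$aridity_range[1]
  for (fn in soil_function_names()) {
    expected <- aridishift:::function_baselines()[[fn]] -
      0.8 * (tab$aridity - a0) + tr$signal
    expect_equal(log10(tab[[fn]]), unname(expected), tolerance = 1e-12)
  }
})

test_that("zero-noise OLS below the break recovers the planted plant coefficient", {
  tab <- generate_sites(noise_free_config(seed = 11))
  tr <- attr(tab, "truth")
  mf <- multifunctionality_index(tab)
  sf <- standardize_functions(tab)
  k <- mean(1 / sf$scale)  # z-averaging rescales the log10-scale coefficients
  below <- tab$aridity < 0.8
  fit <- stats::lm(mf[below] ~ tab$aridity[below] + tr$z_plant[below] +
                     tr$z_mic[below])
  expect_lt(sum(stats::residuals(fit)^2), 1e-18)
  expect_equal(unname(stats::coef(fit)[3]) / k, 0.30, tolerance = 1e-6)
  expect_equal(unname(stats::coef(fit)[4]) / k, -0.10, tolerance = 1e-6)
})

test_that("function-noise correlation converges to the configured target", {
  cfg <- generator_config(
    n_sites = 5000,
    subtype_counts = c("dry-subhumid" = 500, "semiarid" = 1600,
                       "arid" = 2100, "hyperarid" = 800),
    sigma_soil = 0, sigma_veg = 0, seed = 8)
  tab <- generate_sites(cfg)
  tr <- attr(tab, "truth")
  # strip the deterministic part to leave the pure noise
  L <- log10(as.matrix(tab[, soil_function_names()]))
  det <- sweep(tr$decline, 2,
               unlist(aridishift:::function_baselines()), "+") + tr$signal
  eps <- L - det
  cors <- stats::cor(eps)[upper.tri(diag(7))]
  expect_true(all(abs(cors - 0.5) < 0.05))
})

test_that("microcosm tables have the planted moisture structure", {
  mc <- generate_microcosm(generator_config(seed = 3))
  expect_equal(nrow(mc), 30L)
  expect_equal(unname(table(mc$moisture_level)), rep(3L, 10),
               ignore_attr = TRUE)
  # monotone in expectation: level means strictly increase
  m <- tapply(mc$moisture_content, mc$moisture_level, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) > 0))
  expect_identical(mc, generate_microcosm(generator_config(seed = 3)))

  # planted waterlogging suppression, exact in the deterministic case
  mc0 <- generate_microcosm(generator_config(seed = 3, sigma_resid = 0))
  fn <- c("dna_conc", "phosphatase", "invertase", "urease",
          "beta_glucosidase", "catalase", "respiration")
  at <- function(lev) colMeans(mc0[mc0$moisture_level == lev, fn])
  expect_true(all(at(120) < at(100)))
})
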