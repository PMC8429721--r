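#' Generate a synthetic dryland site table
#'
#' Draws a seeded, deterministic table of field sites along an aridity
#' gradient with the statistical structure the downstream analysis assumes:
#' subtype counts fixed by the configuration, plant richness declining more
#' steeply with aridity than microbial richness rises, seven positive soil
#' function columns built on the log10 scale from a per-function aridity
#' decline plus a diversity signal whose standardized coefficients switch at
#' the planted change point, correlated function noise, and random intercepts
#' shared by sites of the same soil or vegetation type.
#'
#' The returned data.frame carries a `"truth"` attribute with the latent
#' quantities (standardized diversity scores, random intercepts, decline
#' matrix and the config) used to build the functions, for use in
#' parameter-recovery tests.
#'
#' @param config a [generator_config()].
#' @return A data.frame with one row per site (class `"site_table"`).
#' @examples
#' sites <- generate_sites(generator_config(seed = 42))
#' table(sites$subtype)
#' @export
generate_sites <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  config <- validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_sites
  bands <- aridity_bands()

  ## aridity: uniform within each subtype's band clipped to the config range
  subtype <- rep(names(config$subtype_counts), config$subtype_counts)
  aridity <- numeric(n)
  for (s in names(config$subtype_counts)) {
    row <- bands[bands$subtype == s, ]
    if (nrow(row) == 0L) stop("unknown dryland subtype: ", s, call. = FALSE)
    lo <- max(row$lower, config$aridity_range[1])
    hi <- min(row$upper, config$aridity_range[2])
    if (lo >= hi) stop("subtype ", s, " band empty within aridity_range",
                       call. = FALSE)
    idx <- which(subtype == s)
    aridity[idx] <- stats::runif(length(idx), lo, hi)
  }
  ord <- order(aridity)
  aridity <- aridity[ord]
  subtype <- subtype[ord]

  ## design covariates
  latitude  <- stats::runif(n, 35.89, 50.70)
  longitude <- stats::runif(n, 76.62, 122.41)
  elevation <- pmin(pmax(round(stats::rlnorm(n, log(1100), 0.45)), 204), 3570)
  year <- sample(config$years, n, replace = TRUE)
  soil_type <- sample(sprintf("soil_%02d", seq_len(config$n_soil_types)),
                      n, replace = TRUE)
  vegetation_type <- sample(sprintf("veg_%d", seq_len(config$n_veg_types)),
                            n, replace = TRUE)
  soil_pH <- pmin(pmax(7.0 + 2.0 * aridity + stats::rnorm(n, 0, 0.25), 6.5), 9.8)
  clay <- pmin(pmax(22 - 16 * aridity + stats::rnorm(n, 0, 3), 1), 45)
  perennial_cover <- pmin(pmax(
    0.85 * stats::plogis(2.2 - 5.5 * (aridity - 0.35)) + stats::rnorm(n, 0, 0.05),
    0.02), 0.95)
  ndvi <- pmin(pmax(0.07 + 0.45 * (1 - aridity)^2 + stats::rnorm(n, 0, 0.03),
                    0.01), 0.9)
  agb <- stats::rlnorm(n, log(120) - 2.0 * (aridity - 0.35), 0.35)
  root_biomass <- agb * stats::rlnorm(n, log(1.6), 0.25)

  ## richness: rounded log-normal draws; plant decline steeper than the
  ## microbial rise along the gradient
  plant_richness <- round(stats::rlnorm(n, log(25) - 3.0 * (aridity - 0.35), 0.35))
  archaeal_richness  <- round(stats::rlnorm(n, log(150) + 0.10 * (aridity - 0.35), 0.25))
  bacterial_richness <- round(stats::rlnorm(n, log(1500) + 0.12 * (aridity - 0.35), 0.22))
  fungal_richness    <- round(stats::rlnorm(n, log(350) + 0.15 * (aridity - 0.35), 0.28))
  saprotroph_richness <- stats::rbinom(n, fungal_richness, 0.45)
  pathogen_richness   <- stats::rbinom(n, fungal_richness, 0.15)
  symbiont_richness   <- stats::rbinom(n, fungal_richness, 0.10)

  ## latent standardized diversity scores used by the function generator
  z_plant <- as.numeric(scale(log10(plant_richness + 1)))
  z_mic <- as.numeric(scale(rowMeans(cbind(scale(archaeal_richness),
                                           scale(bacterial_richness),
                                           scale(fungal_richness)))))

  ## random intercepts drawn once per label and reused across sites
  u_soil_levels <- stats::rnorm(config$n_soil_types, 0, config$sigma_soil)
  names(u_soil_levels) <- sprintf("soil_%02d", seq_len(config$n_soil_types))
  u_veg_levels <- stats::rnorm(config$n_veg_types, 0, config$sigma_veg)
  names(u_veg_levels) <- sprintf("veg_%d", seq_len(config$n_veg_types))
  u_soil <- u_soil_levels[soil_type]
  u_veg <- u_veg_levels[vegetation_type]

  ## planted piecewise coefficient profile
  prof <- true_coefficient_profile(config, aridity)
  signal <- prof$beta_plant * z_plant + prof$beta_mic * z_mic

  fnames <- names(config$function_decline)
  F <- length(fnames)
  decline <- vapply(config$function_decline, eval_decline, numeric(n),
                    aridity = aridity, origin = config$aridity_range[1])
  eps <- correlated_noise(n, F, config$sigma_resid, config$function_correlation)

  alpha <- function_baselines()[fnames]
  log10_fun <- sweep(decline, 2, unlist(alpha), "+") +
    signal + u_soil + u_veg + eps
  fun_cols <- as.data.frame(10^log10_fun)
  names(fun_cols) <- fnames

  out <- data.frame(site_id = sprintf("site_%03d", seq_len(n)),
                    aridity = aridity, subtype = subtype,
                    latitude = latitude, longitude = longitude,
                    elevation = elevation, year = year,
                    soil_type = soil_type, vegetation_type = vegetation_type,
                    soil_pH = soil_pH, clay = clay,
                    perennial_cover = perennial_cover,
                    plant_richness = plant_richness,
                    archaeal_richness = archaeal_richness,
                    bacterial_richness = bacterial_richness,
                    fungal_richness = fungal_richness,
                    saprotroph_richness = saprotroph_richness,
                    pathogen_richness = pathogen_richness,
                    symbiont_richness = symbiont_richness,
                    ndvi = ndvi, agb = agb, root_biomass = root_biomass,
                    stringsAsFactors = FALSE)
  out <- cbind(out, fun_cols)
  attr(out, "truth") <- list(z_plant = z_plant, z_mic = z_mic,
                             u_soil = u_soil_levels, u_veg = u_veg_levels,
                             decline = decline, signal = signal,
                             config = config)
  attr(out, "units") <- site_table_units()
  class(out) <- c("site_table", "data.frame")
  out
}

# decline term, zero at the low edge of the gradient
eval_decline <- function(spec, aridity, origin) {
  if (identical(spec$form, "linear")) {
    spec$slope * (aridity - origin)
  } else if (identical(spec$form, "segmented")) {
    spec$slope1 * (pmin(aridity, spec$threshold) - origin) +
      spec$slope2 * pmax(aridity - spec$threshold, 0)
  } else stop("unknown decline form: ", spec$form, call. = FALSE)
}

# compound-symmetric Gaussian noise across function columns
correlated_noise <- function(n, F, sigma, rho) {
  if (sigma == 0) return(matrix(0, n, F))
  R <- matrix(rho, F, F)
  diag(R) <- 1
  MASS::mvrnorm(n, mu = rep(0, F), Sigma = sigma^2 * R)
}

# per-function log10 baselines (rough field magnitudes; units in metadata)
function_baselines <- function() {
  c(dna_conc = 1.2, org_C = 0.9, total_N = 0.0, ammonium = 0.7,
    nitrate = 0.6, total_P = 2.8, avail_P = 0.8)
}

site_table_units <- function() {
  c(aridity = "1 - AI", latitude = "deg N", longitude = "deg E",
    elevation = "m a.s.l.", soil_pH = "pH", clay = "%",
    perennial_cover = "fraction", ndvi = "NDVI",
    agb = "g m-2", root_biomass = "g m-2",
    dna_conc = "ug g-1", org_C = "g kg-1", total_N = "g kg-1",
    ammonium = "mg kg-1", nitrate = "mg kg-1", total_P = "mg kg-1",
    avail_P = "mg kg-1")
}

#' Names of the seven soil-function columns
#'
#' @param simplified drop `total_N` and `total_P` (the redundant /
#'   abiotically-controlled functions) to get the five-function simplified
#'   set.
#' @return Character vector of column names.
#' @export
soil_function_names <- function(simplified = FALSE) {
  full <- c("dna_conc", "org_C", "total_N", "ammonium", "nitrate",
            "total_P", "avail_P")
  if (simplified) setdiff(full, c("total_N", "total_P")) else full
}
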