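#' Configuration for the synthetic dryland survey generator
#'
#' Builds and validates the parameter set used by [generate_sites()] and
#' [generate_microcosm()]. Defaults emulate a 130-site dryland survey across
#' the four dryland subtypes (dry-subhumid, semiarid, arid, hyperarid) with
#' soil functions declining nonlinearly along the aridity gradient and a
#' planted change point in the diversity--multifunctionality coefficients at
#' aridity 0.8, the semiarid/arid boundary.
#'
#' Function columns are generated on the log10 scale as
#' `alpha_j + decline_j(aridity) + beta_plant(a) * z_plant + beta_mic(a) * z_mic
#'  + u_soil + u_veg + eps`, where `z_plant` is standardized log10 plant
#' richness, `z_mic` the standardized soil microbial diversity index, `u_*`
#' random intercepts drawn once per soil/vegetation label, and `eps` noise with
#' compound-symmetric cross-function correlation. The planted coefficient
#' profile `beta_*(a)` drifts linearly from its `_low` value at the dry-subhumid
#' end of the gradient to its `_break` value at the change point, then ramps
#' to the `_high` value across its transition width (see
#' [true_coefficient_profile()]); a flat low side with zero width gives a
#' pure step whose high side starts at the change point inclusive.
#'
#' @param n_sites number of field sites.
#' @param subtype_counts named integer vector of sites per dryland subtype;
#'   must sum to `n_sites`.
#' @param aridity_range length-2 numeric, the span of aridity (1 - AI) values;
#'   must lie within (0.35, 1).
#' @param changepoint planted aridity change point, strictly inside
#'   `aridity_range`.
#' @param transition_width_plant,transition_width_mic widths of the
#'   coefficient transitions: each planted coefficient ramps linearly across
#'   `[changepoint, changepoint + width]` from its `_break` to its `_high`
#'   value. Zero gives a pure step at `changepoint`
#'   (high side from `changepoint` inclusive). The defaults make the plant
#'   effect collapse at the boundary while the microbial effect builds up
#'   gradually across the arid band, mirroring how a bottom-up effect is
#'   cut off by water limitation while a top-down microbial effect
#'   strengthens as conditions dry.
#' @param beta_plant_low,beta_plant_high standardized plant-richness
#'   coefficient at the dry-subhumid end of the gradient / beyond the change
#'   point's transition (log10 function-scale units per SD of diversity).
#' @param beta_mic_low,beta_mic_high same for the soil microbial diversity
#'   index.
#' @param beta_plant_break,beta_mic_break coefficient values reached just
#'   below the change point. The low side of each profile drifts linearly
#'   from the `_low` value at the start of the gradient to the `_break`
#'   value at `changepoint`; `NULL` (flat low side, `_break` = `_low`)
#'   recovers a piecewise-constant low side. The defaults plant the
#'   trajectory shape seen in dryland surveys: the microbial coefficient
#'   sinks to its minimum at the threshold and then climbs steeply, while
#'   the plant coefficient weakens gradually and collapses past the
#'   threshold.
#' @param function_decline named list, one entry per soil function, each a list
#'   with `form` ("linear" or "segmented"), `slope` (linear) or
#'   `threshold`/`slope1`/`slope2` (segmented), all on the log10 scale per
#'   unit aridity.
#' @param function_correlation target pairwise correlation of the function
#'   noise (compound symmetry); must give a positive-semidefinite covariance,
#'   i.e. `>= -1/(F-1)`.
#' @param sigma_resid residual SD of the function noise (log10 units).
#' @param sigma_soil,sigma_veg SDs of the soil-type and vegetation-type random
#'   intercepts (log10 units).
#' @param n_soil_types,n_veg_types numbers of categorical labels.
#' @param years sampling-year labels sites are assigned to.
#' @param seed integer seed; the generator is deterministic given the config.
#'
#' @return An object of class `"generator_config"` (a validated list).
#' @examples
#' cfg <- generator_config()
#' cfg$changepoint
#' @export
generator_config <- function(n_sites = 130,
                             subtype_counts = c("dry-subhumid" = 12,
                                                "semiarid"     = 42,
                                                "arid"         = 56,
                                                "hyperarid"    = 20),
                             aridity_range = c(0.36, 0.99),
                             changepoint = 0.80,
                             transition_width_plant = 0,
                             transition_width_mic = 0.15,
                             beta_plant_low = 0.35,
                             beta_plant_high = 0,
                             beta_mic_low = -0.05,
                             beta_mic_high = 0.25,
                             beta_plant_break = 0.25,
                             beta_mic_break = -0.20,
                             function_decline = default_function_decline(),
                             function_correlation = 0.5,
                             sigma_resid = 0.15,
                             sigma_soil = 0.05,
                             sigma_veg = 0.05,
                             n_soil_types = 14,
                             n_veg_types = 4,
                             years = 2015:2017,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              subtype_counts = subtype_counts,
              aridity_range = as.numeric(aridity_range),
              changepoint = changepoint,
              transition_width_plant = transition_width_plant,
              transition_width_mic = transition_width_mic,
              beta_plant_low = beta_plant_low,
              beta_plant_high = beta_plant_high,
              beta_mic_low = beta_mic_low,
              beta_mic_high = beta_mic_high,
              beta_plant_break = if (is.null(beta_plant_break)) beta_plant_low
                                 else beta_plant_break,
              beta_mic_break = if (is.null(beta_mic_break)) beta_mic_low
                               else beta_mic_break,
              function_decline = function_decline,
              function_correlation = function_correlation,
              sigma_resid = sigma_resid,
              sigma_soil = sigma_soil,
              sigma_veg = sigma_veg,
              n_soil_types = as.integer(n_soil_types),
              n_veg_types = as.integer(n_veg_types),
              years = years,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic dryland survey configuration\n")
  cat("  sites:", x$n_sites,
      sprintf("(%s)", paste(names(x$subtype_counts), x$subtype_counts,
                            sep = "=", collapse = ", ")), "\n")
  cat(sprintf("  aridity range: [%.2f, %.2f], change point: %.2f\n",
              x$aridity_range[1], x$aridity_range[2], x$changepoint))
  cat(sprintf("  planted coefficients: plant %.2f -> %.2f, microbial %.2f -> %.2f\n",
              x$beta_plant_low, x$beta_plant_high,
              x$beta_mic_low, x$beta_mic_high))
  cat(sprintf("  noise: sigma_resid %.3f (cor %.2f), sigma_soil %.3f, sigma_veg %.3f\n",
              x$sigma_resid, x$function_correlation, x$sigma_soil, x$sigma_veg))
  invisible(x)
}

# Per-function aridity trends on the log10 scale. Most functions decline
# gently up to a function-specific aridity level and steeply beyond it;
# nitrate and total P are nearly flat (they track parent material more than
# biology).
default_function_decline <- function() {
  list(
    dna_conc = list(form = "segmented", threshold = 0.70, slope1 = -0.30, slope2 = -2.0),
    org_C    = list(form = "segmented", threshold = 0.62, slope1 = -0.40, slope2 = -1.8),
    total_N  = list(form = "segmented", threshold = 0.64, slope1 = -0.40, slope2 = -1.8),
    ammonium = list(form = "segmented", threshold = 0.75, slope1 = -0.20, slope2 = -1.5),
    nitrate  = list(form = "linear",    slope = -0.15),
    total_P  = list(form = "linear",    slope = -0.05),
    avail_P  = list(form = "segmented", threshold = 0.85, slope1 = -0.20, slope2 = -1.2)
  )
}

#' @keywords internal
validate_generator_config <- function(cfg) {
  if (sum(cfg$subtype_counts) != cfg$n_sites)
    stop("subtype_counts must sum to n_sites (", cfg$n_sites, "), got ",
         sum(cfg$subtype_counts), call. = FALSE)
  rng <- cfg$aridity_range
  if (length(rng) != 2L || rng[1] >= rng[2])
    stop("aridity_range must be an increasing length-2 interval", call. = FALSE)
  if (rng[1] < 0.35 || rng[2] >= 1)
    stop("aridity_range must lie within (0.35, 1): drylands only", call. = FALSE)
  if (cfg$changepoint <= rng[1] || cfg$changepoint >= rng[2])
    stop("changepoint must be strictly inside aridity_range", call. = FALSE)
  if (cfg$transition_width_plant < 0 || cfg$transition_width_mic < 0)
    stop("transition widths must be >= 0", call. = FALSE)
  sds <- c(cfg$sigma_resid, cfg$sigma_soil, cfg$sigma_veg)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  nf <- length(cfg$function_decline)
  if (nf < 2L) stop("need at least two soil functions", call. = FALSE)
  rho <- cfg$function_correlation
  # compound symmetry is PSD iff rho >= -1/(F-1) and rho <= 1
  if (rho > 1 || rho < -1 / (nf - 1))
    stop("function_correlation ", rho, " gives a non-positive-semidefinite ",
         "noise covariance for ", nf, " functions", call. = FALSE)
  cfg
}

# UNEP-style aridity bands used both by the generator and classify_aridity().
aridity_bands <- function() {
  data.frame(subtype = c("non-dryland", "dry-subhumid", "semiarid", "arid",
                         "hyperarid"),
             lower = c(0, 0.35, 0.50, 0.80, 0.95),
             upper = c(0.35, 0.50, 0.80, 0.95, 1),
             stringsAsFactors = FALSE)
}

#' Planted diversity coefficients at a given aridity level
#'
#' Ground truth for recovery tests: the standardized plant-richness and
#' microbial-index coefficients the generator used at aridity `aridity`.
#' Each coefficient drifts linearly from its `_low` value at the start of
#' the aridity range to its `_break` value just below `changepoint`, ramps
#' linearly across `[changepoint, changepoint + transition_width]` (its own
#' width) to the `_high` value, and holds it from the ramp's end on. With a
#' flat low side (`_break` = `_low`) and a width of 0 the profile is a pure
#' piecewise-constant step whose high side starts at `changepoint`
#' inclusive (half-open convention, matching the <0.8 / >0.8 regional
#' split).
#'
#' @param config a [generator_config()].
#' @param aridity numeric vector of aridity levels within
#'   `config$aridity_range`.
#' @return A data.frame with columns `aridity`, `beta_plant`, `beta_mic`.
#' @examples
#' true_coefficient_profile(generator_config(), c(0.5, 0.9))
#' @export
true_coefficient_profile <- function(config, aridity) {
  stopifnot(inherits(config, "generator_config"))
  rng <- config$aridity_range
  if (any(aridity < rng[1] | aridity > rng[2]))
    stop("aridity outside configured range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  profile1 <- function(lo, brk, hi, wd) {
    below <- pmin(pmax((aridity - rng[1]) / (config$changepoint - rng[1]),
                       0), 1)
    base <- lo + below * (brk - lo)        # low-side drift, = brk at c*
    up <- if (wd > 0) pmin(pmax((aridity - config$changepoint) / wd, 0), 1)
          else as.numeric(aridity >= config$changepoint)
    base + up * (hi - brk)                 # ramp brk -> hi above c*
  }
  data.frame(aridity = aridity,
             beta_plant = profile1(config$beta_plant_low,
                                   config$beta_plant_break,
                                   config$beta_plant_high,
                                   config$transition_width_plant),
             beta_mic = profile1(config$beta_mic_low,
                                 config$beta_mic_break,
                                 config$beta_mic_high,
                                 config$transition_width_mic))
}
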