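#' Generate a synthetic soil-moisture microcosm table
#'
#' Emulates a 30-microcosm incubation (10 moisture levels, 3 replicates)
#' manipulating soil water availability in the absence of plants. Moisture
#' content rises monotonically in expectation with the imposed level
#' (% of a field capacity of 27.6%), microbial richness follows a negative
#' quadratic in moisture content, and the seven process-rate functions
#' increase with moisture except at 120% field capacity, where waterlogging
#' suppresses them below the 100% level. Below 20% field capacity the
#' microbial-diversity coefficient on the functions is strengthened,
#' mirroring the tighter diversity--multifunctionality coupling expected
#' under dry conditions.
#'
#' @param config a [generator_config()]; only `seed`, `sigma_resid` and
#'   `function_correlation` are used.
#' @param beta_mic_dry,beta_mic_wet standardized microbial-index coefficient
#'   on the log10 process rates at moisture levels <= 20% / > 20% field
#'   capacity.
#' @return A 30-row data.frame (class `"microcosm_table"`).
#' @examples
#' mc <- generate_microcosm(generator_config(seed = 3))
#' table(mc$moisture_level)
#' @export
generate_microcosm <- function(config = generator_config(),
                               beta_mic_dry = 0.30, beta_mic_wet = 0.05) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 101L)
  levels <- c(3, 5, 8, 10, 20, 40, 60, 80, 100, 120)
  moisture_level <- rep(levels, each = 3)
  replicate <- rep(1:3, times = length(levels))
  n <- length(moisture_level)
  # sigma_resid = 0 is the fully deterministic case: silence every noise term
  s <- if (config$sigma_resid > 0) 1 else 0

  ## measured moisture content (% mass): anchored to the observed span
  ## 2.03% at 3% FC up to 33.57% at 120% FC
  mc_mean <- 2.03 + (33.57 - 2.03) * (moisture_level - 3) / (120 - 3)
  moisture_content <- pmax(mc_mean + stats::rnorm(n, 0, 0.35 * s), 0.5)

  ## richness: negative quadratic in moisture content, peak near 18%
  quad <- -((moisture_content - 18) / 16)^2
  archaeal_richness  <- round(stats::rlnorm(n, log(180)  + 0.4 * quad, 0.10 * s))
  bacterial_richness <- round(stats::rlnorm(n, log(1300) + 0.8 * quad, 0.08 * s))
  fungal_richness    <- round(stats::rlnorm(n, log(300)  + 0.8 * quad, 0.10 * s))

  z_mic <- as.numeric(scale(rowMeans(cbind(scale(archaeal_richness),
                                           scale(bacterial_richness),
                                           scale(fungal_richness)))))

  ## process rates: rise with moisture level, dip at 120% FC
  rise <- 0.45 * log10(pmin(moisture_level, 100) / 3)
  rise[moisture_level == 120] <- max(rise) - 0.15
  beta <- ifelse(moisture_level <= 20, beta_mic_dry, beta_mic_wet)

  fnames <- c("dna_conc", "phosphatase", "invertase", "urease",
              "beta_glucosidase", "catalase", "respiration")
  alpha <- c(dna_conc = 1.0, phosphatase = 0.5, invertase = 0.9, urease = 0.3,
             beta_glucosidase = 0.4, catalase = 0.7, respiration = 0.2)
  eps <- correlated_noise(n, length(fnames),
                          min(config$sigma_resid, 0.05),
                          config$function_correlation)
  log10_fun <- outer(rise + beta * z_mic, rep(1, length(fnames))) +
    matrix(alpha, n, length(fnames), byrow = TRUE) + eps
  fun_cols <- as.data.frame(10^log10_fun)
  names(fun_cols) <- fnames

  out <- data.frame(moisture_level = moisture_level, replicate = replicate,
                    moisture_content = moisture_content,
                    archaeal_richness = archaeal_richness,
                    bacterial_richness = bacterial_richness,
                    fungal_richness = fungal_richness,
                    stringsAsFactors = FALSE)
  out <- cbind(out, fun_cols)
  attr(out, "truth") <- list(z_mic = z_mic, beta = beta, rise = rise,
                             config = config)
  class(out) <- c("microcosm_table", "data.frame")
  out
}
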