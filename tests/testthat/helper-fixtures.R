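# shared fixtures, built in code at test time

# a small flat-profile, noise-free configuration: step coefficients, common
# linear declines, no random intercepts -- the analytically tractable case
noise_free_config <- function(seed = 1L, ...) {
  generator_config(
    seed = seed,
    sigma_resid = 0, sigma_soil = 0, sigma_veg = 0,
    function_correlation = 0,
    transition_width_plant = 0, transition_width_mic = 0,
    beta_plant_low = 0.30, beta_plant_break = 0.30, beta_plant_high = 0.02,
    beta_mic_low = -0.10, beta_mic_break = -0.10, beta_mic_high = 0.25,
    function_decline = stats::setNames(
      rep(list(list(form = "linear", slope = -0.8)), 7),
      soil_function_names()),
    ...)
}

# piecewise-linear response with a slope change at `brk`, noise scaled so
# that R^2 is approximately `r2`
planted_segmented <- function(n, brk, slope1 = -0.5, slope2 = -2.5,
                              r2 = 0.5, xlim = c(0.36, 0.99)) {
  x <- sort(stats::runif(n, xlim[1], xlim[2]))
  signal <- slope1 * x + (slope2 - slope1) * pmax(x - brk, 0)
  noise_sd <- stats::sd(signal) * sqrt((1 - r2) / r2)
  list(x = x, y = signal + stats::rnorm(n, 0, noise_sd))
}
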