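# aridishift

Dryland field surveys repeatedly find that biodiversity supports soil
functioning, but *which* biodiversity matters appears to depend on how dry a
site is: plant species richness tracks soil multifunctionality where water is
less limiting, while soil microbial diversity — fungi in particular — takes
over in the driest regions, with the hand-off occurring near aridity
(1 − precipitation/potential-evapotranspiration) of about 0.8, the
semiarid/arid boundary. `aridishift` implements the full analysis pipeline
needed to detect such a shift in a per-site survey table, together with a
seeded synthetic-data generator that plants a known shift so every stage can
be validated end to end without any field data.

The package is aimed at community and ecosystem ecologists working with
site × (diversity, environment, soil-function) tables along environmental
gradients.

## What it computes

**Soil multifunctionality (averaging approach).** Each soil function
*f<sub>j</sub>* (log10-transformed) is Z-scored across sites and averaged:

&nbsp;&nbsp;&nbsp;&nbsp;MF<sub>i</sub> = (1/F) Σ<sub>j</sub> z(log₁₀ f<sub>ij</sub>)

The same construction on archaeal, bacterial and fungal OTU richness gives
the soil microbial diversity index. The multiple-threshold variant counts,
for every threshold t ∈ {1, …, 99}%, the functions exceeding t% of their
maximum level (mean of the top four observed values) and regresses that
count on diversity, reporting T<sub>min</sub>, T<sub>mde</sub>,
T<sub>max</sub> and the matching M indices.

**Aridity-threshold detection.** For a response y along the gradient x the
protocol (i) compares linear, quadratic and GAM trends by AIC (ΔAIC > 2
rule), (ii) screens x for bimodality with a Gaussian-mixture fit, (iii) fits
three change-point regressions by exhaustive grid search over candidate
change points —

- step: y = β₀ + β₁·1[x > c]
- segmented: y = β₀ + β₁x + β₂(x − c)·1[x > c] (continuous at c)
- stegmented: both intercept and slope change —

selecting by AIC with ties resolved to the simpler form, and (iv) validates
the winning change point by bootstrapping linear regressions on each side of
c and comparing slopes and predictions at c with Mann–Whitney U-tests.

**Mixed models.** Multifunctionality is modelled with linear mixed models
(REML, random soil-type and vegetation-type intercepts), sequential (type-I)
ANOVA with Satterthwaite denominator df, standardized coefficients, VIF
screening and Nakagawa marginal/conditional R². The 13-term full model adds
BNPP (from the aboveground/root biomass ratio with NDVI as the ANPP proxy),
soil pH, clay and the spatial covariates; the 7-term simplified model keeps
Year, the two diversity terms, aridity and the aridity × diversity
interactions.

**Moving-window bootstrap.** Sites are sorted by aridity and the simplified
model is refit in every 60-site window (n − w + 1 = 71 windows for 130
sites), bootstrapping the standardized coefficients within each window
(B = 500 by default). The per-window medians, indexed by window-mean
aridity, form coefficient trajectories; the threshold protocol applied to a
trajectory localizes the aridity level where a biodiversity–
multifunctionality relationship shifts.

## Worked example

```r
library(aridishift)

cfg   <- generator_config(seed = 1)   # 130 sites, planted shift at 0.8
sites <- generate_sites(cfg)
table(sites$subtype)
#>         arid dry-subhumid    hyperarid     semiarid
#>           56           12           20           42

fit <- fit_mixed(build_design(sites, model_spec("simplified")))
print(fit)
#> Linear mixed model (sequential ANOVA, simplified variant)
#>                        term df ddf      MS       F        P estimate ...
#>                        year  1 117  0.7879   4.700 3.22e-02  -0.0485
#>              plant_richness  1 118 63.7583 380.335 1.17e-38   0.2816
#>             microbial_index  1 113  0.0527   0.314 5.76e-01  -0.1571
#>                     aridity  1 120  8.3624  49.884 1.14e-10  -0.4011
#>    aridity_x_plant_richness  1 115  5.1185  30.533 2.08e-07  -0.2101
#>   aridity_x_microbial_index  1 118 10.3627  61.816 2.02e-12   0.4126
#>  aridity_x_plant_... (3-way)  1 121  5.8370  34.819 3.40e-08  -0.2615
#> Marginal R2 = 0.78, conditional R2 = 0.84

mw <- moving_window_analysis(sites, w = 60, B = 200, seed = 42,
                             trajectory_terms = c("plant_richness",
                                                  "microbial_index"))
print(mw$windows)
#> Moving windows: 71 windows of 60 sites (70 one-site shifts)
print(mw$thresholds$microbial_index)
#> Threshold decision: continuous
#>   best form segmented at c = 0.8231
```

Reading the output: plant richness carries a strong positive standardized
coefficient (0.28) and the aridity × microbial-index interaction a strong
positive one (0.41) — the microbial effect strengthens as sites dry. The
trajectory of the microbial-index coefficient across the 71 windows shifts
slope at aridity ≈ 0.82, recovering the planted change point at 0.8.

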