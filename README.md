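# coastcete

Conservation assessment of small, geographically isolated coastal dolphin
populations from boat-based photo-identification surveys.

Small inshore dolphin populations — a few tens of animals confined to one
estuary — are among the hardest taxa to assess: too few individuals for
design-based abundance surveys, ranges too small for coarse national
listings, and mounting pressure from coastal development. `coastcete`
implements the full analysis chain such an assessment needs, end to end and
reproducibly:

1. **Representative range and core area** — kernel utilization
   distributions (UD) of school sightings with least-squares
   cross-validated bandwidths; the 95% and 50% isopleths define the
   representative range and core area; the minimum convex polygon (MCP)
   gives the extent of occurrence; polygon overlays quantify protection-zone
   coverage and development footprints.
2. **Depth-habitat selection** — a bathymetry grid interpolated by inverse
   distance weighting, classified into depth bands, and tested for
   electivity with Manly's alpha
   `alpha_r = (f_r / g_r) / sum_s (f_s / g_s)`, the Bray–Curtis
   dissimilarity `BCD = sum|f − E(f)| / sum(f + E(f))` as a global
   statistic, and multinomial randomization (10,000 draws) for global and
   per-habitat (`D_r = alpha_r − 1/n_R`) inference with Bonferroni
   correction.
3. **Abundance** — the POPAN (Schwarz–Arnason) parameterization of the
   Jolly–Seber open-population model: superpopulation size `N_m`, entry
   proportions `pent`, survival `phi`, detection `p_t`, fitted by maximum
   likelihood (sin/MLogit/log links), ranked by QAICc under a bootstrap
   overdispersion factor, and converted to total abundance with the mark
   ratio `N = N_m / theta` and its variance
   `Var(N) = N^2 (Var(N_m)/N_m^2 + (1 − theta)/(n theta))`.
4. **Potential Biological Removal** — `PBR = N_min × ½ R_max × F_r` with
   `N_min = N / exp(0.842 sqrt(ln(1 + CV^2)))` and Monte Carlo uncertainty
   (5,000 draws).
5. **IUCN regional Red List criteria** — B1 (extent of occurrence), B2
   (area of occupancy, proxied by the 95% UD), and D (mature population
   size) as a transparent, config-driven rules engine with the full
   CR/EN/VU ladders and the regional one-step downgrade.

A seeded synthetic-data generator (`synthetic_scenario()` and friends)
produces sightings, bathymetry and capture histories with the statistical
structure the analyses assume, so every stage is testable without field
data. All spatial computation is planar (projected meters, e.g. UTM).

## Worked example

Habitat electivity from a published-style table of per-class areas and
school counts within a representative range:

```r
library(coastcete)

areas  <- c(57.4, 153.5, 83.9, 30.2, 5.6)   # km2 per depth class
schools <- c(28, 274, 170, 67, 2)           # sightings per class
avail <- habitat_availability(areas)
round(manly_alpha(schools, avail), 2)
#> [1] 0.07 0.26 0.29 0.32 0.05
el <- electivity(schools, avail, n_iter = 10000, seed = 7)
el$global$bcd_obs            #> 0.1351097
el$global$bcd_exp_mean       #> 0.0299387
el$global$p_global           #> 0
```

The alphas say the moderate-depth class (10–15 m) is used about six times
more, relative to its availability, than the intertidal class; the observed
Bray–Curtis distance from proportional use (0.135) never occurs among
10,000 multinomial null draws (p = 0), so selection is highly non-random.

The whole pipeline on the default synthetic scenario:

```r
cfg <- pipeline_config(scenario = synthetic_scenario(seed = 3))
res <- run_pipeline(cfg, "coastcete-out")
```

prints per-stage timings and writes `summary.txt`:

```
95% UD = 292.4 km2; 50% UD = 103.9 km2; MCP = 284.5 km2
best POPAN model: phi(.)p(.)pent(.)N, N_m = 77.8, N_total = 101 (95% CI 89-115)
PBR at Fr=0.1: 0.19 /yr
IUCN overall (mature fraction 0.50): EN
```

— a population of about a hundred animals in under 300 km² that cannot
sustain the loss of even one individual every five years under an
endangered-stock recovery factor, and meets the Endangered thresholds of
criteria B1, B2 and D.

A thin command-line wrapper lives at `inst/cli/coastcete.R`
(`Rscript inst/cli/coastcete.R run --seed 1 --out DIR`).

## Package layout

- `R/` — synthetic data, spatial range, habitat selection, POPAN,
  PBR, IUCN, pipeline, I/O (CSV / MARK `.inp` / GeoJSON / ASCII grid).
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (exhaustive path-sum likelihood, gift-wrapping hull,
  closed-form expectations).
- `vignettes/coastcete-methods.Rmd` — models, assumptions, numerical
  choices and limitations.
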