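# riverpa

Do upstream protected areas change the trajectory of river invertebrate
communities? `riverpa` is an R package for relating *rates of temporal
change* in river invertebrate abundance, taxon richness, and ecological
quality (the Ecological Quality Ratio, EQR — an observed-to-expected
similarity to least-impacted reference communities, 0 = heavily impacted,
1 = reference) to protected-area (PA) cover measured across four upstream
spatial scales: buffered corridors following the channel and all
tributaries to 1-, 10-, and 100-km along-network distances, and the full
upstream catchment.

It is written for freshwater ecologists and conservation analysts working
with long-term invertebrate monitoring collations, and for methodologists
who want a fully synthetic, ground-truthed test bed for this style of
multi-scale trend analysis.

## What it computes

**Per-site trends.** For each site and metric, the log metric is regressed
on calendar year by generalized least squares with AR(1) residual
correlation decaying with the calendar-year gap,

    y_t = a + b t + e_t,   cor(e_s, e_t) = phi^|s - t|,

with `phi` profiled by REML. The slope is reported as the interpretable
rate `(exp(b) - 1) * 100` percent per year.

**Cover and gain.** Percent PA cover of each upstream-scale polygon is
computed for the year before the first and the year before the last
sampling year (communities get >= 1 year to respond), averaged (mean cover)
and differenced (gain rate, %/yr, non-negative). Corridor half-width on a
segment of Strahler order k is `100 k + width(k)/2` meters per side.

**Inference.** Analysis set 1 compares trend rates between
protected/unprotected and gain/no-gain groups per scale with linear mixed
models (`group + latitude + longitude + ts_length + (1 | provider)`),
likelihood-ratio tests, and Benjamini–Hochberg correction within each
metric-by-family set of four scales. Analysis set 2 relates trends of
protected (or gaining) sites to sqrt-transformed cover proportions with
penalized additive models — thin-plate main effects plus pure-interaction
tensor smooths `ti(pa, size)` and `ti(pa, eqr0)` — Wald-type smooth tests,
and conditional effect curves at initial EQR 0.2/0.4/0.6/0.8.

**Synthetic studies.** `gen_study()` generates a planar river network,
drainage tiles, clustered PAs with establishment years, sites, and
AR(1)-noised community series whose true log-slopes follow
`baseline + effect * sqrt(cover) * w(eqr0)`, `w` falling from 1 at initial
EQR 0.2 to 0 at 0.8 — with the full ground truth saved alongside.

The geometry layer (exact union areas by sweep, convex clipping,
point-in-polygon pixel counting, GeoJSON I/O) is self-contained planar
computational geometry; no GIS stack is required. Coordinates are projected
meters throughout.

## Worked example

```r
library(riverpa)

cfg <- run_config(generator = generator_config(seed = 7, n_headwaters = 10,
                                               n_sites = 60, n_pas = 25))
bundle <- run_pipeline(cfg)
bundle
#> <result_bundle: 60 sites (0 excluded), 24 group tests, 63 smooth tests>
#>   config hash: a3549acc7e4be7074f038bb5735262d7

subset(bundle$group$tests, metric == "eqr" & family == "protected",
       select = c(scale, n_group, n_ref, contrast, statistic, p_raw, p_adjusted))
#>    scale n_group n_ref   contrast statistic     p_raw p_adjusted
#> 17   1km      31    29 -0.3564115  1.126501 0.2885229  0.2885229
#> 18  10km      51     9  0.5385773  1.419222 0.2335315  0.2885229
#> 19 100km      51     9  0.5385773  1.419222 0.2335315  0.2885229
#> 20  full      59     1 -1.2887924  1.373058 0.2412871  0.2885229
```

Reading this: at the 1-km scale, 31 of the 60 synthetic sites have some
upstream protection; their EQR trend rate is 0.36 %/yr *lower* than
unprotected sites, but the likelihood-ratio statistic (1.13 on 1 df) gives
no evidence of a real group difference at any scale after BH adjustment —
at this small n, the presence/absence contrast is underpowered, which is
exactly why the degree-of-protection models exist. The smooth-model table
(`bundle$smooth$tests`) and effect curves (`bundle$smooth$curves`) carry
those results, e.g. the `ti(pa,eqr0)` rows test whether the cover effect
depends on initial ecological quality.

Tables are written as CSVs (plus a `meta.json` carrying the configuration
hash) when `out_dir` is set. A thin CLI wrapper lives at
`inst/cli/riverpa.R` (`generate`, `run`, `validate` subcommands over YAML
configs).

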