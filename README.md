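# litterfate

Analysis tools for soil incubation experiments that trace C4 plant litter
into soil organic carbon (SOC) fractions by natural-abundance δ¹³C.

## The problem

When C4 litter (δ¹³C ≈ −14 ‰, e.g. *Miscanthus* roots) is added to a
C3-dominated soil (≈ −26 ‰), every measured δ¹³C encodes how much carbon
derives from the litter ("new" C) versus the native soil ("old" C). With
a 20 µm particle-size fractionation — coarse particulate organic carbon
(POC) and fine mineral-associated organic carbon (MAOC) — the two-source
mixing model

f_C4 = (δ¹³C_sample − δ¹³C_ref) / (δ¹³C_litter − δ¹³C_ref)

splits each fraction into four source-resolved pools (POC_new, POC_old,
MAOC_new, MAOC_old). From these the package computes the quantities such
studies report:

* **pool accounting** with recovery diagnostics (mass recovery after
  fractionation; summed-pool C recovery against bulk SOC);
* **mass-balance fluxes**: litter C respired (as the residual of the
  POC/MAOC/CO₂ split) and mineralised litter N (C4-C loss over litter
  C:N);
* **priming**: relative change in native-C loss versus the unamended
  control, per old pool and treatment;
* **litter quality** from DRIFT mid-infrared spectra: maximum-absorbance
  compound ratios (aliphatic:aromatic, polysaccharide:lignin,
  aliphatic:amide I–III) in standard diagnostic band windows;
* **statistics**: per-occasion OLS regressions of pools on quality
  indicators, one-way ANOVA with Tukey HSD compact letter displays, and
  a numeric residual-normality note.

A first-order four-pool decomposition simulator (exact exponential
solution, source-preserving POC→MAOC transfer, C:N-dependent priming
multiplier, realistic measurement noise) generates complete synthetic
experiments, so the entire pipeline is testable without laboratory data.
Its defaults emulate a two-year, 6-treatment × 5-replicate *Miscanthus*
root-litter incubation with litter C:N ratios from 50 to 124.

## Worked example

```r
library(litterfate)
res <- run_incubation_analysis(experiment_design(),
                               simulation_config(seed = 1))

res$summary[, c("treatment", "d_soc_mean", "d_maoc_old_mean")]
#>   treatment d_soc_mean d_maoc_old_mean
#> 1     CN124      -46.0           -21.4
#> 2    CN124N      -46.8           -21.3
#> 3      CN50      -46.0           -13.9
#> 4      CN65      -44.1           -15.3
#> 5      CN85      -45.3           -16.1
#> 6   Average      -45.7           -17.6
```

After two simulated years the jars lost ~46 % of their total SOC
(`d_soc_mean`), and native MAOC loss deepens with litter C:N — the
N-mining priming gradient built into the simulator and recovered by the
analysis. The litter mass balance and the priming statistic:

```r
res$fate[res$fate$treatment == "CN50", ]
#>   pct_remaining_poc pct_maoc pct_respired month treatment
#> 1              19.8     9.83         70.3    24      CN50

pr <- res$priming
pr[pr$pool == "MAOC_old", c("treatment", "priming_pct", "priming_sd")]
#>   treatment priming_pct priming_sd
#> 1      CN50        3.19       22.9
#> 2      CN65       12.97       14.9
#> 3      CN85       19.43       17.9
#> 4     CN124       58.14       20.4
#> 5    CN124N       57.67       33.2
```

About 20 % of the added litter C is still POC after two years, ~10 % has
been stabilised as MAOC, and ~70 % was respired (mass-balance residual).
Native-MAOC priming rises monotonically with litter C:N and is strongest
when mineral N accompanies the poorest litter.

Individual building blocks are exported: `f_c4()`, `partition_pools()`,
`litter_fate()`, `n_mineralised()`, `priming()`, `generate_spectrum()`,
`compound_ratios()`, `linear_fit()`, `anova_tukey()`, and the
generator (`experiment_design()`, `simulation_config()`,
`generate_experiment()`). See the methods vignette
(`vignettes/litterfate-methods.Rmd`) for the model, its assumptions and
the calibration of the defaults.

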