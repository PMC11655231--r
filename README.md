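# gastrosim

Simulation and analysis of infant-formula digestion in a dynamic in vitro
gastric model.

Dynamic gastric simulators digest a reconstituted formula under continuous
simulated-gastric-fluid (SGF) secretion and periodic sieved emptying, and
the resulting data — particle-size distributions of the chyme, nutrient
retention over time, gel-band intensities — are what food scientists use
to compare casein-dominant, whey-dominant, and biopolymer-stabilized
formulae. gastrosim packages that whole workflow:

- **Mass-balance simulator** of the device protocol (100 g meal + 10 g
  basal SGF, 0.4 + 0.1 mL/min secretion, 22 g emptied through a 1 mm
  sieve every 20 min over 160 min), with phenomenological curd
  (sieve-retained coagulate) retention per nutrient and a simplified
  titration pH model.
- **Particle-size metrics**: the volume-weighted mean diameter
  d₄,₃ = Σnᵢdᵢ⁴/Σnᵢdᵢ³, the aggregation index
  AI = (d₄,₃(chyme) − d₄,₃(initial))/d₄,₃(initial) on water-dispersed
  measurements, and the coalescence index CI (same ratio after SDS + EDTA
  dispersion, which dissolves protein flocs so only true droplet
  coalescence remains), plus a power-law flow-curve classifier.
- **Retention kinetics**: the modified power-exponential model
  y(t) = α₀·exp(−(κt)^β) — κ the gastric emptying rate per minute, β the
  shape index — with bounded least-squares fitting and half-emptying
  times.
- **Correlation analyses**: two-stage (plateau → linear rise) fits of
  destabilization indices against percent nutrient emptied, and
  lipid-versus-protein emptying regressions, pooled and per profile
  group.
- **Densitometry**: dilution-corrected residual-intact-protein fractions
  and hydrolysis half-times from band-intensity tables.
- **Synthetic-data generator** producing complete, seed-reproducible
  study bundles with the statistical structure the analyses assume, so
  every stage is testable without laboratory data.

See `FORMATS.md` for the CSV/YAML interchange schemas and
`vignettes/gastric-digestion-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

Simulate a casein-dominant formula (1.7% protein, 3.94% fat) whose
protein curd plateaus at 20%, fit its retention curve, and compute the
aggregation index of a synthetic chyme:

```r
library(gastrosim)

formula <- formula_spec("casein_if", protein_frac = 0.017, fat_frac = 0.0394,
                        whey_casein_ratio = c(20, 80),
                        profile = "casein_dominant",
                        curd_fraction_params = list(protein = c(30, 0.06, 0.20),
                                                    lipid   = c(40, 0.05, 0.25)))
sim <- run_digestion(formula, digestion_protocol())
sim
#> <gastric_time_series> casein_if: 161 states over 160 min, 8 aliquots
#>   final chyme 14.00 g (protein 0.124 g, lipid 0.331 g)

fit <- fit_retention(nutrient_retention(sim, "protein",
                                        times = seq(0, 160, 20)))
fit
#> <elashoff_fit> alpha0 = 100.00%, kappa = 0.01152 /min (11.5 x10^-3), beta = 1.272
#>   rss = 41.79 on 9 points; converged: TRUE
half_emptying_time(fit)
#> [1] 65.05332

tpl <- default_templates()$casein_dominant
ser <- water <- Filter(function(p) p$dispersant == "water",
                       synth_psd_series(tpl, c(0, 40, 160)))
aggregation_index(d43(ser[[3]]), d43(ser[[1]]))
#> [1] 36.17177
```

Reading the numbers: the simulator empties 8 × 22 g aliquots and keeps
14 g of chyme at 160 min; the fitted emptying rate κ = 11.5 × 10⁻³/min is
depressed relative to the zero-curd proportional-removal rate because the
curd holds protein back (β > 1 captures the delayed early emptying), and
half the initial protein has left the stomach by ~65 min. The synthetic
casein-dominant chyme coarsens from d₄,₃ = 0.78 µm to ~29 µm by 160 min,
an aggregation index of ~36.

Full pipelines run on study bundles (directories of schema-validated
CSVs):

```r
study <- synth_study(n_per_profile = 2, seed = 42)
write_study_bundle(study, "bundle")
results <- run_pipeline("bundle", out_dir = "results")
results$regressions   # lipid-vs-protein emptying slopes per profile group
```

A thin CLI wraps the same functions:
`Rscript inst/cli/gastrosim.R pipeline --bundle bundle --out results`
(subcommands: simulate, indices, fit, correlate, bands, synth, pipeline).

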