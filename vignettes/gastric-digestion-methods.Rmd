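---
title: "Models and methods behind gastrosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gastrosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrosim)
```

gastrosim models the gastric phase of infant formula digestion as it is
studied in dynamic in vitro gastric simulators: a stomach compartment
receives a reconstituted formula meal plus a small basal load of simulated
gastric fluid (SGF), is fed continuously with SGF and an enzyme solution,
and is emptied periodically through a sieve that holds back coagulated
protein (curd). The package couples a mass-balance model of that device to
the three analyses used to interpret it: particle-size destabilization
indices, gastric-retention kinetics, and the correlation structure between
colloidal destabilization and macronutrient delivery.

## The mass-balance simulator

The stomach state is a small ledger: chyme mass, protein and lipid masses
(each split into an emptiable pool and a sieve-retained curd pool), the
secreted fluid currently in the chyme, and cumulative secreted acid.
Between emptying events the only dynamics are secretion: mass increases at
`sgf_flow + enzyme_flow` (0.4 + 0.1 mL/min by default) with all streams at
1 g/mL, a convention that makes gram and millilitre protocol statements
interchangeable. Secretions carry no protein or lipid; enzymes are tracked
as delivered activity only, because hydrolysis is quantified separately by
densitometry, not by reacting species in the mass balance.

Emptying is a discrete event: every `emptying_interval` (20 min, first
event at t = 20) the simulator withdraws up to `emptying_mass` (22 g) of
the *emptiable* phase. The emptiable phase is the chyme minus the curd
pools; the aliquot has exactly the emptiable phase's composition
(well-mixed assumption, no concentration gradients). At a grid point that
is simultaneously a secretion step, an event, and a recording time, the
order is: secrete over the preceding interval, empty, record. This makes
retention exactly 100% at t = 0 and gives the first aliquot the
110 + 10 = 120 g dilution the protocol implies. The integration grid is
the union of a 1-minute base grid, all event times and all sampling
times; mass conservation (meal + basal + secreted = chyme + emptied) is
asserted at every recorded point to 1e-9 g and is also exercised in the
test suite on randomized protocols.

Curd formation — casein coagulation into particles larger than the 1 mm
sieve — is modeled phenomenologically, not mechanistically: the curd
fraction of each nutrient follows a logistic time course
(onset, rate, plateau), renormalized so it is exactly 0 at t = 0 and rises
monotonically to the plateau. Casein-dominant profiles use an early onset
and high plateau, whey-dominant profiles a late onset and low plateau, and
biopolymer-stabilized profiles low protein curd with moderate lipid
entrapment. These shapes reproduce the qualitative behavior reported for
such systems (early visible curd in casein-dominant formulae, little or
none in whey-dominant ones) without claiming kinetic detail the data do
not constrain.

The pH model is deliberately minimal: pH(t) = max(floor,
pH0 − acid(t) / (buffer_capacity × protein(t))), a linear titration
against the protein still in the chyme with a floor at the SGF pH. It is
used only for directional statements — a more strongly buffered chyme
stays at a higher pH — and is never fitted to measured pH curves; treat
its absolute values as qualitative.

### The dilution ledger

Band-intensity normalization needs the factor by which secretion has
diluted the meal material at each time. A naive counterfactual ("the same
run without secretion") is ill-defined once sieved emptying can drain the
unsecreted stomach to zero before the run ends. gastrosim instead tracks
the secreted fluid resident in the chyme: emptying removes it in
proportion to its share of the emptiable phase, and the dilution factor is
`chyme_mass / (chyme_mass − secreted_in_chyme)`. This equals 1 at t = 0
and under zero flows, reproduces the 120/110 factor at the first event,
and — because removal is proportional — is continuous across events.

## Particle-size metrics

Distributions are binned volume densities on strictly increasing diameter
edges, normalized on construction. Bin midpoints are geometric means of
the edges: laser-diffraction instruments report log-spaced bins, for which
the geometric midpoint is the natural representative (arithmetic midpoints
differ by well under 1% at typical resolution; the choice is fixed and
documented rather than configurable). The volume-weighted mean diameter is
the De Brouckere mean d4,3 = Σnᵢdᵢ⁴/Σnᵢdᵢ³, which on a volume-weighted
representation reduces to Σvᵢdᵢ/Σvᵢ; the equivalence is tested against
direct number-moment arithmetic.

Two normalized indices quantify destabilization. The aggregation index
AI = (d4,3(chyme) − d4,3(initial)) / d4,3(initial) is computed on
water-dispersed measurements and responds to flocculation and coalescence
alike. The coalescence index CI is the same ratio on SDS + EDTA-dispersed
measurements: the buffer dissolves casein micelles and protein-mediated
flocs, so only genuinely coalesced oil droplets remain large. The
reference value is always the undigested formula (t = 0), not the
formula-plus-basal-SGF mixture, and both arguments must share a dispersant
dialect — mixing dialects is an error, not a warning. Negative indices are
reported as-is with a warning; clamping would hide measurement drift.

A minor helper fits the Ostwald–de Waele flow curve
log η = log K + (n − 1) log γ̇ and classifies rheology as Newtonian when
|n − 1| ≤ 0.05 (the threshold is configurable; the band is a practical
convention, not a physical constant).

## Retention kinetics

Gastric retention is modeled by the modified power-exponential curve
y(t) = α₀·exp(−(κt)^β): α₀ is the retention at t = 0 (100% for relative
curves), κ the emptying rate per minute, β the shape index (β = 1 is a
single exponential; β > 1 delays early emptying). The compact published
rendering of this model is ambiguous between exp(−(κt)^β) and
exp(−κ·t^β); gastrosim defaults to the former, consistent with κ being a
per-minute rate, and offers the latter behind `form = "exp_power"`.

Fitting is unweighted nonlinear least squares via bounded
Levenberg–Marquardt (minpack.lm), with κ started from a log-linear
regression slope, β started at 1, and bounds κ ∈ (1e-6, 1), β ∈ (0.1, 5).
α₀ is fixed at the observed t = 0 value by default, since published rate
tables report κ only and leaving α₀ free would let baseline noise leak
into the rate; β is reported but treated as a nuisance shape. On noiseless
model data the fitter recovers (κ, β) to machine precision across the grid
κ ∈ [5e-3, 2e-2], β ∈ [0.6, 2]; under 2% observation noise on six time
points the Monte-Carlo bias of κ (500 replicates) is well under 5%. Both
statements are properties the test suite computes, not assumptions.
Non-convergence yields a flagged fit rather than an exception; constant
retention data are a degenerate-data error. The half-emptying time is the
closed form t½ = (ln 2)^(1/β)/κ.

## Two-stage correlation analysis

Plotting a destabilization index against percent nutrient emptied
produces, in these systems, a near-zero plateau (stage 1: steady sieved
emptying before visible destabilization) followed by a near-linear rise
(stage 2). The stage boundary in the source analyses is descriptive, so
the default fit is deliberately simple: stage 1 is all points with index
at or below `index_floor` (default 0.5, roughly three standard deviations
of baseline AI noise in the synthetic baseline), stage 2 is fitted by OLS
of index on percent emptied, and the stage-2 line's x-intercept is the
headline number — the percent emptied at which destabilization begins to
track emptying. An SSE-minimizing grid search over the split point is
available (`method = "grid"`) as a sensitivity check; free-knot segmented
regression and information-criterion changepoint selection are
deliberately out of scope. On exact hinge data both methods recover the
knee; with fewer than two stage-2 points the fit is flagged degenerate
rather than extrapolated. Biopolymer-stabilized samples are excluded from
two-stage fits by default: their large initial particle size deflates the
normalized indices and the index-emptying correlation is not meaningful
for them; they remain in the group regressions.

The lipid-versus-protein emptying regression is OLS of lipid emptied (y)
on protein emptied (x) with free intercept, per sample group and pooled.

## Densitometry

Residual intact protein per band is
intensity(b, t) × dilution_factor(t) / intensity(b, 0); bands absent at
t = 0 are undefined (NA), and residuals above 1 are retained with a
warning. Hydrolysis half-time is the linearly interpolated first crossing
of 0.5, censored when never crossed in the window. Band matching is by
explicit label; gel-image processing is out of scope.

## The synthetic-data generator

The generator exists so the whole pipeline can be exercised, and its
estimators validated, without laboratory data. Its defaults encode the
study conditions the analyses assume: three profile classes whose initial
d4,3 values are calibrated analytically (a lognormal volume mode with
median m and geometric SD g has mean m·exp(ln²g/2)) to representative
undigested measurements — 0.78/0.66 µm (water/buffer) for the
casein-dominant class, 0.98/0.61 µm whey-dominant, and a bimodal
59.65/54.62 µm for the biopolymer-stabilized class whose coarse mode
persists in buffer. Aggregation onsets are 15 min (casein-dominant) and
80 min (whey-dominant), the times at which chyme distributions visibly
coarsen in each class; emptying rates are the class means of published
rate tables (κ_protein ≈ 11, 16.2, 16.4 ×10⁻³/min for casein, whey and
biopolymer classes; lipid correspondingly, with the biopolymer lipid rate
depressed to ≈ 11 ×10⁻³/min). Band decay rates make κ-casein residual
fall below 0.2 by 15 min in every profile, whey-profile caseins and
α-lactalbumin vanish by 120 min, and β-lactoglobulin persist longest —
the ordering seen on gels of such digestions.

Coarse-mode growth after onset is saturating (volume fraction
plateau × (1 − e^(−rate·Δt))), which produces the plateau-then-rise hinge
shape in AI-versus-emptied traces by construction. PSD noise is
multiplicative log-normal per bin with renormalization (additive noise can
go negative); retention noise is additive Gaussian with σ = 2 percentage
points by default (the variance model is a modeling choice, recorded in
every bundle's manifest) clamped to [0, 110]; band noise is multiplicative
log-normal. Per-sample emptying rates are jittered with 3% CV so samples
within a class differ the way commercial products do. Everything is
deterministic for a fixed seed.

What the generator does *not* emulate matters for interpreting green
tests: there is no creaming, no spatially structured curd, no coupling
from pH to aggregation rate, no enzymology, and the noise is homoscedastic
and independent across times. Passing recovery tests therefore shows the
estimators are correct and well-conditioned under the assumed statistical
structure — not that real digesta obey that structure.

## Numerical choices and problem sizes

Diameter grids use log-spaced bins; calibration examples use 100–400 bins
over 0.01–10 µm (fine emulsions) or 0.01–2000 µm (bimodal systems), at
which the midpoint-quadrature bias of d4,3 is below the second printed
decimal. The simulator grid is 1 min. Nonlinear fits use ftol = ptol =
1e-14 so noiseless round-trips reach 1e-6 relative recovery with margin.
Test and validation workloads are sized for interactive use: randomized
mass-balance checks use 100 protocol draws, Monte-Carlo bias studies 500
replicates of 6-point fits, and pipeline checks 1–2 formulae per profile;
all complete in seconds on one core.

## Known limitations

The simulator is a bookkeeping model: it has no contraction mechanics, no
spatial structure, and its pH is qualitative. Curd dynamics are a
parametric stand-in for coagulation physics. The two-stage fit's
breakpoint is threshold-based and inherits the floor's arbitrariness — use
the grid method to check sensitivity. The published intercept and
projected-index values for real formulae derive from figure-level data
that are not redistributable, so the package anchors those shapes in its
generator rather than reproducing the original fits.
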