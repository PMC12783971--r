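---
title: "Isotope tracer accounting in mushroom cultures: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope tracer accounting in mushroom cultures: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoflux)
library(dplyr)
```

`mycoflux` supports the design and analysis of stable-isotope tracer
experiments in cultivated fungi: dosing a substrate with ^13^C-glucose,
^15^N-ammonium chloride or D~2~O, measuring bulk samples by EA-IRMS, and
asking where the tracer went — how much stayed in the labelled
compartment, how much moved along the mycelial network, how much was
respired or degassed, and which substrate layer fed a developing
mushroom. A companion module analyses nanoSIMS ion-count images at
single-cell resolution. This vignette explains the models, the tunable
parameters, and the design decisions, in that order.

## Delta notation, atom fractions and mixing

All bulk measurements arrive as δ values, per-mil deviations of the
heavy/light isotope ratio from an international reference:

$$R = R_\mathrm{std}\left(\frac{\delta}{1000} + 1\right), \qquad
  AF = \frac{R}{1+R}.$$

The reference ratios (VPDB ^13^C/^12^C = 0.0111802, AIR ^15^N/^14^N =
0.0036765, VSMOW D/H = 0.00015576) live in a registry
(`iso_standards()`, overridable from YAML), never in the computation
paths, so a laboratory calibration change is a configuration change.
The two-isotope identity $AF = R/(1+R)$ is used throughout; at
tracer-level enrichments multi-isotope corrections are far below
EA-IRMS precision. Conversions round-trip to 1e-12 relative and are
strictly monotone; both properties are enforced by tests.

Pools mix by mole-weighted averaging of atom fractions
(`mix_pools()`), which conserves element and heavy-isotope moles
exactly. Dose design inverts the mixing balance:

$$n_\mathrm{tracer} = n_\mathrm{pool}
  \frac{AF_\mathrm{target} - AF_\mathrm{nat}}
       {AF_\mathrm{tracer} - AF_\mathrm{target}},$$

so `required_tracer_amount()` followed by `mix_pools()` reproduces the
target exactly — the identity behind the worked dose example in the
README. Suppliers state "all positions labelled" more often than a
certified purity, so the tracer atom fraction defaults to 0.99 and is a
required, overridable field of every compound definition
(`tracer_compounds()`).

## Tracer recovery accounting

A bulk sample is reduced to element moles
($m_\mathrm{dry} \times$ fraction / atomic mass) and a signed heavy
excess $E \cdot n = (AF_\mathrm{sample} - AF_\mathrm{ref})\, n$.
References are material-matched: compost, casing and malt medium all
sit away from the international standards, so `natural_refs()` derives
per-role references from unlabelled controls, falling back to the
standard composition only with a warning. Percent of added tracer is

$$100 \times \frac{(AF_\mathrm{sample} - AF_\mathrm{ref})\,n}
  {n_\mathrm{dose}\,(AF_\mathrm{tracer} - AF_\mathrm{nat})},$$

with the denominator the *excess* heavy atoms added above natural
abundance. Whether published recoveries use excess or gross heavy atoms
in the denominator is genuinely ambiguous; the excess convention is the
default because it makes a closed system sum to exactly 100 %, and
`denominator = "gross"` switches conventions. Negative excesses
(possible under measurement noise) are kept signed in the per-replicate
table for diagnostics and clipped to zero only at the percent stage,
with a warning. Replicates aggregate as mean ± SD, matching the
reporting convention of triplicated IRMS designs. Closure by difference
(`unrecovered_fraction()`) reads as respiration plus unmeasured loss
for carbon and degassing plus unmeasured loss for nitrogen; it may be
negative under noise and is then reported signed and flagged.

Two summaries sit on top: `directionality_index()`, the normalised
difference between tracer recovered peripheral versus central of the
labelled position along an ordered layout (+1 all outward, 0
symmetric); and `tracer_cn_ratio()`, the molar ratio of tracer-derived
carbon to nitrogen in one compartment.

## Source partitioning of sink enrichment

To attribute a mushroom's (or pin's) tracer content to substrate
layers, each labelling arm's sink excess is normalised by the initial
enrichment $e_{0,i}$ its layer actually reached — measured on a
dedicated control incubation labelled in all layers simultaneously and
sampled a few hours later — and the normalised ratios are expressed as
percentages:

$$U_i = \frac{E_{\mathrm{sink},i}/e_{0,i}}
             {\sum_j E_{\mathrm{sink},j}/e_{0,j}} \times 100.$$

This normalised-ratio form is isolated in `partition_sink()` so the
functional form can be swapped without touching the rest of the
pipeline. Normalising by measured $e_0$ (rather than by the dose mass,
which differs between casing and compost) is the default because it
absorbs between-layer differences in element stock and absorption;
`normalise = "dose"` provides the alternative. The assumptions — equal
sink biomass across arms, $e_0$ stable over the chase, no cross-arm
contamination — are stated rather than tested: the function warns on
clipped negatives but cannot verify field conduct. Contributions are
non-negative and sum to 100 by construction; carbon and nitrogen
partitions are computed independently and never pooled. A Bayesian
mixing model with uncertainty propagation is a documented extension
point, not implemented.

## nanoSIMS single-cell analysis

Carbon is imaged as C~2~^−^ molecular ions, so the heavy dimer
^12^C^13^C^−^ carries one heavy atom per two carbons and the atomic
ratio is half the count ratio:

$$r_{13} = 0.5\,\frac{n(^{12}\mathrm{C}^{13}\mathrm{C})}
                     {n(^{12}\mathrm{C}_2)}, \qquad
  r_{15} = \frac{n(^{12}\mathrm{C}^{15}\mathrm{N})}
                {n(^{12}\mathrm{C}^{14}\mathrm{N})}.$$

Planes are assumed aligned upstream (alignment is the acquisition
software's job); `accumulate_planes()` only sums. Ratios are computed
from total counts over each ROI's pixels, cells with zero denominator
counts are excluded with a warning, and per-cell δ values are expressed
relative to designated control cells of natural composition. Whether
the control reference should be the mean of per-cell ratios or the
ratio of pooled counts is not standardised; the mean-of-cells
convention is the default (`control_method = "cell_mean"`) because it
weights each control cell equally regardless of size, and `"pooled"` is
provided. Enrichment classification draws boundaries at the control
mean ± 2 × control SD (sample SD, n−1) and flags a cell only when its δ
lies *strictly above* the upper boundary: the test is one-sided because
only enrichment is biologically expected from a labelling experiment,
the lower boundary is reported but unused, and ties are not enriched.
Dead-time and quasi-simultaneous-arrival corrections are not applied —
a documented limitation; at the count rates typical of these analyses
the bias is small relative to the 2 SD band.

## The synthetic experiment generators

Every stage is testable by parameter recovery because the generators
(`simulate_ring_plate()`, `simulate_dish()`, `simulate_bed()`,
`simulate_nanosims()`) carry exact ground truth. The process model
allocates dose *atoms* across compartments: a fraction `degas` of
labelled-medium nitrogen redistributes in proportion to compartment
area (ammonia volatilisation), `leak` spreads passively to the other
medium compartments, `uptake` enters the mycelium, of which `respired`
is lost (carbon only), `transported` moves outward with probability
(1 + `bias`)/2 and per-ring decay `decay`, and a fraction `secretion`
of arriving tracer returns to that ring's medium. Allocated atoms are
forward-mixed into each compartment's natural element pool — the
written dry mass grows with the pool, so the analysis recovers the
allocated atoms exactly — and Gaussian noise is added to the δ values
per replicate. Pre-noise mass balance is exact by construction and
asserted on every run.

Defaults are the study conditions the generators emulate: ring-plate
doses of 2.95 g ^13^C-glucose and 0.16 g ^15^N-ammonium chloride per
200 mL of medium scaled to the labelled ring's volume, dish doses of
5.5 mg and 0.21 mg, bed doses of 30 mg and 1.5 mg per labelled layer;
five equal-volume rings of 10 mL (ring volumes are configurable — the
published plate geometry is not reproduced); malt medium at 40 %C,
1.4 %N and 50 g/L solids; compost at 35 %C, 2 %N; casing at 20 %C,
1 %N; three replicates. Measurement noise defaults to σ~δ~ = 0.2 ‰ (C)
and 0.3 ‰ (N), typical EA-IRMS precisions. Natural background δ values
are uniform per element across materials by default so that
material-matched references cancel exactly in conservation checks;
real substrates differ by a few per mil, which the analysis handles via
per-role references but the default generator deliberately does not
emulate. Bed sink weights default to `(casing 0.15, upper 0.55, lower
0.30)`, a top-compost-dominated feeding pattern; in the bed generator
the sink's excess atom fraction in arm *i* is exactly
`sink_uptake_scale` × w~i~ × e~0,i~, so `partition_sink()` recovers the
weights identically at zero noise.

What the generators do **not** emulate bounds what passing tests show:
no microbial sequestration or re-release of tracer, no bacterial
transport along hyphae, no spatially continuous diffusion, no
evaporation–condensation dynamics for deuterium beyond the qualitative
leak term, and no compost heterogeneity. Parameter-recovery tolerances
therefore certify the accounting arithmetic, not the biology of real
compost.

The nanoSIMS generator draws per-pixel, per-plane Poisson counts with
expected dimer counts tied to each cell group's true δ through the
0.5-corrected ratio, on a grid of square ROIs. Default expected counts
(400 per pixel for the major species over 36-pixel cells) put
\>10^4^ counts in every ROI, where Poisson-propagated δ errors are a
few tens of per mil — matching the regime in which single-cell
enrichments of hundreds of per mil (^15^N) are unambiguous while weak
^13^C enrichment (tens of per mil) sits near the detection boundary.

## Numerical choices and degenerate inputs

* δ ≤ −1000 ‰, non-positive ratios, atom fractions outside [0, 1) and
  empty pools raise classed domain errors; infeasible dose targets
  (target ≥ tracer purity) raise a distinct infeasibility error.
* All per-mil values are carried as plain doubles; nothing is rounded
  before output formatting.
* One global seed drives each generator run through a single RNG whose
  state is restored afterwards; identical seeds give byte-identical
  tables.
* Ties at the enrichment boundary are "not enriched" (strict `>`);
  zero-variance control sets are an error rather than a zero-width
  band.
* The directionality index returns 0 when nothing was recovered on
  either side, avoiding 0/0.
* Test and simulation problem sizes (20–50 seeded runs for parameter
  recovery, 10^4^ draws for round-trip checks, 10^5^ cells for the
  classifier's false-positive rate) were chosen so the whole suite
  runs in well under a minute on one core while keeping Monte-Carlo
  error a factor of a few below every asserted tolerance.

## Known limitations

Isotope fractionation (kinetic or equilibrium) is not modelled — at
tracer-level enrichments it is negligible against the signal, but the
package should not be used for natural-abundance ecology. Instrument
drift and blank corrections are assumed done upstream. The nanoSIMS
module does not segment images (ROIs are inputs), does not read vendor
raw files, and applies no dead-time/QSA correction. The deuterium
system is supported in the conversion and dose-design layer, but the
evaporation–condensation behaviour that makes D~2~O an unreliable
quantitative tracer in these cultures is exactly why no recovery
workflow is built around it.
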