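---
title: "Detecting riverbank habitat regime shifts and their effect on crocodylian nesting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting riverbank habitat regime shifts and their effect on crocodylian nesting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivershift)
```

## The scientific setting

Gharials nest only on open sand — riverbanks and mid-river sandbars kept
bare by seasonal floods. When flow drops in a regulated or
channel-shifted river, scouring stops and woody vegetation takes over the
banks; nesting then declines. The measurable signature of that process is
spectral: the Enhanced Vegetation Index (EVI) of a usable bank oscillates
seasonally between slightly negative values (submerged) and small
positive values (bare sand and grass), while an encroached bank sits
persistently above the woody threshold. This package provides the full
chain from reflectances to the ecological conclusion: EVI computation,
habitat classification with ground-truth validation, changepoint-based
regime-shift detection, and nest-count modelling.

## EVI and its classification

`compute_evi()` uses the canonical Landsat parameterisation
(G = 2.5, C1 = 6, C2 = 7.5, L = 1) on surface reflectances in [0, 1].
Observations with a near-zero denominator (tolerance 1e-6) are undefined
and dropped with a warning rather than clamped; values outside [-1, 1]
are flagged invalid when a series is assembled, because every habitat
class of interest lives inside (-1, 0.325).

Two classification schemes coexist:

* the **five-class scheme** (water, sand, grass, shrub, tree) with
  interval thresholds -1 < water < 0, 0 < sand < 0.08,
  0.05 < grass < 0.13, 0.13 < shrub < 0.215, 0.215 < tree < 0.325. Sand
  and grass genuinely overlap in EVI; the classifier resolves each
  adjacent pair at the midpoint of its overlap or gap (0.065 for
  sand/grass), uses half-open intervals [lo, hi) so boundary points are
  always assigned, and treats anything at or above the tree interval as
  tree;
* the **merged three-class scheme** — water (EVI < 0), sandy grassland
  (0 ≤ EVI < 0.13), woody vegetation (EVI ≥ 0.13) — which is
  threshold-exact and is what every downstream analysis consumes.
  Merging the five-class output reproduces the three-class labels
  everywhere, and coarsening can only raise agreement with ground truth,
  which is why validation accuracy improves after merging.

Ground truth comes from cover fractions in 1 m² plots. The rules are
evaluated woodiest-first (tree > 10%, shrub > 10%, grass > 30%,
water > 75%, sand > 75%) because sparse woody cover dominates a plot's
character; a plot firing no rule is reported `"unclassified"` and
excluded from confusion matrices. `calibrate_thresholds()` re-derives the
intervals as per-class (min, max) EVI on a random 80% training split;
`validate()` reports overall accuracy, producer's and user's accuracy
(the per-class figure quoted in reports is producer's accuracy, i.e.
recall, with the unweighted mean given alongside), and Cohen's kappa,
which is undefined (NA) when only one class occurs.

## Changepoints and the "no return" rule

`detect_changepoints()` segments a series by minimising total Gaussian
cost plus a per-changepoint penalty. Two cost families are exposed:
mean-only (segment RSS scaled by a pooled variance estimated from lag-1
differences, which is robust to mean jumps) and mean-and-variance (the
full Gaussian negative log-likelihood, with the segment variance floored
at 1e-8 so flat segments keep a finite cost). The default penalty is the
customary modified-BIC family, 3·p·log(n) with p parameters per
changepoint (1 for mean, 2 for meanvar); any numeric value can be passed
instead, and the number of changepoints is non-increasing in the
penalty. Three algorithms share the cost code: PELT and an unpruned
optimal-partitioning dynamic program both return the global optimum —
their agreement is asserted against an independent brute-force
enumeration of all segmentations in the test suite — and binary
segmentation provides the classic greedy baseline. One implementation
subtlety matters for correctness: with a minimum segment length above 1,
a PELT candidate pruned at time t may still be required before the
pruning competitor itself becomes admissible, so candidate removal is
delayed by the minimum segment length.

Detection runs on raw EVI, not on class labels: the shift of interest is
in the mean and/or variance of the habitat signal, and classes enter
only afterwards. `find_regime_shift()` encodes the ecological criterion:
scanning changepoints in time order, the first one after which the
fraction of later observations still classified into the pre-shift modal
class is at most `return_tolerance` is the regime shift. The default
tolerance 0.05 is a strict reading of "no return" that forgives isolated
noisy scenes; 0 gives the literal rule. The changepoint index convention
is the last observation of the left segment, and the shift date is that
observation's date — so an abrupt event at the start of year Y is
reported at the final scene of year Y−1.

## The nest-count relation

`fit_models()` fits three functional forms of nests against
nesting-season (March–April) average EVI: linear; exponential via least
squares on log(nests + 1), where the +1 admits the zero counts that real
nest tables contain; and logarithmic with a shifted argument
log(evi − min(evi) + 0.01), since EVI is frequently zero or negative.
All R² values are computed on the count scale so the forms compete
fairly; the exponential and logarithmic transforms would otherwise be
rewarded on their own scales. `select_best()` takes the highest R²,
breaking exact ties toward the simpler shape (linear, then logarithmic,
then exponential). The "p-value" attached to the winner is the
two-sided t-test on the slope of the (transformed) least-squares fit,
averaged over 1000 random 80% subsamples drawn without replacement —
a subsample scheme, not a classical bootstrap, and named accordingly.
Replicates with degenerate EVI spread are skipped and counted; more than
half skipped is an error. Site-years where nesting was observed but not
counted are excluded before fitting, since only actual counts carry
information about intensity.

## What the synthetic riverscape emulates

The generator is the package's stand-in for a 31-year Landsat archive
plus field surveys, and its defaults are the study conditions the
analyses assume:

* **Time base**: 8 sites, 1988–2019, 12 evenly spaced scenes per year
  (384 per site — the archive this emulates averaged ~11.5 scenes per
  site-year, and a monthly cadence keeps a March–April window
  populated).
* **Pre-disturbance signal**: baseline EVI 0.04 with seasonal amplitude
  0.08, so the noiseless cycle spans −0.04 to 0.12 — the oscillation
  between submerged bank and sandy grassland. Scene noise is Gaussian,
  SD 0.02.
* **Disturbance**: in 2010 the mean moves to `woody_target` 0.20 either
  abruptly, by a 3-year linear ramp, or via a 2-year submergence plateau
  at −0.10 followed by the ramp (the three site histories observed in
  this system). After conversion the seasonal amplitude is damped to a
  quarter of its open-bank value: a woody canopy's EVI varies far less
  than a flood-scoured bank's.
* **Plot EVI distributions**: class-conditional Gaussians centred at
  −0.5, 0.04, 0.10, 0.17, 0.27 with spread 0.02 — inside each published
  interval, with realistic sand/grass and shrub/tree overlap. Cover
  fractions come from a Dirichlet tilted toward the true class and are
  rejection-sampled until the ground-truth rules recover the label, the
  simplest construction that guarantees self-consistency.
* **Nest counts**: negative binomial with mean exp(3.0 − 10·EVI) and
  overdispersion 0.2 (variance μ + 0.2μ²; 0 gives Poisson). The
  log-linear slope −10 reproduces the observed contrast — about 20
  nests on open sand falling to ~1 in woody vegetation — and the
  overdispersion matches the spread of real per-site counts.

Everything is a pure function of `(seed, arguments)`: per-generator,
per-site substreams are derived from the master seed, so outputs are
bit-reproducible and adding a site never perturbs another site's draw.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: cross-sensor band differences across
the Landsat 4–8 series, atmospheric effects and cloud contamination,
mixed pixels at habitat edges (a pixel mostly water with a usable sand
patch classifies as water), spatial autocorrelation between neighbouring
sites, and flood-by-flood variability in the timing of vegetation
rebounds. Conclusions about a real river still require the validation
chain the package provides, run against real ground plots.

## Numerical and design choices

* Denominator tolerance 1e-6 in EVI; out-of-range values flagged, not
  clamped.
* Variance floor 1e-8 in the meanvar cost; in principle flooring can
  break the cost subadditivity PELT's pruning relies on, but the
  brute-force agreement property is part of the test suite and has never
  observed it on continuous data.
* Regime-shift localisation at a 3σ effect: the simulation study in the
  acceptance suite uses `return_tolerance = 0.2`. At a 3σ mean jump, the
  expected fraction of post-shift scenes misclassified back into the
  pre-shift class is about Φ(−1.3) ≈ 0.10, so the strict default 0.05
  would measure certification stringency rather than localisation; 0.2
  (double the expected overlap) isolates the question "is the year
  right?".
* Degenerate inputs: fits require ≥ 3 points and ≥ 2 distinct EVI
  values; single-class confusion matrices report accuracy with NA kappa;
  too-short series (< 4) are rejected; batch processing converts
  per-site errors into failure records instead of aborting.
* Problem sizes in the shipped simulations — 400 plots, 200 short series
  for the optimality property, 200 recovery replicates, 100 nest
  datasets — were chosen so each Monte-Carlo proportion has a standard
  error below ~0.035 while the whole suite stays interactive.

## Known limitations

The five-class EVI scheme is inherently ambiguous in the sand/grass and
shrub/tree overlaps; the merged scheme is the analysis-grade product.
The "no return" rule is evaluated on whatever window follows the
changepoint, so a shift detected near the end of a series rests on few
observations; the per-changepoint post-window fraction is reported so
users can judge. Counts are modelled by curve fitting on the count
scale, as in the analysis this package operationalises — a
negative-binomial GLM would be the natural next step but is deliberately
out of scope.
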