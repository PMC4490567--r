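---
title: "Methods: footprint, sourcing distance and supply limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint, sourcing distance and supply limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanfootprint)
```

This vignette documents the models implemented in `oceanfootprint`, their
assumptions, the parameters that matter, and the design choices made where
the methodology was genuinely open. The package's deliberate stance is that
every analysis runs on a synthetic world whose ground truth is retained, so
each statistical procedure can be validated against quantities that are
known exactly.

## The trophic footprint statistic

The primary production required (PPR) to generate a catch converts each
landed tonne back into the photosynthetic carbon that supported it:

$$\mathrm{PPR} = \sum_{i=1}^{n} \frac{C_i}{\mathrm{CR}}
  \left(\frac{1}{\mathrm{TE}}\right)^{\mathrm{TL}_i - 1}$$

with $C_i$ the wet-weight catch of taxon $i$ (tonnes), CR the wet-weight to
carbon conversion ratio (default 9, dimensionless), TE the trophic transfer
efficiency (default 0.10) and $\mathrm{TL}_i$ the taxon's trophic level.
The statistic is linear in catch, additive over disjoint groups, exactly
halved when CR doubles, and reduces to $C/\mathrm{CR}$ at TL 1 (harvested
primary producers) — all of which the test suite asserts. Its key
assumption is that a single global TE describes energy transfer at every
step of every food chain; the Monte Carlo layer (below) is the honest
acknowledgement of how strong that assumption is, since PPR depends on TE
through an exponent and small TE changes move high-TL footprints a lot.

Dividing cell-level PPR by the cell's multi-year mean primary production
(PP) gives an exploitation ratio. Ratios are binned into three area bands
with half-open intervals $[0.10, 0.20)$, $[0.20, 0.30)$, $[0.30, \infty)$:
closed on the left so the bands are disjoint and together exhaust
everything at or above the lowest threshold. The accessible-ocean summary
restricts both numerator and denominator to sea cells strictly shallower
than 1,000 m — the depth most fishing methods can reach — and reports
$100 \times \sum \mathrm{PPR} / \sum \mathrm{PP}$ per year.

## Monte Carlo uncertainty

`mc_accessible_percentage()` propagates two uncertainties per trial:

* **TE** is drawn from a truncated normal with mean 0.10 and s.d. 0.0303
  (the spread whose central 90% roughly spans 5–15%), truncated to
  $[0.05, 0.15]$ by default. The truncation interval is configuration, not
  constant: wider explorations (1.5–20%) are possible via
  `mc_config(te_bounds =)`, but the default follows the narrower
  confidence-limit reading because untruncated draws near 1–2% make
  $(1/\mathrm{TE})^{\mathrm{TL}-1}$ explode for top predators and would
  dominate every interval.
* **PP level** is a single global draw from a normal fitted to the
  interannual totals of accessible-ocean production — a level shift, not
  per-cell resampling, because the uncertainty being modelled is in the
  global productivity estimate rather than its spatial pattern. A
  single-year PP archive makes the s.d. zero; this is permitted and
  flagged in the output (`pp_degenerate`).

Intervals are the ranked 2.5/97.5 percentiles (`quantile(type = 1)`, so
endpoints are realized trial values). With both variances zero every trial
collapses to the deterministic statistic to machine precision, which the
tests require at `1e-12`. Trials aggregate catch to carbon per trophic
level first, so cost scales with the number of distinct TLs, not records;
100,000-trial runs are cheap, and the suite checks a 1,000-trial interval
against one.

## Sourcing distance

Each consumed tonne belongs to one of four categories: domestic wild,
imported wild, imported mariculture, or domestic mariculture. Domestic
mariculture is assigned distance exactly zero — it is consumed where it is
farmed. Wild records use the great-circle (haversine, R = 6,371 km)
distance from the catch cell centre to the nearest port of the consuming
country; imported mariculture uses the minimum over all (origin coastal
cell, importer port) pairs. All distances are therefore minimum bounds:
real seafood often travels further via processing hubs, and no
processing/re-export chain is modelled.

Exports are traced to catch cells by a deterministic three-tier matcher:
exact (exporter, year, taxon) allocation pro-rata across that taxon's
cells; residue pooled across all the exporter's taxa that year; any
remainder flagged unmatched with a warning. The tiers are a design choice
— the matching problem is underdetermined from trade records alone — so
the matcher sits behind its own function and the synthetic trade generator
retains true provenance to validate it.

The yearly estimate is a catch-weighted median with a hierarchical
bootstrap: each of `n_trials` trials draws `n_samples` records, first
choosing the category with probability proportional to its published total
tonnage, then a record within the category (tonnage-weighted by default).
The per-trial statistic weights each sampled record by tonnage divided by
its selection probability. This matters: tonnage-weighted draws already
carry the weighting in their sampling frequency, so their importance
weights are constant and the statistic is the plain sample median, while
uniform within-category draws are reweighted — both modes estimate the
same catch-weighted median, and the coverage experiment in the test suite
(200 replicate record sets with known truth) checks the intervals do what
they claim. Shapiro–Wilk on the trial statistics (α = 0.05) records
whether their distribution looks normal; the median is reported regardless.
Ties in the weighted median resolve to the lower value, for determinism.

## Supply limits

With wild capture effectively static, future supply growth must come from
mariculture, whose feeds still require wild-sourced fishmeal. The model is
closed-form:

$$F = W \cdot fr, \qquad M = F \cdot fm \cdot rfm / ffm, \qquad
  S = W(1 - fr) + M$$

Defaults: $W = 105$ Mt/yr (reported plus IUU landings; range 94.5–126),
$fr = 0.36$ (0.25–0.45), $fm = 0.9$ (0.7–1.0), $rfm$ defaulting to the
midpoint 0.225 of its 0.21–0.24 range, and $ffm$ scenarios of 0.10, 0.07,
0.05. The midpoint default for $rfm$ is deliberate: it reproduces the
headline limits of 144/177/220 Mt after rounding to whole Mt, whereas the
alternative point value 0.22 gives 142/174/216; both are documented and
either can be supplied. Feed-to-product conversion is fixed at 100% — an
optimistic simplification that makes room for farmed filter feeders. Fish
oil is not modelled separately; it is folded into the reduction rate. The
derivative $\partial S / \partial fr = W(fm \cdot rfm / ffm - 1)$ changes
sign where $fm \cdot rfm$ crosses $ffm$: diverting more catch to fodder
raises the ceiling only while mariculture returns more than the diverted
fish would have provided directly. A ~200 Mt variant that adds
climate-driven productivity gains and currently discarded catch is
sometimes quoted alongside these limits; its combination rule is not
specified precisely enough to compute, so it is mentioned here and not
implemented.

`supply_sensitivity()` samples (W, fr, fm, rfm) independently — uniform
over each range by default, truncated normal on request; no joint
distribution is defended anywhere, so independence plus two families is
the transparent choice — and reports the mean, ranked 95% interval and
width-to-mean percentage. Under uniform sampling over the full ranges that
percentage is around 40%, driven almost entirely by the width of the $fr$
range; claims of much tighter spreads imply a much more concentrated
sampling scheme than the published ranges support, so the package reports
the spread rather than asserting any particular value.

## Demand projection

Consumption is regressed on global population by ordinary least squares
(a Gaussian identity-link GLM), on totals rather than per-capita values.
The fitted line is evaluated along the low / median / high population
scenarios to 2100 — a deliberately simple structure with no autoregression
— and crossing years are the first strict exceedance of a limit on annual
points, with no sub-year interpolation. Crossing years are monotone
non-decreasing in the limit, which the tests verify by exhaustive scan.

## The synthetic world

The generator produces what the analyses assume, with ground truth kept:

* **Grid.** Equal-angle cells; areas from the exact spherical band formula
  $R^2 \Delta\lambda (\sin\varphi_2 - \sin\varphi_1)$ with R = 6,371 km,
  so total area is $4\pi R^2$ to rounding. Resolution is a parameter
  (30-min cells at full scale, tiny grids in tests). Land is an i.i.d.
  mask; depths are uniform within a configured range.
* **Productivity.** A fixed lognormal spatial pattern (mean 150 t C
  km⁻² yr⁻¹, spatial CV 0.4–0.5 — open-ocean-to-shelf contrasts) times
  cell area, with small lognormal interannual noise (CV 0.05).
* **Countries.** Contiguous EEZ strips over a configurable share of sea
  cells, the rest high seas; ports at coastal cell centres; high-seas
  catches are attributed to the fishing country, mirroring EEZ-claim
  accounting.
* **Catches.** Calibrated so the implied PPR at (CR = 9, TE = 0.1) equals
  a target fraction of each seeded cell's mean PP, split across taxa by
  random shares and inverted through the trophic ladder —
  $C = \mathrm{PPR} \cdot \mathrm{CR} \cdot \mathrm{TE}^{\mathrm{TL}-1}$ —
  so the footprint recovers the target to 1e-9 (a round-trip the tests
  enforce). The default pipeline target of 0.12 puts the default world
  inside the exploitation bands; an effort trend multiplies tonnage
  year-on-year.
* **Trade and population.** Per-record export fractions with retained
  provenance; a linear consumption–population history (intercept −3×10⁷ t,
  slope 0.02 t/person — roughly the global per-capita order of magnitude —
  with 10⁶ t Gaussian noise) and three growth scenarios diverging after
  the historical window.

What the generator does **not** emulate: real coastline geometry, the
strong coastal concentration of both productivity and fishing, trade
networks with processing hubs, taxon-specific catchability, or any
co-calibration of national populations with catch volumes (per-capita
consumption values in the EEZ summary are therefore internally consistent
but not realistic in magnitude). Passing tests consequently demonstrate
that the estimators are correct and calibrated on worlds satisfying their
assumptions — not that any particular historical series is reproduced;
that would require the real catch, productivity and trade archives.

## Numerical and reproducibility choices

* One master seed per run; each stage derives a substream by hashing the
  stage name, so stages are individually rerunnable and re-ordering is
  harmless. All derived seeds stay below $2^{31}$.
* Truncated normal draws use the inverse-CDF transform; a zero s.d.
  returns the mean exactly, which is what makes the degenerate Monte
  Carlo collapse exact rather than approximate.
* Ranked percentile intervals use `quantile(type = 1)` so endpoints are
  order statistics of the actual trials.
* Weighted-median ties take the lower value; nearest-port ties take the
  lowest port index.
* Result bundles are written through a staging directory and moved only
  on success; the manifest stores an md5 of the canonical JSON rendering
  of the configuration, and identical configurations produce
  byte-identical bundles (asserted in the tests).
* Default problem sizes (a 12×24 grid, 10 years, 500–1,000 Monte Carlo
  trials, 200×2,000 bootstrap) keep a full pipeline run in seconds while
  leaving every statistic's sampling error small relative to the effects
  the tests assert; all sizes are configuration, and the acceptance
  script runs a larger 18×36 world.

## Known limitations

* PPR treats TE as globally constant per draw; real transfer efficiencies
  vary by ecosystem and trophic step.
* The distance estimate is a lower bound by construction and ignores
  processing chains and re-exports.
* The matcher's tier structure is one defensible resolution of an
  underdetermined matching problem; alternatives (e.g. price-weighted)
  would need trade-value data the package does not model.
* The supply model is static and aggregate: no species structure, no
  feedback from price or policy, fish oil folded into `rfm`.
* The projection inherits everything a linear population-driven model
  misses — saturation, dietary shifts, income effects.
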