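---
title: "Models and methods behind secscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secscreen)
```

`secscreen` analyses random clone-picking screens of secretion
signal-peptide (SP) libraries. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The occupancy model

After a pooled library of `N` constructs is transformed and plated, picking
`n` colonies is modelled as `n` independent draws with replacement: the
identity of each picked clone is a categorical draw over the `N` members
with weights `w` (uniform `1/N` for an unbiased pool). Three consequences
are exposed as closed forms:

* **Multiplicity.** For one member the number of recoveries is
  `X ~ Binomial(n, w_i)`, so `multiplicity_pmf()` is the exact binomial mass
  function. For the canonical campaign (`n = 66`, `N = 148`) it gives
  `r paste(sprintf("%.3f", multiplicity_pmf(66, 148, 1:4)), collapse = ", ")`
  for one to four recoveries.
* **Coverage.** `coverage_probability(n, N) = 1 - (1 - 1/N)^n`, computed via
  `log1p` for numerical stability. At fixed oversampling `k = n/N` and
  growing `N` it converges to `1 - exp(-k)`, which is why coverage targets
  are usually quoted per oversampling factor (~0.95 at threefold, ~0.98 at
  fourfold).
* **Design inversion.** `required_picks()` returns the smallest `n` meeting
  a coverage target. The closed-form ceiling is verified against the exact
  recurrence at the boundary, so floating-point rounding can never return an
  off-by-one pick count. Coverage 1 is unreachable with replacement and is
  rejected.

Two similarly named quantities are deliberately kept distinct. The
*per-member probability* `P(X = m)` has the member as its unit; the
*relative occurrence* of a campaign census divides the number of members
recovered exactly `m` times by the number of **picks**. Screening reports
often print the two side by side and call them comparable; they have
different denominators, and the package never equates them —
`multiplicity_pmf()` computes the first, `empirical_relative_occurrence()`
the second.

A note on printed comparisons: probabilities quoted at three decimals are
compared after rounding half away from zero (`round_half_away()`); base R's
round-half-to-even would disagree exactly at the printed boundaries. For the
two-recovery case the exact binomial value is
`r sprintf("%.6f", multiplicity_pmf(66, 148, 2))`, which rounds to 0.063; a
Poisson approximation with the same mean gives 0.0637. Reports that quote
0.064 for this quantity are consistent with the Poisson approximation, not
with the exact binomial, which the package retains.

## The picking simulator

`simulate_picks()` performs the categorical draws directly;
`replicate_campaigns()` repeats whole campaigns from a single stream seeded
once, so extending the replicate count reproduces every earlier campaign
bit-identically — incremental studies never invalidate earlier results. The
summary reports the min/mean/max member count per multiplicity, the "number
range" view used to judge whether an observed census is compatible with an
unbiased pool. Pool bias is modelled phenomenologically as
symmetric-Dirichlet weights (`dirichlet_library()`): a single concentration
parameter controls overdispersion, standing in for all mechanisms (plasmid
abundance after pooled cloning, transformation and growth bias) whose
aggregate effect is an uneven weight vector. The replicate count defaults to
10^4 in interactive use; tests use smaller sizes (a few hundred to a few
thousand campaigns) with Monte-Carlo standard-error tolerances, and the
acceptance computation uses 10^5 campaigns, where the exactly-once frequency
carries a standard error of ~0.0014.

## Assay reduction

The pNPP assay follows p-nitrophenol release at 410 nm; activity derives
from the blanked linear slope:

* `fit_slope()` — ordinary least squares of A410 on time (closed form),
  reported per minute with its r². A constant trace has slope 0 and r²
  defined as 0. An optional lag trim (`trim_lag = TRUE`) selects the
  contiguous tail window of at least five points with maximal r², for traces
  with mixing lag; the default uses all points.
* `blank_correct()` — subtraction of the water-blank slope.
* `activity_from_slope()` — Beer–Lambert inversion:
  `activity = slope / (ε d) × V_reaction/V_sample × dilution` in U/mL
  (numerically equal to kU/L; both unit labels are accepted on input and
  normalised to U/mL).

Defaults: ε = 15 cm²/µmol, 20 µL sample in 200 µL reaction, 25 s read
interval. The optical path length `d` is rarely reported with plate-reader
protocols; the default 0.58 cm is the liquid-column height of a 200 µL fill
in a standard cylindrical 96-well (≈6.6 mm diameter) and every measurement
records the `d` it used, so a path-corrected instrument can override it
transparently. Non-positive blanked slopes are reported as activity 0 with a
`below_detection` flag rather than as negative activities — activity tables
floor at zero. Supernatant dilution is a required input, never inferred:
"appropriately diluted" is an experimental decision, not a computable one.

## Phenotyping and classification

Replicates aggregate to mean ± sample SD (n−1; a single value has SD 0).
Relative activities are computed per host series as a percentage of that
series' maximum, so the argmax row is exactly 100 and normalization is
idempotent and scale-invariant. Ranking is by descending mean with
lexicographic tie-break on SP id, making the order total and reproducible.
SPs recovered in several clones stay as separate records (as activity tables
print them); cross-host pairing collapses them by mean.

A note on recomputing printed relative columns: published tables typically
compute relatives from unrounded means and then round both columns for
print. Recomputing the relative from the rounded activity column therefore
deviates by up to a few tenths of a percentage point on some rows (the
packaged fixture documents which); rows whose printed precision happens to
survive the double rounding (Epr, Vpr, LipB in the fixture's
*C. glutamicum* series) agree to 0.1.

`classify_clone()` assigns an unknown clone to every reference-panel entry
whose interval `mean ± k_sigma·s` contains its activity, with `s` the panel
SD and the clone's own SD combined in quadrature (standard error
propagation; the rule is a deliberate design choice, as published
classifications of this kind report outcomes but no decision rule). The
default `k_sigma = 2` reproduces the qualitative pattern such screens
report: a clearly superior SP is called uniquely, while weak SPs with
overlapping distributions form an ambiguity set that only sequencing can
resolve. When no interval matches, the nearest entry by standardized
distance is returned flagged `nearest_only` rather than silently forced.
`distinguishability_groups()` is the panel-level view: connected components
of pairwise interval overlap.

## Cross-host comparison

`pair_hosts()` inner-joins two max-normalized series on SP id (collapsing
repeats by mean; a per-clone mode keeps them). `crosshost_correlation()`
always reports both Pearson (on the relative values) and Spearman (mid-ranks
for ties); no hypothesis test is attached because the transferability
question is about effect size, not significance. Zero-variance series yield
`NA` with an explanatory note rather than an error.

`concordance_classes()` labels pairs: discordant when the two relatives
differ more than `ratio_threshold`-fold (default 4), with both values
floored at 2 percentage points so that a 0%-vs-5% pair does not produce an
infinite ratio; otherwise concordant, split high/low at 50% on both axes.
The defaults label the canonical examples correctly — an SP at 85% vs 8% is
discordant, one at 85% vs 64% concordant-high — and the labelling is
symmetric under swapping hosts. The thresholds are reporting conventions,
not fitted parameters; any analysis hinging on a borderline pair should vary
them.

## The synthetic-data generator

The generator emulates the campaign the statistics assume: a library of `N`
members with selection weights, a latent true activity per member, clone
picks drawn with **the same categorical sampler the simulator uses** (so a
generated campaign's multiplicity census equals `simulate_picks()` under the
same seed), replicate activities `true × (1 + N(0, cv))` truncated at zero,
and kinetic traces whose slope is the exact algebraic inverse of the assay
conversion (so zero-noise traces round-trip to the input activity to machine
precision).

Defaults and why: true activities come either from resampling the packaged
activity table's *C. glutamicum* means (`mode = "fixture"` — the empirical
spread of a real SP library, ~0–13 U/mL, many weak and few strong secreters)
or from a log-normal (`mode = "lognormal"`), the standard model for
strictly positive, right-skewed expression phenotypes. The replicate CV
defaults to 0.15, mid-range of the relative SDs real activity tables show
(roughly 1–80%); absorbance noise is additive Gaussian per read (default
0.005 in tests, a typical plate-reader read noise). Negative replicate draws
truncate to zero rather than being resampled, matching the assay floor.

What the generator does **not** emulate: growth dynamics and harvest
timing, substrate depletion or product inhibition in the assay (traces are
linear by construction), systematic plate effects, and any mechanistic
link between SP sequence and activity. Passing the synthetic round-trip
tests therefore shows the *arithmetic* of the pipeline is self-consistent;
it says nothing about non-linear traces or biased plates in real data.

For the top-rank recovery property (the best secreter among the picked
clones is ranked first), the truth oracle needs almost-surely distinct true
activities, so the property is evaluated under the log-normal mode; fixture
resampling duplicates printed values (including near-ties ~1% apart, below
the resolution of 8 replicates at CV 0.1) and would make "the best SP"
ill-defined. The shipped check uses 200 seeded campaigns of 30 clones × 8
replicates from a 40-member library — small enough that the whole suite
runs in seconds, large enough that the ≥95% recovery bound has a
comfortable deterministic margin at the fixed seeds.

## Numerical and interface choices

* All randomness flows from explicit integer seeds; every seeded function
  restores the caller's RNG state, so package calls never perturb a user's
  stream.
* Coverage and required-pick computations use `log1p` and boundary
  verification against the exact recurrence.
* CSV output is one fixed dialect (comma, UTF-8, `.` decimal, mandatory
  header), numeric columns carry unit suffixes, and writes are atomic
  (write-then-rename), so a crashed run never leaves a truncated table.
* `run_pipeline()` is deterministic given config and seed (the run log's
  timestamp aside) and records versions, seed and all parameters in force.

## Known limitations

* The occupancy model is with-replacement only; for campaigns that pick a
  large fraction of a *finite colony pool* a hypergeometric model would
  differ, but the intended regime (colonies vastly outnumber picks) is
  with-replacement by construction.
* Interval-overlap classification ignores multimodality and assumes
  roughly symmetric replicate scatter; panels with strongly skewed
  distributions would need a quantile-based rule.
* The concordance labels are threshold conventions; they are stable for
  clearly concordant/discordant SPs and intentionally conservative near the
  boundaries (a 14.5% vs 57.2% pair sits just inside the 4-fold ratio after
  flooring and is labelled concordant-low, not discordant).
* The packaged two-host table is a transcription of a printed table and
  inherits its rounding and row-count caveats (see `?load_table1`).
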