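# secscreen

Statistics and data reduction for random clone-picking screens of secretion
signal-peptide (SP) expression libraries.

When a pooled plasmid library (one construct per SP fused to a reporter
enzyme) is transformed into an expression host and colonies are picked at
random, three questions dominate the campaign: *how many clones must be
picked to see every library member*, *is the observed recovery pattern
compatible with an unbiased pool*, and *which SPs secrete best — and does
that ranking transfer to another host*. `secscreen` answers all three for
the canonical setup of a ~150-member Sec SP library screened with a
chromogenic cutinase activity assay, and generalises to any library size.

## The model

Picking is sampling with replacement: each of `n` picks lands on library
member `i` with probability `w_i` (uniform `1/N` for an unbiased pool of `N`
members). For one member the number of recoveries is binomial,

    P(X = m) = C(n, m) (1/N)^m (1 - 1/N)^(n - m),

the coverage of a designated member is `P(X >= 1) = 1 - (1 - 1/N)^n ≈
1 - e^(-k)` at oversampling `k = n/N`, and the expected number of members
recovered exactly `m` times is `N * P(X = m)`. A seeded Monte-Carlo
simulator draws whole campaigns (optionally with symmetric-Dirichlet biased
weights) to put ranges around those expectations.

Phenotypes come from kinetic p-nitrophenyl-palmitate (pNPP) traces: the
blanked least-squares slope of A410 against time converts to volumetric
activity via the molar extinction coefficient `ε` (15 cm²/µmol) and path
length `d`,

    activity [U/mL] = slope [1/min] / (ε d) × V_reaction / V_sample × dilution,

with U/mL numerically equal to kU/L. Replicates are aggregated
(mean ± sample SD), max-normalized per host series, ranked, and unknown
clones are classified against a reference panel by interval overlap at
`k_sigma` combined standard deviations. Cross-host transfer is quantified by
Pearson and Spearman correlation of paired per-SP relative activities plus a
concordant/discordant labelling.

## Worked example

```r
library(secscreen)

# design: how safe is a 66-pick campaign on a 148-member library?
multiplicity_pmf(66, 148, 1:4)
#> [1] 0.2870102970 0.0634546575 0.0092088392 0.0009866613
coverage_probability(c(3, 4) * 148, 148)
#> [1] 0.9507172 0.9819313
required_picks(0.95, 148)
#> [1] 442
```

So a randomly picked clone pool recovers any given SP exactly once with
probability 0.287 and twice with 0.063; threefold oversampling (444 picks)
sees a designated member at least once with probability ~0.95, and 442 picks
are the exact minimum for 95% coverage.

```r
# phenotyping the packaged two-host cutinase table
tab <- load_table1()
rec <- normalize_by_max(data.frame(sp_id = tab$sp_id, host = tab$host,
                                   mean_activity = tab$mean_activity_U_per_mL))
head(rank_sps(rec[rec$host == "C_glutamicum", ]), 3)
#>   sp_id         host mean_activity relative_activity_pct
#> 1   Epr C_glutamicum          13.1             100.00000
#> 2  YwfM C_glutamicum          11.2              85.49618
#> 3   Bpr C_glutamicum          11.1              84.73282

# does SP performance transfer between hosts?
a <- tab[tab$host == "C_glutamicum", ]; b <- tab[tab$host == "B_subtilis", ]
pairs <- pair_hosts(a, b)
concordance_classes(pairs)[1:3, ]
#>   sp_id rel_host_a rel_host_b concordance_class
#> 1  YwfM       85.5        7.7 discordant_a_high
#> 2   Bpr       84.8       63.6   concordant_high
#> 3   Vpr       80.2       47.1    concordant_low
```

YwfM is the archetypal discordant SP: 86% of the maximum in
*C. glutamicum*, 8% in *B. subtilis* — the best SP in one host need not
even be usable in another.

An end-to-end run (design report, picking simulation, phenotype table,
cross-host comparison, run log) is one call:

```r
run_pipeline(list(preset = "paper", seed = 1, out_dir = "out"))
```

## Scope

The package covers campaign statistics and assay data reduction only. Strain
construction, cultivation robotics, growth-curve triggering and SP sequence
analysis are out of scope, as are without-replacement (hypergeometric)
picking models and mechanistic secretion kinetics.
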