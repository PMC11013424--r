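---
title: "Estimating lipophilicity from RP-TLC retention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lipophilicity from RP-TLC retention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmzero)
```

## The measurement model

Reversed-phase TLC mimics membrane partitioning: a compound spotted on
alkyl-bonded (RP-18) silica is developed in a water–organic mobile phase,
and its retention factor $R_F \in (0,1)$ — migration distance relative to
the solvent front — reflects how strongly it partitions into the nonpolar
stationary phase. The working quantity is

$$R_M = \log_{10}\!\left(\frac{1}{R_F} - 1\right),$$

the base-10 logit of $1 - R_F$. For a fixed compound, $R_M$ is to good
approximation linear in the volume fraction $C$ of organic modifier:

$$R_M = R_{M0} + b\,C, \qquad b < 0,$$

and the intercept $R_{M0}$ — the value extrapolated to a purely aqueous
mobile phase — is the chromatographic lipophilicity index. Replicate $R_F$
readings are averaged *before* the transform, in $R_F$ space, because that
is the measured quantity and the logit is nonlinear; one averaged point per
concentration then enters an ordinary least-squares fit.

Two caveats are built into the fit report rather than hidden. First, the
measured window (here 50–85% v/v) sits far from $C = 0$, so $R_{M0}$ is a
long extrapolation; `fit_retention_line()` records the leverage of the
extrapolation point ($1/n + \bar C^2 / S_{xx}$) but, following standard
chromatographic practice, does not reject it. Second, a series with constant
$R_M$ has an undefined correlation; it is returned as a flagged degenerate
fit (`b = 0`, `r = NA`) instead of an error, so batch processing continues.

`qc_retention_fits()` flags fits with $|r|$ below a threshold (default 0.99
— routinely achievable on well-behaved plates, and configurable), with
non-negative slopes (retention must decrease with modifier strength in a
reversed-phase system), or with too few levels (default minimum 3; the
packaged study used 8).

## Calibration to absolute logP

$R_{M0}$ is only a relative index; anchoring it to the logP scale uses
standards of known literature logP chromatographed under identical
conditions. `fit_calibration()` regresses $\log P_{lit}$ on $R_{M0}$ and
reports the conventional calibration statistics: Pearson $r$, standard
error of estimate $s = \sqrt{SSE/(n-2)}$, and the regression
$F = r^2(n-2)/(1-r^2)$. `apply_calibration()` then maps any $R_{M0}$ to
$\log P_{TLC}$. The packaged five-standard set (acetanilide through
p,p′-DDT, logP 1.21–6.38) gives

```{r calibration}
std <- read_calibration_standards(
  system.file("extdata", "calibration_standards.csv", package = "rmzero"))
fit_calibration(std)
```

Two coefficient routes are supported, and the choice deserves a note. The
packaged standards carry $R_{M0}$ at two decimal places; refitting from them
gives slope 1.2905 and intercept 0.1996 ($F \approx 442$). The study that
produced these tables reports slope 1.2838 and intercept 0.2138
($F = 459.32$), evidently computed from unrounded $R_{M0}$ values that are
not recoverable from the published precision. The package therefore defaults
to refitting from the supplied standards (`calibration = "refit"`), and
offers `fixed_calibration(slope, intercept)` /
`calibration = "fixed"` to apply externally published coefficients exactly.
The two routes agree to two decimals for most compounds — e.g. $R_{M0} =
3.15 \mapsto 4.26$ and standard II ($R_{M0} = 1.16$) $\mapsto 1.70$ under
both — but a few third-decimal differences are unavoidable, which is why
reported values are rounded half-away-from-zero to two decimals
(`round_half_up()`) while full precision is kept internally.

## Concordance between experimental and calculated logP

With eight calculation algorithms in play, three summaries matter:

* `correlation_matrix()` — Pearson correlation (Spearman behind a flag, as a
  robustness check) of each algorithm column with the experimental column,
  with pairwise deletion of missing cells;
* `spread_summary()` — per-compound max − min across algorithms, locating
  the structure the algorithms disagree about most;
* `range_summary()` — global extrema with their (compound, method)
  coordinates.

Constant columns arise in practice (the packaged predicted-ADME table has
human intestinal absorption saturated at 100% for every compound), and a
correlation against a constant is mathematically undefined. The package
reports that as an explicit "undefined (zero variance)" row rather than
$r = 0$ — zero would assert "no association", which is not what the data
say — and `pearson_r()` raises a classed condition that
`adme_correlation_screen()` converts to data. No multiple-testing correction
is applied across the screen; the p-values are descriptive, and the screen's
purpose is ranking, not inference.

## Clustering

Similarity structure over methods (columns) and compounds (rows) uses
Euclidean distances and single-linkage agglomeration, the combination under
which the packaged study's dendrograms were produced. `single_linkage()` is
a direct implementation of bottom-up agglomeration with the minimum-pairwise
inter-cluster distance and a deterministic tie-break (the pair earliest in
cluster-creation order merges first); single linkage is reducible, so merge
heights are non-decreasing, and the test suite verifies the implementation
against exhaustive brute-force agglomeration (all random matrices with
$n \le 7$), against `stats::hclust`, and against the minimum-spanning-tree
identity (sorted merge heights = sorted MST edge weights).

All logP columns share the log10 scale, so distances default to raw values;
`standardize = TRUE` z-scores each variable first for tables mixing scales.
Because published dendrograms rarely state whether variables were
standardized, cluster memberships recovered from such figures are treated as
soft, report-level checks: with the packaged tables, the raw-value $k = 3$
cut of the compound dendrogram cleanly separates the allyl/propargyl
naphthoquinothiazines (16, 17, 20, 21) and the intermediate group (3, 7, 13,
14, 15, 18, 19), matching the published grouping, but the package does not
hard-assert figure-derived memberships.

`export_dendrogram()` writes Newick with the midpoint height convention
(leaves under a merge at height $h$ sit at depth $h/2$, so the tree is
ultrametric); `as.hclust()` converts to the base-R class for plotting.

## Drug-likeness rules

Four classical oral-bioavailability filters over a descriptor table:

| rule | criteria | aggregation |
|---|---|---|
| Lipinski | MW ≤ 500; HBD ≤ 5; HBA ≤ 10; logP ≤ 5 | ≥ 3 of 4 (configurable to all-4; with four criteria, ≥3-of-4 equals the classical "at most one violation") |
| Ghose | MW ∈ [160, 480]; logP ∈ [0.4, 5.6]; atoms ∈ [20, 70]; molar refractivity ∈ [40, 130] | all |
| Veber | rotatable bonds ≤ 10; TPSA ≤ 140 Å² | all |
| Egan | TPSA ≤ 131.6 Å²; logP ≤ 5.88 | all |

All interval bounds are inclusive. Egan's published model is an elliptical
confidence region in the (PSA, logP) plane rather than a box; the default
bounds here are the region's axis extents, which is how common screening
platforms operationalise it, and both are configurable
(`egan(psa_max =, logp_max =)`). Which logP flavor feeds the rules is the
caller's choice — descriptor tables carry a single `logp` column, and the
caller decides which estimator fills it. Per-criterion flags are computed
independently of the aggregation policy, so changing the policy can never
alter a criterion row, only the overall verdict.

## The synthetic plate generator

`simulate_plate()` emulates the study design the retention module targets:
eight modifier levels from 50 to 85% v/v in 5% steps, a linear $R_M$–$C$
relationship with negative slope per compound, Gaussian noise added in $R_F$
space (where measurement error actually lives), clipping to $[0.01, 0.99]$
(mirroring the transform's domain — a spot indistinguishable from the origin
or front would be remeasured, not transformed), and averaging of replicates
(default 3, as in routine practice) before the transform. Default truth
ranges — $R_{M0} \in [3.15, 4.60]$, $b \in [-0.0582, -0.0383]$, noise sd
0.01 — are the observed extrema for the packaged compound class, with slope
steepening as $R_{M0}$ grows (as observed: more lipophilic compounds need
stronger eluents) so that noise-free $R_F$ stays on-plate across the
gradient. Each compound draws from its own seed stream derived from the
global seed, so extending a design never perturbs existing compounds' data.

What the generator does *not* emulate: nonlinear $R_M$–$C$ curvature at
gradient extremes, spot tailing, plate-to-plate batch effects, or
heteroscedastic densitometry error. Passing recovery tests therefore shows
the estimator chain is correct under the stated model, not that real plates
are this well behaved.

Two recovery regimes are exercised. Noiseless simulation must invert
exactly (recovered $R_{M0}$, $b$ within $10^{-9}$ — a correctness check on
the whole transform–fit chain). Under the study design with noise (sd 0.01,
3 replicates, 200 compounds) the mean absolute $R_{M0}$ error must stay
below 0.15, a bound frozen from an independent Monte-Carlo run of the same
design before the module was written (observed ≈ 0.09; the extrapolation to
$C = 0$ amplifies plate noise roughly twofold, which is the cost of the
index being an extrapolated intercept).

## Pipeline and reproducibility

`run_full_analysis()` chains the stages behind a single validated
configuration object (`run_config()` — a named-list constructor, the natural
R idiom for a package-level API; `validate_config()` returns *all*
violations as data rather than failing at the first). Retention input is
either raw long-format measurements or a precomputed fit table; stages
beyond calibration are optional and disabling one cannot change another's
output. Reports are plain CSV/JSON/Newick with an MD5-checksummed manifest,
and reruns with identical inputs are byte-identical. Reported logP values
use two decimals, correlations three, matching the field's tables.

Problem sizes in the shipped tests and acceptance script — 21-compound
tables, 200-compound recovery benchmarks, 500 random matrices ($n \le 7$)
for the clustering oracle, 120 replicate calibration fits — were chosen to
make the statistical checks stable at comfortable margins while keeping a
full run fast on a laptop.

## Known limitations

* Only the linear $R_M$–$C$ model is implemented; quadratic variants used
  for wide gradients are out of scope.
* Calibration is unweighted OLS; errors-in-variables regression (both
  $R_{M0}$ and $\log P_{lit}$ are measured) is not offered.
* Single linkage only, matching the target workflow; it chains on elongated
  clusters, and no other linkage or bootstrap support is provided.
* Descriptor computation from structures (SMILES → MW/TPSA/...) is out of
  scope; the rule engine consumes descriptor tables.
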