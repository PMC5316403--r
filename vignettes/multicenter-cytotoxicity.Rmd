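---
title: "Multicenter concentration-response analysis for acute hepatotoxicity panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicenter concentration-response analysis for acute hepatotoxicity panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytotoxpanel)
library(dplyr)
```

## The problem

Simple hepatic cell models — HepG2 clones, HepaRG, Upcyte hepatocytes and
primary human hepatocytes (PHH) — are routinely used with basic cell-health
endpoints (intracellular ATP, resorufin formation from resazurin) to screen
compounds for drug-induced liver injury (DILI) risk. When several
laboratories run the same harmonized protocol on the same compound panel,
the analysis has to answer a chain of questions: what is each compound's
cytotoxic potency (EC50) in each cell model; when are two dilution series
*really* different; how reproducible are the profiles across laboratories,
donors and clones; does potency alone, or potency scaled by therapeutic
exposure (EC50/Cmax), separate DILI from non-DILI compounds; and which cell
models behave alike?

`cytotoxpanel` implements that chain as composable, tested stages operating
on a tidy well-level table, and pairs it with a synthetic multicenter data
generator with known ground truth so that every stage can be validated end
to end. The packaged compound panel is a fixed 13-compound training set
(9 DILI-implicated, 4 without known DILI liability), each with a 7-point
dose grid in µM and a therapeutic Cmax in µM.

## The concentration-response model

Raw signals are first normalized per experimental block
`(cell_model, site, unit, endpoint, exposure_h, run)` to the mean of that
block's vehicle (0.5 % DMSO) wells, giving percent viability. Each dilution
series is then fitted with the constrained two-parameter sigmoid

$$V(c) = \frac{\mathrm{Top}}{1 + 10^{\,\log_{10} c - \log_{10} EC_{50}}}
       = \mathrm{Top}\cdot\frac{EC_{50}}{EC_{50} + c},$$

a log-concentration logistic with the lower plateau fixed at 0 and the Hill
coefficient fixed at −1. The free parameters are Top (bounded to (0, 150] %,
optionally fixable at 100) and $\log_{10} EC_{50}$. Because Top enters the
residual sum of squares quadratically, it is profiled out in closed form;
the remaining one-dimensional objective in $\log_{10} EC_{50}$ is minimized
by a deterministic dense grid of starts (0.05 log10 spacing, two decades
beyond the tested range on each side) followed by local refinement. This
multi-start scheme is deterministic, avoids local minima without
randomness, and in tests matches an exhaustive grid-search oracle.

Technical replicates enter as individual residuals, never as means: this
preserves the residual degrees of freedom the F-test below relies on.
Vehicle wells (c = 0) are used only for normalization, never as fit points
(log of zero is undefined). Leaving Top free is the default because the
fit as stated constrains exactly two parameters (bottom and slope) and a
free Top absorbs normalization drift; `fit_options(fix_top = 100)` gives
the stricter variant.

### The no-fit rule

"No decrease in viability" is operationalized with two numeric teeth, both
exposed in `fit_options()`: a series is `no_fit` when (a) the optimizer did
not converge, (b) mean viability at the highest tested concentration stays
above 80 % of control, or (c) the fitted EC50 exceeds the highest tested
concentration. Both thresholds are deliberately conservative: a compound
failing them provides no usable potency estimate within its tested range.

## Comparing two dilution series

Whether two series differ is decided by an extra-sum-of-squares F-test
between nested models: the null fits *one* shared (Top, log10 EC50) curve
to the pooled points; the alternative is the pair of separate fits. With
$RSS_0, df_0 = n_a + n_b - 2$ and $RSS_1 = RSS_a + RSS_b,
df_1 = n_a + n_b - 4$,

$$F = \frac{(RSS_0 - RSS_1)/(df_0 - df_1)}{RSS_1/df_1},$$

with the p-value from the upper tail of $F(df_0 - df_1,\; df_1)$. Sharing
*both* parameters in the null is the strictest nested reading of
"difference between two dilution series" as whole-curve identity. A
difference is only declared when **both** parts of the dual rule hold:
p < 0.05 (strict) *and* the EC50 fold-ratio
$\max(EC_{50,a}/EC_{50,b},\, EC_{50,b}/EC_{50,a})$ exceeds 3 (strict). The
fold gate enforces biological relevance: with many residual degrees of
freedom the F-test detects arbitrarily small horizontal shifts, and the
gate is the stated guard against significant-but-tiny differences — no
multiple-testing correction is applied, deliberately. Zero-residual
degenerate comparisons are resolved in the continuous limit (F → ∞, p → 0
when the curves differ; p = 1 when they coincide), so the verdict is then
decided by the fold gate alone. If either member is `no_fit`, the verdict
is `no_fit` and carries no statistics.

## Variability coefficients

Reproducibility is summarized per stratum as the *variability coefficient*:
the number of pairwise comparisons judged different divided by the number
of all pairwise comparisons, with `no_fit` pairs kept in the denominator
(they are comparisons that were made) and reported as their own category.
`enumerate_pairs()` builds the pair lists: site pairs within cell model,
unit, compound, endpoint, time and run (`inter_lab`); run pairs within a
laboratory (`intra_lab`); donor pairs within PHH irrespective of site
(`inter_donor`, since donors are allocated to sites); HepG2 clone pairs
within a site (`clone`); and fresh-versus-cryopreserved pairs of the same
cell type (`fresh_vs_cryo`). Where several runs exist, inter-laboratory
pairs are run-matched (run 1 of site A with run 1 of site B); comparing
run-averaged series instead is possible by fitting averaged inputs, but
run-matching keeps the per-comparison degrees of freedom explicit.

## Margin-of-safety classification

Potency alone does not separate DILI from non-DILI compounds
(`separation_check()` tests whether any single EC50 cutoff perfectly splits
the labels and counts inversions). Scaling by exposure does better: each
compound's aggregated EC50 (geometric mean across fitted series) is divided
by its therapeutic Cmax, and the compound is flagged potentially
hepatotoxic when EC50/Cmax falls *strictly below* a threshold, 20 by
default; an exact tie is non-toxic. `no_fit` compounds can never be flagged
— they showed no measurable cytotoxicity in range — so flat non-responders
are false negatives by construction, which is exactly the behavior such a
screen exhibits for compounds whose toxicity requires mechanisms (e.g.
immune-mediated) that a 3-day viability assay cannot express.
`threshold_sweep()` reports sensitivity (flagged DILI / all DILI) and
specificity (unflagged non-DILI / all non-DILI) over a threshold grid,
keeping no-fit compounds in denominators but never in numerators.

## Concordance and clustering

`endpoint_correlation()` pairs ATP and resorufin measurements at identical
experimental coordinates and reports their Pearson correlation — per well
on percent viability by default (the headline concordance number is a
well-level statement over all compounds, times and cells), or per series on
fitted log10 EC50s. `paired_time_test()` applies a two-sided paired
Student's t-test to matched 24 h/72 h log10 EC50 differences, dropping (and
counting) pairs with a `no_fit` member; an all-identical-difference vector
is degenerate and resolved by convention (p = 1 for zero shift, p = 0 for a
nonzero constant shift).

For clustering, `build_ec50_matrix()` assembles compounds × cell-model
instances of log10 EC50; missing (no-fit) cells are either dropped row-wise
(default, the least inventive policy) or right-censored at log10 of the
compound's highest tested dose, flagged as censored. Rows are mean-centered
and sigma-normalized (z-scored); zero-variance rows are dropped with a
warning. Columns are clustered by complete (maximum) linkage. "Maximum"
naming is genuinely ambiguous between the *linkage* and the *distance*;
the package reads it as complete linkage and makes the metric a choice —
Euclidean by default, Chebyshev ("maximum distance") available — and the
test suite exercises both. Ties are broken deterministically by column
label order. Dendrograms serialize to Newick via `ape`.

## The synthetic generator: what it emulates and what it does not

`generate_dataset()` draws, for a configurable multicenter design, every
combination of block × run × endpoint × exposure × compound × grid dose ×
technical triplicate plus six vehicle wells per block. Its statistical
structure mirrors the assumptions of the analysis:

* true EC50s per compound × cell model, with flat **non-responders** as a
  compound property (not stochastic);
* site, unit (donor/clone/lot) and run effects acting on **log10 EC50** —
  horizontal curve shifts, matching the EC50-centric comparisons — not on
  Top;
* additive Gaussian well noise on percent viability, truncated at 0,
  matching how residuals enter the least-squares fit;
* raw signals formed as viability × block vehicle mean × lognormal
  vehicle noise, so normalization is itself exercised;
* at 24 h, EC50s shift up by a configurable log10 increment (shorter
  exposure is less sensitive).

Defaults: 3 sites for PHH-like and HepG2-like models and 2 for the others,
with one reference donor shared by all PHH sites; 2 runs; 5 % well noise;
0.15 log10 between-site SD; 0.05 log10 donor and run SDs; 10 % vehicle CV;
true EC50s anchored at the 5th of 7 grid doses (so the top dose sits well
past the EC50 but truncation at 0 stays negligible); 24 h shift
0.3 log10. The within-run variance defaults are scenario parameters chosen
as realistic for plate-based viability assays, not measured facts.

What the generator does **not** emulate: plate-geometry or edge effects,
compound-specific curve shapes (the Hill slope is exactly −1 by
construction, so fits cannot be misspecified), mechanistic toxicity, or
donor-by-compound interactions. Passing recovery and calibration tests
therefore demonstrates that the *pipeline logic* is correct under its own
model assumptions — not that real multicenter data will be this
well-behaved.

### Preset scenarios

* `default` — the full design above; ground-truth recovery is checked as
  the median absolute log10 error of estimated vs true EC50s (< 0.15).
* `null_interlab` — two sites, zero site/unit/run shifts, used to check
  F-test calibration. Its vehicle CV is set to ~0 on purpose: with noisy
  vehicle wells each series is rescaled by its own block's estimated
  vehicle mean, which makes two "identical" series differ by a small
  multiplicative Top factor — the whole-curve null would be false by
  construction and the scenario would no longer measure calibration.
  (This also documents a real property of the statistic: vehicle-well
  noise inflates whole-curve rejection rates in practice.)
* `phh_like` — three PHH-like sites whose true EC50s place the 8
  fit-able DILI compounds at margin 5, one control (entacapone) at margin
  10 and the remaining controls well above 20, with the ninth DILI
  compound a flat non-responder; at threshold 20 and 72 h exactly 8/9 and
  1/4 classify toxic. This is a construction patterned on the qualitative
  published outcome, not a fit to any experimental data.
* `clustered` — five donor columns share one profile and three cell-line
  columns a clearly different one (±0.6 log10 alternating around the 4th
  grid dose, inside every tested range), so the correct top-level split is
  known.
* `attenuation` — one block, both endpoints sharing the latent dose-
  response with independent 5 % noise; the observed endpoint correlation
  must equal the closed-form attenuation
  $\mathrm{var}(L)/(\mathrm{var}(L)+\sigma^2)$ within Monte-Carlo error.
  EC50s sit at the 6th grid dose here so the latent viability stays ≥ 25 %
  and truncation does not bias the formula.

All randomness flows from the single integer seed passed to
`generate_dataset()`; the same seed and configuration reproduce the
dataset byte for byte.

## Numerical choices and degenerate inputs

* log10 EC50 search interval: tested range ± 2 decades; profile grid step
  0.05 with `optimize()` refinement (tolerance 1e−9).
* A free Top is clamped to (0, 150]; fits with fewer than 5 distinct
  concentrations are refused.
* `rss_0` is floored at `rss_1` (nested models cannot invert) to guard
  against optimizer slack; F is then guaranteed non-negative.
* Under-determined comparisons (`df_1 < 1`) are an error, not a silent NA.
* Normalization refuses blocks with fewer than 3 vehicle wells or a
  non-positive vehicle mean, naming the offending block.
* Strict inequalities throughout the decision rules (p < 0.05, fold > 3,
  margin < 20), as printed constants of the analysis.

## Problem sizes used in the test suite

The suite validates on deliberately compact instances: the full default
scenario (≈31k wells, ≈2,900 series) once for recovery; 77 two-site null
datasets (1,001 pairs) for F calibration; 40 pairs each at true fold 2.5
and 5 for the dual rule; 12 null pairs × 400 residual permutations for the
permutation cross-check of the parametric p-value; 10 seeds for the
attenuation identity. These sizes give Monte-Carlo error comfortably below
the tested tolerances while keeping the suite fast.

## Worked example

```{r example, eval = FALSE}
library(cytotoxpanel)
panel <- load_panel()
sc <- preset_scenarios(panel)$phh_like
d <- generate_dataset(panel, sc$design, sc$params, seed = 7)
fits <- fit_all(normalize_to_vehicle(d$wells))
agg <- aggregate_ec50(fits[fits$exposure_h == 72 & fits$endpoint == "ATP", ])
classify_margins(compute_margins(agg, panel), threshold = 20)
```

See the README for the printed output and `run_pipeline()` for the
one-call orchestration that writes the full CSV/Newick/manifest bundle.

## Known limitations

* The F-test's nominal level relies on the model being exactly true;
  vehicle-well noise, truncation at 0 and Hill-slope misspecification all
  push rejection rates up in real data (the null scenario shows the clean
  case at ≈5 %).
* Aggregation to one EC50 per compound × model is an unweighted geometric
  mean over fitted series; no variance weighting is attempted.
* Cmax is an input; nothing is predicted pharmacokinetically, and the
  total-versus-free Cmax question is outside the package's scope.
* The variability coefficient is a proportion, not a variance-component
  decomposition; it depends on the pair enumeration and on assay power.
```
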