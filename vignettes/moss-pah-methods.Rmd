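---
title: "Reconstructing historical PAH deposition from herbarium mosses: models and design choices"
author: "mossPAH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing historical PAH deposition from herbarium mosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossPAH)
```

## The problem

Mosses take up airborne pollutants directly from deposition — they have no
roots or cuticle to speak of — so their tissue burden of polycyclic
aromatic hydrocarbons (PAHs) is a quantitative record of atmospheric
contamination at the time they grew. Dated herbarium specimens therefore
let us read decade-scale deposition history in regions where no
instrumental record exists. mossPAH implements the full analysis chain for
such a study: targeted GC-MS quantification, censoring-aware
preprocessing, period summarization, trend statistics and
diagnostic-ratio source apportionment, together with a seeded synthetic
generator that emulates a 42-specimen, five-decade survey so that every
stage is testable without instrument data.

## The compound panel and the weight-class split

The panel (`defaultPanel()`) is the 16 US-EPA priority PAHs plus retene,
benzo[e]pyrene and perylene — three compounds routinely added in
atmospheric work. Panels are data (CSV/YAML via `readPanel()`), not code,
because targeted methods differ between laboratories.

The low/high molecular weight (LMW/HMW) split is by *benzene* ring count:
LMW means fewer than four six-membered aromatic rings. The distinction
matters for one compound in particular: fluoranthene has four fused rings
but only three of them are benzene rings, so it is LMW. Only this
convention makes the LMW/HMW accounting of period summary tables close
exactly (per sample, total PAH = LMW sum + HMW sum). Ring counts are
curated inputs, not parsed from structures.

## Quantification model

Quantification follows the classical internal-standard method. For each
compound a 6-point calibration regresses the area ratio
$y = A_{analyte}/A_{IS}$ on the amount ratio $x = m_{analyte}/m_{IS}$ by
ordinary least squares (`fitCalibration()`; $1/x$ weighting is available
for calibrations spanning orders of magnitude, but unweighted is the
default because the regression variable choice is otherwise
unconstrained). Back-calculation inverts the line and scales by the
internal-standard spike (default 1600 ng = 200 µl of an 8 µg ml⁻¹ mix)
and the specimen dry mass:

$$c = \frac{(y - b)/a \cdot m_{IS}}{m_{dry}} \quad [\mathrm{ng\,g^{-1}}]$$

Values below the compound's limit of quantification (LOQ) are *censored*:
they carry no number, only a flag. The boundary is strictly below — a
value exactly at the LOQ is retained. Negative back-calculated amounts
are reported as censored, never as negative concentrations. Recovery
correction (`recoveryCorrect()`) divides each concentration by the
recovery fraction of its paired deuterated standard; it is optional and
off by default, since how recovery standards enter the final numbers is a
per-laboratory policy.

## Preprocessing rules

Downstream statistics use three deliberately simple rules:

* **Censored → 0** (`replaceCensored()`): censored cells become zeros.
  No maximum-likelihood or Kaplan–Meier censored estimators are offered;
  with ~75% censoring concentrated in compounds that are then removed by
  the prevalence filter, zero replacement is transparent and matches the
  workflow this package reproduces.
* **Prevalence filter** (`prevalenceFilter()`): keep compounds detected
  in at least 20 of 42 samples, generalized as `ceiling(20/42 * n)`; an
  absolute threshold overrides the fraction. Under the default synthetic
  conditions exactly naphthalene, phenanthrene, fluoranthene and pyrene
  survive.
* **Log transform** (`logTransform()`): $\ln(x + \delta)$ with
  $\delta = 1$ ng g⁻¹ by default, so zeros map to zero and ordering is
  preserved; a half-minimum-positive offset can be supplied instead. An
  offset of zero is refused whenever zeros are present.

Grouping is total: every sample gets one decade bin
(`decadeOf()`; the sparse 1930s are merged into the 1920s, so year 1932
is binned "1920s") and one fuel era (`eraOf()`; coal through the 1940s,
oil from the 1950s).

## Period summaries

`periodSummary()` uses two conventions side by side, and that duality is
deliberate: per-compound period means are *conditional* on detection
(mean over uncensored values only, suppressed entirely when fewer than
two samples detected the compound — single detections report only the
range up to the maximum), while the LMW/HMW/ΣPAH aggregates are
*zero-filled per-sample sums* averaged over all samples. Conditional
means answer "how much was there when we saw it"; zero-filled aggregates
keep the accounting identity ΣPAH = LMW + HMW exact. Published survey
tables of this kind demonstrably mix the two conventions in exactly this
way — the package reproduces their internal arithmetic because it adopts
both. A consequence worth knowing: a conditional mean always equals or
exceeds the zero-filled mean, and heavier censoring inflates it.

`zscoreMatrix()` standardizes each compound column to mean 0, sd 1 (the
heat-map normalization); constant columns become 0 and are flagged.

## Trend statistics

Per retained compound (and the per-sample ΣPAH), `anovaPerCompound()`
fits a one-way ANOVA of log concentration on decade or era. Era
contrasts use the same machinery with two groups, where F is exactly the
squared pooled t statistic. p values are corrected across the compound
family by Benjamini–Hochberg FDR (`fdrAdjust()`, a named wrapper over
`p.adjust`). Pairwise contrasts use Tukey's HSD (Tukey–Kramer under
imbalance) with a hand-written insert–absorb compact letter display;
significance is reported at both 0.05 and 0.1 because decade contrasts
of this kind are conventionally read at both levels.

Chemical dissimilarity uses Bray–Curtis
($\sum|x-y| / \sum(x+y)$, via `vegan::vegdist`), with the all-zero pair
defined as 0 and flagged. `dissimilarityByDecade()` groups the pairwise
values by unordered decade-pair category (5 decades → 15 categories) and
runs ANOVA + Tukey across categories. The pairs are not independent —
each sample participates in many pairs — so the result carries an
explicit `caveat` flag; a PERMANOVA-style permutation test would be the
rigorous alternative but is out of scope here, and the category means
remain useful descriptively.

## Diagnostic-ratio source apportionment

Nine diagnostic ratios (`ratioRules()`, YAML-configurable) map ratio
values to emission-source families — petrogenic (unburned petroleum) vs
pyrogenic (combustion), with finer labels such as "Coal, wood or grass
combustion". Boundary convention: printed "<a" and ">b" thresholds are
strict; printed ranges "a–b" are closed on both sides, so a tie at a
shared boundary lands in the range interval. A defined value covered by
no interval is "indeterminate".

Two rules need special care:

* **Phenanthrene/Anthracene** is conventionally printed as "<10
  pyrogenic, <15 petrogenic", which is self-contradictory below 10. The
  shipped rule is amended to <10 pyrogenic, >15 petrogenic, 10–15
  indeterminate, and carries an `amended` flag with the printed
  thresholds in its note.
* **HMW/LMW** at exactly 1 and fluoranthene/pyrene at exactly 1 are
  indeterminate (both printed thresholds are strict).

Per-sample ratios (`computeRatio()`) use uncensored values only: a ratio
is undefined when any required compound is censored or the denominator
is zero; LMW/HMW aggregate sides treat censored cells as 0 but require
at least one uncensored member per side. Period-level apportionment
(`apportion()`) reports *both* the ratio of period conditional means
(ratio-of-means) and the mean of per-sample ratios with its observed
range (per-sample-mean), because published period ratio tables are
internally inconsistent about which they use: the HMW/LMW and
benz[a]anthracene rows of the reference survey reproduce exactly under
ratio-of-means, while its fluoranthene/pyrene row matches neither method
exactly. Neither method is declared canonical; both are labelled.

## The synthetic generator: what it emulates and what it does not

`simulateStudy()` draws true tissue concentrations as
$c_{ic} = \mathrm{baseline}_c \times f_{decade} \times f_{species}
\times e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, with
$\sigma = 0.4$ by default — lognormal because concentrations are
positive and the analysis log-transforms. The default conditions mirror
the reference survey: 42 specimens of three moss species (13/15/14)
across five decade bins; dry mass uniform on 0.38–1.64 g; baselines set
to the published 1920s conditional means for the nine tabulated
compounds (naphthalene 370, phenanthrene 260, fluoranthene 80, pyrene
55 ng g⁻¹, …), near-LOQ baselines for anthracene and benzo[a]pyrene,
and ~0.5 ng g⁻¹ for the eight compounds that are never detected; decade
factors decline 1.00 → 0.31 with a 1960s uptick (0.55 after 0.47),
tracking the published ΣPAH trajectory; Dicranum scoparium accumulates
~1.5× more than the pleurocarpous species. Compound LOQs default to
5 ng g⁻¹ with method-style overrides (e.g. chrysene 35 ng g⁻¹) chosen so
the detection census matches the survey's: four ubiquitous compounds,
seven intermittent, eight never seen. Censoring is applied strictly
below LOQ; `simulatePeakAreas()` then converts truth to area tables with
multiplicative $N(0, cv^2)$ area noise and a 6-level calibration series
spanning the simulated amount-ratio range.

All randomness flows from one user-supplied seed, restored-RNG style, so
runs are reproducible and side-effect free.

What the generator does *not* emulate: spatial structure and locality
effects, storage-time contamination drift, species-by-compound uptake
interactions, correlated multi-compound noise, chromatographic
artefacts (the simulation starts at integrated peak areas), and
non-lognormal outliers. Passing tests therefore demonstrate the
*arithmetic and statistical machinery* on study-shaped data, not that
real moss data satisfy lognormality or independence.

## Numerical and design notes

* Problem sizes in the test suite are the study's own (42 samples, 19
  compounds); simulation-based checks use 100–500 replicates, enough to
  bound Monte-Carlo error on the properties asserted.
* The pipeline (`runPipeline()`) writes every table with a provenance
  header (package version, config hash, seed) and no timestamps, so one
  config + seed is byte-identical across runs.
* Tied calibration amount-ratios abort the fit (singular design);
  single-point calibrations are refused.
* `formatPeriodTable()` rounds to 1 decimal, the resolution of the
  reference tables; underlying objects keep full precision.
* The published fluoranthene/pyrene period ratios cannot be derived
  from the published period means (e.g. 1950s: 43.2/33.7 = 1.28 vs a
  printed 1.43); the package reports maxima and ratios from the data it
  is given and leaves that discrepancy visible rather than resolving it.

## A worked example

```{r example, eval = FALSE}
library(mossPAH)
me <- simulateMossExperiment(studyDesign(seed = 7))
retained <- prevalenceFilter(replaceCensored(me))
retained
#> [1] "naphthalene"  "phenanthrene" "fluoranthene" "pyrene"
apportion(me)[1:4, ]
```

## Limitations

Beyond the generator's idealizations listed above: zero replacement
biases conditional-vs-unconditional comparisons under heavy censoring;
the dissimilarity ANOVA treats non-independent pairs as observations
(flagged, not corrected); species are pooled, not modelled; and the
apportionment thresholds are literature conventions whose boundaries are
themselves approximate — classifications near a boundary should be read
as direction, not certainty.
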