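---
title: "The scalogram method: scoring, Sturges tiers, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scalogram method: scoring, Sturges tiers, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalogram)
```

## The model

The scalogram technique turns a region × indicator table of per-capita
health-resource rates into an ordinal composite and a five-tier development
classification. Its premise is that regional development is a common factor
behind many structural indicators, so a simple sum of ordinal scores — with
no weights and no distributional assumptions — orders regions usefully even
when individual indicators are noisy or on incomparable scales.

For each indicator $j$ with observed rates $x_{1j}, \dots, x_{nj}$:

* **equal-width binning** (default) splits the observed range
  $[\min_j, \max_j]$ into four equal sub-intervals; a region in the $k$-th
  interval from the bottom scores $s_{rj} = k$ (or $5-k$ for an indicator
  declared `higher_is_worse`). Bins are half-open $[\text{low}, \text{high})$
  with the top bin closed, so every value gets exactly one score.
* **quartile binning** uses the empirical quartiles instead:
  $x \le Q_1 \to 1$, $\le Q_2 \to 2$, $\le Q_3 \to 3$, else $4$.

The composite is $T_r = \sum_j s_{rj}$, with per-cluster subtotals over the
three indicator clusters (institutional, human-resource, rural
institutional). With $n$ indicators, $T_r \in [n, 4n]$ by construction; a
30-indicator instrument is bounded by 30 and 120.

Regions are then cut into five ordered tiers. The class-interval width comes
from the Sturges rule on the score range $R$ and item count $N$:
$$ i = \frac{R}{1 + 3.3 \log_{10} N}. $$
Tier lower bounds step up from the range minimum; intervals are half-open
with the top tier closed at the range maximum.

## Choices that matter, and why

**Which binning.** The mapping from raw rates to 1–4 is the one genuinely
underdetermined step of the technique: "ranking and scoring" can be read as
either range-based or rank-based classes. Equal-width over the observed
range is the default because it is deterministic, parameter-free and ties
are impossible except exactly at bin edges; quartile classes are exposed as
an alternative reading (they guarantee occupancy of all four scores but tie
heavily at repeated values). Reports record which was used, and the two are
not interchangeable on skewed data: a single well-endowed metropolis
stretches equal-width bins and pushes everyone else down, which is visible
in the synthetic examples below.

**Degenerate (constant) columns.** An indicator on which all regions are
equal cannot discriminate; scoring it low would penalise every region for a
non-informative column. All regions receive 4 and a warning is raised.

**Rounded-step bounds.** Published scalogram tables print class bounds at
one decimal. If exact Sturges widths were accumulated and then rounded for
display, the displayed table could not be reproduced from its own numbers
(four exact widths of 10.5159 from 33 give 75.06, which prints as 75.1,
while four printed steps of 10.5 give exactly 75). `build_class_scheme()`
therefore steps the bounds by the width *rounded to the reporting decimals*
(`step`), keeping the printed scheme and the scheme actually used for
assignment identical. The exact width is kept alongside in `width`. Two
consequences, both deliberate:

* the top tier absorbs whatever remainder the rounded steps leave, so it can
  be wider than one step (the packaged Fars reference scheme's top tier runs
  75–89.4, about 14.4 wide against a 10.5 step);
* the lowest bound is the range minimum itself, unrounded — rounding it
  could lift it above the minimum and leave a sliver of the range
  unassignable.

If rounding collapses two bounds (a tiny range at coarse decimals), the
constructor refuses and advises more decimals rather than emitting a
degenerate scheme.

**Scheme endpoints and $N$.** Defaults are the observed range of the
computed totals and $N$ = number of regions, both overridable: published
schemes sometimes pin other endpoints (the Fars reference scheme uses
33–89.4 with $N = 21$, which this package reproduces as lower bounds 33,
43.5, 54, 64.5, 75), and reproducing such a scheme exactly requires passing
its pinned values to `score_range`/`sturges_n`.

**Ties and boundaries.** Ranking is competition-style (tied totals share
the smaller rank; the next rank is offset by the tie count). A score that
falls exactly on a shared bound belongs to the *upper* tier — the half-open
convention — so e.g. 43.5 under the Fars scheme is `less_development`, not
`under_development`. Tier percentages are computed arithmetically to two
decimals; they sum to 100 within rounding (±0.05 per tier).

**Units.** All rates are normalised to per-1,000 population on read; a
column declared per-10,000 in the schema is divided by 10. Missing cells
are an error by default; the permissive mode imputes the indicator's
observed minimum (the conservative "negative condition" reading) with a
warning. Region-name joins, including geometry joins for choropleth export,
are exact after whitespace trimming and case folding — no fuzzy matching,
for determinism.

## The synthetic generator

The per-city matrix behind the Fars assessment was never published, so the
package generates matrices of the same shape for testing and benchmarking.
Region $r$ draws a latent development level
$d_r \sim N(0, \sigma_d^2)$ and cell $(r, j)$ is

$$ x_{rj} = \beta_j \, \exp(d_r + \varepsilon_{rj}), \qquad
   \varepsilon_{rj} \sim N(0, \sigma_\varepsilon^2), $$

truncated at zero (a no-op for the log-normal form, kept as a guard). The
multiplicative single-factor model is the simplest structure under which
(a) rates stay nonnegative, (b) one axis drives all three clusters — the
technique's own premise — and (c) rank recovery of $d_r$ is a meaningful
benchmark. Defaults are the study shape: 22 regions, the packaged
31-indicator three-cluster schema, $\sigma_d = 0.5$, $\sigma_\varepsilon =
0.3$. Baseline rates $\beta_j$ come from the packaged fixture's
province-wide indicator values scaled by 1/100, giving means of roughly
0.3–0.65 per 1,000 population — the order of magnitude of facility and
specialist densities.

What the generator deliberately does **not** emulate: cluster-specific
factors (a region strong on rural care but weak on specialists), count
noise for rare resources (a district with 0 or 1 radiotherapist), spatial
autocorrelation between neighbouring districts, and population-size effects
on rate stability. Passing tests therefore show the pipeline is correct and
that a *single common gradient* is recoverable; they do not show that real
yearbook data satisfy the single-factor premise.

```{r recovery}
r <- recovery_simulation(n_reps = 50, config = synthetic_config(), seed = 1)
round(c(mean = mean(r), sd = sd(r)), 3)
```

Under the default conditions the Monte-Carlo benchmark puts the mean
Spearman correlation between planted levels and computed totals near 0.97
(the acceptance suite runs 200 replicates per seed stream and asserts a
conservative floor of 0.9, stable across streams). Recovery degrades as
$\sigma_\varepsilon$ grows, and in the noiseless limit the composite is
weakly monotone in $d_r$ — *weakly*, because four score bins tie regions
that share a bin; exact rank recovery of 22 regions from at most 4 distinct
totals is impossible by pigeonhole, which is a property of ordinal scoring
itself, not of the generator.

## Numerical notes and problem sizes

Equal-width bin edges are computed as $\text{lo} + k/4 \cdot
(\text{hi}-\text{lo})$ with the top edge set to `hi` exactly, guarding
against floating-point drift; interval membership uses `findInterval` with
a closed right end. Tier assignment tolerates $10^{-9}$-scale slack at the
range endpoints only. Table round-trips format doubles with 17 significant
digits so written reports re-read bit-identically; report metadata carries
an MD5 digest of the input matrix and no timestamps, making identical runs
byte-identical.

The test suite works at the study's own scale (22 regions × 31 indicators)
and smaller: property checks use 4–22 regions with 20 random repetitions,
grid coverage uses 401–1001-point grids, and the recovery benchmark uses
200 replicates per seed stream — the whole suite runs in a few seconds.

## Known limitations

* Equal-width binning is outlier-sensitive: one extreme region compresses
  everyone else into the lower bins. That is faithful to the technique, not
  a defect, but quartile binning is the safer choice for heavy-tailed rates.
* The five-tier Sturges construction takes $N$ as given; the package does
  not second-guess whether $N$ should be the region count or another item
  count, it only defaults to the former.
* No optimal-breaks classification (Jenks, head/tails) and no projection
  handling in the GeoJSON export — coordinates pass through untouched.
* The composite is unweighted by design; if some indicators should matter
  more, that is outside this technique.
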