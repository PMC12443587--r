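---
title: "Measuring the alignment of research output with disease burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the alignment of research output with disease burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenalign)
```

## The model

The unit of analysis is a pair of discrete probability distributions over the
16 level-2 causes of the Global Burden of Disease hierarchy, evaluated per
calendar year:

* the **burden shares** `p(x)`: each cause's fraction of global DALYs (or
  deaths, or prevalence) in that year, and
* the **research shares** `q(x)`: each cause's fraction of the year's
  article-to-cause links.

The alignment statistic is the Kullback–Leibler divergence of research from
burden, `KLD(p||q) = sum_x p(x) ln(p(x)/q(x))`, in nats. The burden side is
the reference: the statistic weights each cause's log-mismatch by its burden,
so neglecting a high-burden cause is penalized more than over-researching a
small one. Zero indicates perfect alignment; the statistic is asymmetric and
unbounded, which motivates the sensitivity metrics computed alongside it
(Population Stability Index, Hellinger distance, Jensen–Shannon divergence —
the latter two bounded by 1 and ln 2).

Counting conventions: article-to-cause **links** are the counting unit, so an
article about two diseases contributes to both causes; geolocation is by
first-author country. Causes with zero counts in a scope keep share 0 rather
than being dropped, so every distribution lives on the same 16-cause support.
Tables keyed at hierarchy levels 3/4 are first rolled up to their level-2
ancestors (`rollup_to_level2()`), and country-keyed tables can be aggregated
to the eight UN regions (`aggregate_regions()`); both conserve totals
exactly.

## Handling zero and near-zero shares

`KLD` diverges when research on a positive-burden cause is absent. Three
selectable policies, applied to the same inputs as the headline statistic:

* **Laplace smoothing** (default): research shares are computed as
  `(count + alpha) / (total + alpha * 16)` with `alpha = 1`, i.e. one
  pseudo-article per cause. At the article volumes the statistic is meant
  for (tens of thousands of links per year) the smoothing is numerically
  negligible except exactly where it is needed.
* **Exclusion**: causes where either share falls below `eps = 0.01` are
  dropped and both vectors renormalized over the survivors.
* **Raw / error**: unsmoothed shares, returning `Inf` or failing loudly.

The default is a deliberate choice — the three variants give consistent
trends, but a pipeline must pick one, and smoothing is the only variant that
keeps the full 16-cause support and exact decomposability (below).

## Burden uncertainty

Burden estimates come with asymmetric (lower, mean, upper) bounds. Draws are
simulated from a log-normal with

    sigma = ln(upper / lower) / (2 z),   mu = ln(mean) - sigma^2 / 2,

with `z = 1.959964`, so the distribution mean equals the reported mean and
the central 95% interval spans the reported upper/lower ratio. This captures
the nonnegative, right-skewed character of burden estimates; it matches the
reported interval endpoints exactly only when the triple is geometrically
balanced (`sqrt(lower*upper)` close to the mean), which is the shape real
burden bounds take. Draws are independent across causes — the reported
bounds are per-cause marginals and no covariance is published — and each
cause's draw vector is renormalized into a share distribution per draw.

A divergence result is the across-draw mean, with 95% CI `mean ± z * SD`
(the normal approximation, not a percentile bootstrap). With one draw the CI
is undefined and flagged. Degenerate bounds (`lower == upper`) reproduce the
mean exactly; a nonpositive lower bound falls back to the degenerate
distribution with a warning.

## Decomposition and counterfactuals

With per-cause summand `d_x(t) = p_x(t) ln(p_x(t)/q_x(t))`, a cause's
contribution to the relative change between two years is
`(d_x(t1) - d_x(t0)) / KLD(t0)`. Contributions sum to the total relative
change as an algebraic identity (tested to 1e-12); negative values are
divergence-reducing. The baseline-year normalization (`t0`) is the default
because "change since the base year" is the natural reading; the `t1`
normalization is exposed as an option since either convention is defensible.
Contributions are computed on the same zero-policy-adjusted distributions as
the headline series, so the summands add up to the reported totals.

Two counterfactuals separate the drivers of change: `fixed_research` holds
`q` at its base-year value and lets the burden evolve (`KLD(p_t || q_base)`);
`fixed_burden` does the reverse. CIs come from the burden sampler applied to
whichever burden year enters the comparison — the research side has no
uncertainty model — so both scenarios coincide with the observed series at
the base year. Two scenarios are called statistically distinct in a year when
their 95% CIs do not overlap.

A lagged variant, `KLD(p_t || q_{t+lag})`, asks whether research tracks
burden with a delay; `lag_scan()` evaluates a 0–10 year window, and a world
in which research copies burden with a d-year delay attains its minimum mean
lagged divergence at lag d.

## Geography

A cause's geographic concentration is the Herfindahl–Hirschman index of its
burden shares across the eight UN regions (1/8 for a uniform spread, 1 for a
single-region disease). Causes are **local** when their HHI strictly exceeds
the mean HHI across the 16 causes, otherwise **global**; exact ties (guarded
at 1e-12) go to global. Net-producer status — research share above burden
share — is computed at country level and aggregated for reporting. The
locality–mismatch correlation pairs, per cause, the difference in
within-group burden shares between net producers and the rest (x) with the
difference between global burden and research shares (y); Pearson is the
headline coefficient, Spearman is reported alongside.

## Projections

Research counts are extrapolated per cause by OLS on the yearly totals of a
recent window (default 2018–2021; counts, not shares, so that removing
volume renormalizes correctly). A pandemic-shocked cause can be relaxed
linearly from its last observed level back onto its pre-shock trend line
(anchored on 2016–2019) by the end of 2022–2024 — a documented stand-in, as
no canonical functional form exists for that adjustment. Projected counts
are floored at one article per cause-year to keep divergences finite.

The burden forecast is pluggable: the default is per-cause linear
continuation of the 2010–2021 global means with the last observed relative
interval widths carried forward; an external forecast table (year, cause,
mean, lower, upper) can be dropped in. Each simulation draws burden values
around the forecast means exactly as in the observed-period sampler.

The withdrawal scenario removes the article volume that acknowledges US
public funding and has a non-US first author, phased linearly over five
years (year k removes k/5 of the affected volume; an abrupt mode exists).
The affected share per cause is estimated from the trend window. When the
removed mass sits only in causes whose research share is below their burden
share, the withdrawal scenario's divergence is at least the baseline's in
every projected year — a provable ordering that the test suite checks on a
constructed world. In worlds where the communicable burden keeps declining,
formerly under-researched causes eventually cross to over-researched, and
the ordering can legitimately reverse in the long run.

## The synthetic world

`generate_world()` produces publication and burden tables with the structure
the analysis assumes, plus the analytic ground truth
(`expected_shares()`) that recovery tests compare against:

* **Research**: a fixed baseline share vector (over-weighting neoplasms and
  neurological research, under-weighting communicable and cardiovascular
  causes relative to burden), drawn multinomially per year — 50,000
  article-to-cause links per year by default, so yearly totals are exact and
  divergence, which depends only on shares, is unaffected by the total —
  with optional per-cause drift and an optional "research copies burden with
  a lag" mode.
* **Burden**: first-year global shares with per-cause, per-region
  multiplicative annual trends — communicable burden concentrated in
  sub-Saharan Africa and Central/Southern Asia and declining there (−2.5%/yr,
  −0.5% elsewhere), noncommunicable burden spread across regions and rising
  (+1.5%/yr; cardiovascular tilted upward in Asian regions and slightly
  downward in the research-intensive ones; neoplasms nearly flat) — times
  small log-normal noise (sd 0.02). Bounds are multiplicative
  (−15%/+25%), so `lower <= mean <= upper` holds by construction. Deaths
  and prevalence variants use deterministic per-cause tilts so the three
  metrics are distinct but parallel.
* **Strata and funding**: research type (45% basic / 30% applied / 25%
  clinical), industry authorship (15%, with 30% of industry clinical
  articles as phase-3 trials), funding acknowledgment coverage ~40%, and a
  region-by-cause US-public-funding exposure matrix peaking for HIV research
  led from sub-Saharan Africa (41%) and elevated for respiratory
  infections, substance-use and neurological research. Non-US funder
  countries follow a fixed acknowledgment distribution headed by China
  (20%), the United Kingdom (16%), Canada (12%) and Australia (10%).
* **Reproducibility**: one root seed; per-year substreams are derived by
  counter, so subsetting years never changes earlier years, and regeneration
  is byte-identical.

These defaults were chosen once to reproduce the qualitative world the
analysis targets: research shares virtually unchanged over two decades, a
roughly halving divergence driven by the burden side, cardiovascular burden
up ~4 share points against local communicable burden falling about three
times as fast, and a divergence that stagnates or rises under trend
continuation.

What the generator does **not** emulate: country-level microstructure below
the eight regions (each region holds 2–3 representative countries with fixed
weights); correlation of burden errors across causes or years; citation or
collaboration dynamics; reporting lags. Passing recovery tests on this world
demonstrates that the pipeline measures what it claims on data with the
assumed structure — it does not validate the assumptions themselves against
the real bibliometric record.

## Numerical choices

* Natural logarithms throughout; divergences are in nats.
* Share vectors must sum to 1 within 1e-6 at entry and are exactly
  renormalized whenever a subset is taken.
* `compute_shares()` fails loudly on an empty scope instead of returning
  NaN; years whose filters select no articles are flagged as gaps in the
  series, never silently dropped.
* Seeds: all randomness flows from explicit integer seeds; substreams are
  derived as `(33013*(seed mod 65011) + 7919*counter + 17) mod 2147483629`,
  keeping every derived seed well inside 32-bit range. RNG state of the
  caller is saved and restored around every seeded computation.
* The pandemic-shock injector rescales integer counts to the target share
  and repairs the rounding residual on the largest cell, so configured
  shares are hit to within 1/total.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
worlds of 50,000 links/year over 1999–2021 (1.15M links), 500 burden draws
per year for headline series, 200 for scenario comparisons, 1,000
simulations for the 2050 projections, 50,000 draws per triple for sampler
recovery, and 1,000 random 16-dimensional pairs for the metric oracles.
The full suite completes in well under a minute on one CPU.

## Limitations

* DALY-side uncertainty is treated as independent log-normal per cause; real
  burden estimation errors are correlated across causes, years and regions,
  so the CIs here are a lower bound on the real uncertainty.
* The linear burden continuation is a stand-in for a demographic forecast
  and should be replaced via the pluggable forecast table for substantive
  projection work.
* The withdrawal scenario removes research volume without reallocation;
  compensating behavior by other funders is out of scope.
* Dedupe semantics for multi-cause articles follow the link-counting
  convention, and geolocation is first-author only. The input table carries
  aggregated counts without article identity or co-author lists, so
  unique-article counting and fractional all-author weighting are upstream
  concerns: analyses that need them must pre-aggregate their input
  accordingly.
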