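---
title: "Proxy measures of menstrual pain from transaction logs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy measures of menstrual pain from transaction logs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Menstrual pain is largely self-managed with over-the-counter analgesics, so
clinical data under-represent it and survey samples are small. Retail
loyalty-card logs record, at national scale, the one behaviour most
sufferers do perform: buying pain relief. `basketproxy` operationalises
this as a basket-co-occurrence analysis. A *menstrual product* is any item
the retailer categorises as "tampon" or "sanitary pad"; a *pain product* is
any item categorised "Pain Relief Oral" or "Topical Pain Relief"; a
*menstrual-pain basket* is a single till receipt containing at least one of
each. All probabilities are defined over baskets, not item lines: the till
receipt is the behavioural unit of a shopping decision.

## The probabilistic model

For a basket universe (a customer set, a store, or an area) the package
estimates basket frequencies

- `P(M)` — proxy for menstruation prevalence,
- `P(P)` — proxy for pain prevalence,
- `P(P|M)` and `P(P|¬M)` — conditional pain-inclusion probabilities,

and the **Menstrual Pain Purchasing Ratio**

```
MPR = P(P|M) / P(P|¬M).
```

The normalisation by `P(P|¬M)` is what turns a raw co-occurrence rate into
a relative measure: it discounts customers who buy analgesics with
everything. The headline MPR is computed *within the menstrual-pain
customer set* (customers with at least one menstrual-pain basket), i.e. the
denominator is those same customers' baseline propensity to buy pain relief
on its own; the customer set is an argument of `compute_proxies()`, so
other universes are one call away.

Because all five quantities are frequencies over one basket universe, the
law of total probability

```
P(P) = P(P|M) P(M) + P(P|¬M) (1 − P(M))
```

holds as an exact identity, and the test suite asserts it to machine
precision on every computation. Degenerate denominators (no menstrual or no
non-menstrual baskets, or `P(P|¬M) = 0`) are reported as `NA` with explicit
`*_defined` flags; sentinel numbers are never used.

Interpretation caveats are inherent to the design: pain items in a
menstrual basket need not be for menstrual pain; related purchases can be
split across baskets or retailers; one loyalty card can serve a household.
The measure is relative and is best read as a lower bound on menstrual-pain
purchasing. It carries no information about pain intensity.

## Validating the menstruation proxy by periodicity

If menstrual baskets track menstruation, the day gaps between a customer's
consecutive menstrual baskets should concentrate near the menstrual cycle
length. `compute_intervals()` extracts per-customer gaps (customers with
fewer than two menstrual baskets contribute nothing; same-day pairs give a
gap of 0), and a *physiological filter* retains gaps inside the
conventional cycle bounds, inclusively: 21–35 days. Inclusive bounds are
deliberate — the filtered minimum and maximum should be exactly attainable
at 21 and 35. Summaries report count, integer mode, mean, *population*
standard deviation, median, min and max; modal ties break to the smallest
value so results are deterministic. Pooled summaries aggregate retained
intervals across customers rather than averaging per-customer modes, so a
single `n` describes the evidence. The unfiltered summary is reported
alongside: missed purchases stretch gaps to multiples of the cycle and
stock-ups shorten them, producing the long right tail (mean well above
mode) that motivates the filter.

## The synthetic study generator

Real loyalty-card data of this kind are private, so the `synth` module is a
first-class, tested simulator whose defaults *are* the study conditions,
with a deterministic `true_parameters()` record for recovery tests.

Per menstruating customer, cycle onsets recur at intervals drawn from a
normal distribution with mean 28 and standard deviation 3.8 days, truncated
to [21, 35] and rounded to whole days (sampling is by inverse CDF, so no
rejection loops). The truncation matches the physiological-filter bounds;
3.8 was chosen so the filtered interval spread of recovered data sits near
the high-3s in days. Noise emulates real purchase behaviour:

- an onset produces a recorded menstrual basket only with probability
  `1 − purchase_miss_prob` (default miss 0.3 — shopping elsewhere);
- ordinary trips arrive uniformly at `trip_rate_per_week` (default 0.5, a
  fortnightly visit to a health-and-beauty retailer);
- each ordinary trip of a menstruating customer becomes a menstrual
  stock-up with probability `stockup_prob` (default 0.05).

One basket is generated per customer-day; same-day repeat visits are not
modelled.

Pain inclusion is where the calibration lives. The headline statistics this
simulator is calibrated to are *jointly* incompatible with a homogeneous
per-basket probability: if only about a quarter of menstrual customers ever
record a menstrual-pain basket, yet within that set half of menstrual
baskets contain pain relief, then co-purchasing must be concentrated in a
subset of customers. The generator therefore draws a customer-level
susceptibility flag with probability `menstrual_pain_fraction` (default
0.267). Menstrual baskets of susceptible customers include a pain item with
probability `p_pain_given_menstrual` (default 0.50); menstrual baskets of
non-susceptible customers never do; every non-menstrual basket includes one
with probability `p_pain_given_nonmenstrual` (default 0.1282). The default
ratio 0.50 / 0.1282 ≈ 3.9 is the true MPR within the menstrual-pain set.

**Income effect.** Area deprivation enters through a multiplicative scaling
of `p_pain_given_menstrual` by the customer's MSOA household-income decile.
The ramp is linear in decile rank and normalised to unit mean:

```
s_1 = 2(1 − g) / (2 − g),   s_10 = 2 / (2 − g),   s_d linear in d,
```

with `g = income_gradient` (default 0.32). Two properties motivated the
unit-mean normalisation over the simpler "1 − g at the bottom, 1.0 at the
top" ramp: the bottom-to-top contrast is exactly `g` (so the recovered
decile gradient targets 32%), *and* the population-average `P(P|M)` stays
at 0.50 (so the recovered MPR stays at 3.9). An un-normalised ramp would
depress the average conditional probability by `g/2` and drag the true MPR
down to about 3.3 — the two calibration targets cannot both hold without
it.

**Catalogue and regions.** The catalogue carries the five retailer
categories with log-normal unit prices and popularity weights drawn from a
Gaussian copula against log price, with a stronger negative
price–popularity coupling for pain items (target correlations −0.7 vs
−0.35): cheap analgesics dominate pain sales more than cheap pads dominate
menstrual sales. Regions nest 4–5 LSOAs per MSOA; household income varies
across MSOAs (weekly GBP, mean 520, sd 110), and the other deprivation
features (IMD score, electricity spend, jobseekers claimants, room
occupancy, population structure) are generated with *moderate* income
correlations (about |r| 0.25–0.5 at MSOA level) through separate MSOA-level
and LSOA-level noise. Moderation is deliberate: income is the only causal
driver of the planted pain gradient, and the attribution analysis should be
able to identify it; a feature generated as a near-copy of income would
make the planted signal unidentifiable in principle, not just in practice.

**What the simulator does not emulate.** Contraceptive cycle suppression,
menopause, multi-retailer switching beyond the miss probability, seasonal
and promotional effects, household sharing of one card, and pain-intensity
variation. Passing recovery tests therefore show that the pipeline
estimates are consistent for data satisfying the generator's assumptions —
not that real transaction data satisfy them.

## Regional aggregation and the income gradient

LSOA features are carried to MSOA level by unweighted means
(`lsoa_to_msoa()`). Store baskets are pooled within an MSOA before proxies
are computed (`msoa_proxies()`): pooling counts, never averaging per-store
probabilities, keeps the total-probability identity exact at area level
(the suite includes a case where pooling and averaging differ). Feature ×
measure association uses Pearson correlation with two-sided p-values,
pairwise-deleting MSOAs whose proxy is undefined. The income gradient is
`100 × (top − bottom) / top` of mean `P(P|M)` across MSOA income decile
groups; deciles are rank-based with first-occurrence tie-breaking, and the
grouping resolution is a parameter (`n_groups`).

## Area classification and attribution

Targets `P(M)`, `P(P)`, `P(P|M)` are binarised High/Low against the
unweighted mean over MSOAs, strictly greater meaning High; an all-one-class
target refuses training. Features are the deprivation set (IMD score,
household income, electricity spend, jobseekers claimants, room occupancy,
and the four population counts); a collinear secondary income column is
excluded when weekly household income is present. Scaling is min–max to
[0, 1] — chosen over z-scoring because the target range is the stated
convention — with bounds fitted on training folds only and held-out values
clipped, so no leakage. Model families and grids (small and documented, at
desk scale):

| family | grid |
|---|---|
| ridge logistic regression (glmnet) | lambda 0.01, 0.1, 1, 10 |
| random forest (ranger) | 100/300 trees × depth 3/6/unlimited |
| SVM (e1071) | linear/RBF × cost 0.1/1/10 |
| neural network (nnet, one hidden layer) | 8/16/32 units, decay 5e-4 |

Folds are stratified 10-fold, deterministic under the supplied seed;
accuracy is correct/total per fold, reported mean ± sd at the best grid
point per family, and the best family is refitted on all data for
attribution.

Attribution uses a hand-written model-agnostic Shapley estimator
(permutation sampling in the Štrumbelj–Kononenko scheme) over a background
sample of at most 50 MSOAs and 32 permutations, uniform across model
families. For additive models the estimator is exact up to Monte Carlo
error in the background average, and per-instance attributions always sum
to the prediction minus the background-average prediction; the tests check
it against an independent exact subset-enumeration oracle at 3 features and
against the closed form for linear models. Features are ranked by mean
absolute Shapley value; the signed summary is the mean attribution among
instances above the feature's median, so a positive value reads "high
values of this feature push areas towards the High class".

## Problem sizes and precision

The package's recovery experiments run at three scales, chosen from a
variance analysis rather than convenience:

- **5,000 customers / 100 MSOAs / 2 years** — the desk-scale default;
  ample for interval mode/median (tens of thousands of retained intervals).
- **10,000 customers** — for MPR (Monte Carlo sd ≈ 0.05 against a ±0.15
  check) and the menstrual-pain customer fraction (sd ≈ 0.7 points against
  ±1.5).
- **250,000 customers** — for the income-decile gradient. Its noise is
  dominated not by basket counts but by binomial sampling of the 0.267
  susceptibility within each decile's customers: in relative terms roughly
  `1.6 / sqrt(menstruating customers per decile)`, i.e. ~1.4 percentage
  points at this scale against a ±3-point check. Smaller studies cannot
  resolve a 32% gradient to that tolerance no matter how many baskets each
  customer contributes.

## Known limitations

- The proxy is relative and store-bound; absolute prevalence is out of
  reach by construction.
- Areas are assigned by store location, not customer residence; catchment
  effects are unmodelled.
- The simulator's independence assumptions (customers i.i.d. across areas,
  stationary behaviour over the period) are idealisations; correlations in
  real data (promotions, seasonality) would widen every recovery interval.
- With a single store per MSOA at the defaults, store pooling is exercised
  by tests through multi-store fixtures rather than the default simulation.
- The classifier comparison is a recovery harness, not a benchmark: at
  desk scale with one causal driver, regularised linear models are
  expected to do as well as anything.
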