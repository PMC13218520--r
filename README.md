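# basketproxy

Behavioural proxy measures of menstruation, pain and menstrual pain from
itemised retail transaction logs.

Population-level evidence on menstrual pain (dysmenorrhea) is scarce: most
sufferers self-medicate with over-the-counter analgesics rather than present
to health services, so surveys and clinical records under-count it.
`basketproxy` implements a transaction-log approach for epidemiologists and
health-data scientists: shopping baskets that contain both a menstrual
product (tampons, sanitary pads) and a pain-relief product (oral or topical
analgesics) are treated as a behavioural signal of menstrual pain, estimated
probabilistically, validated through purchase periodicity, and linked to
small-area deprivation.

## The measures

Over a universe of baskets (till receipts) for a customer set, store or
area, the package estimates:

- **P(M)** — probability a basket contains a menstrual item (proxy for
  menstruation prevalence);
- **P(P)** — probability a basket contains a pain item (proxy for pain
  prevalence);
- **P(P|M)**, **P(P|¬M)** — conditional probabilities of a pain item given
  the basket does / does not contain a menstrual item;
- the **Menstrual Pain Purchasing Ratio**,

  **MPR = P(P|M) / P(P|¬M)**,

  the propensity to buy pain relief *together with* menstrual products,
  normalised by the same customers' propensity to buy pain relief on its
  own. MPR > 1 means pain products are preferentially co-purchased with
  menstrual products.

Around this core the package provides:

- a **periodicity validation** of the menstruation proxy: day gaps between a
  customer's consecutive menstrual baskets, with a physiological filter
  retaining gaps of 21–35 days (a periodic signal at ~28 days supports the
  proxy);
- **small-area linkage**: store-level baskets pooled to MSOAs (UK census
  areas of ~7,800 residents), LSOA deprivation features averaged up to
  MSOAs, Pearson correlation grids, and the **income gradient** — the
  relative difference in mean P(P|M) between the top and bottom MSOA income
  deciles;
- **area classification**: MSOAs binarised high/low against the national
  mean, classified from deprivation features (ridge logistic regression,
  random forest, SVM, neural network) under stratified 10-fold
  cross-validation with small hyperparameter grids, and interrogated with a
  model-agnostic **Shapley attribution** estimator;
- a calibrated **synthetic transaction-log simulator** with a deterministic
  ground-truth record, standing in for private retailer data and enabling
  parameter-recovery tests of the whole pipeline.

## Worked example

```r
library(basketproxy)

cfg <- simulation_config(seed = 42)   # 5,000 customers, 100 MSOAs, 2 years
sim <- simulate_study(cfg)
baskets <- build_baskets(sim$transactions, classify_products(sim$catalogue))
sets <- customer_sets(baskets)

# headline ratio, computed within the menstrual-pain customer set
compute_proxies(baskets, customers = sets$menstrual_pain)
#> Proxy measures over 46243 baskets
#>   P(M) = 0.3082   P(P) = 0.2413
#>   P(P|M) = 0.5020   P(P|not M) = 0.1251
#>   MPR = 4.012

# share of menstrual customers who ever co-purchase pain relief
100 * length(sets$menstrual_pain) / length(sets$menstrual)
#> [1] 26.89142

# periodicity validation of the menstruation proxy
periodicity_validation(baskets)$filtered
#> Interval summary (n = 31589): mode 28, mean 27.80 ± 3.34, median 28,
#> range [21, 35] days

print(sim$ground_truth)
#> Ground truth implied by the simulation config
#>   MPR = 3.9002  (P(P|M) = 0.5000 / P(P|not M) = 0.1282)
#>   menstrual-pain customer fraction = 0.2670
#>   income gradient = 32.0%
#>   truncated cycle: mean 28.00, sd 3.21 days
```

The estimated MPR of about 4 says these customers are four times more
likely to buy pain relief alongside menstrual products than on their own;
the 26.9% is the recovered fraction of menstrual customers with at least
one menstrual-pain basket (truth 26.7%); and the filtered purchase
intervals centre exactly on the 28-day cycle planted by the simulator —
the recovery of the configured ground truth, within sampling error.

`run_pipeline(cfg, out_dir)` runs every stage end-to-end and writes stage
CSVs plus `report.json` / `report.md`.

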