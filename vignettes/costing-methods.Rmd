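---
title: "Micro-costing the diagnostic odyssey and trio WGS: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-costing the diagnostic odyssey and trio WGS: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odysseycost)
```

## The problem

Before a rare-disease patient reaches genome-scale sequencing they typically
traverse a "diagnostic odyssey": years of imaging, biochemistry and,
centrally here, a *sub-odyssey* of second-line genetic tests — single-gene
sequencing, gene panels, occasionally epigenetic assays. Two economic
quantities matter when a health system weighs replacing that sub-odyssey
with trio whole-genome sequencing (WGS: proband plus both parents):

1. what the standard genetic-testing pathway costs per proband, and
2. what providing trio WGS costs per family, stage by stage.

`odysseycost` implements both costings, a descriptive summary of
stated-preference (willingness-to-pay and attribute-rating) interview data,
and a calibrated synthetic-cohort generator so that the entire pipeline is
exercised end-to-end without access to patient-level records, which are not
publishable.

## Costing the standard pathway

### The costbook and the amplicon-bin fallback

Unit costs for named tests come from a user-supplied registry (the
*costbook*) with a provenance tier: prices from Scottish NHS genetics
laboratories (`scotland_lab`) are preferred to prices from laboratories
elsewhere in the UK (`uk_lab`). The preference order is a documented,
configurable policy — the sources are stated facts, the *order* is our
design choice.

Tests with no authoritative price are costed by a workload proxy: the
number of amplicons or exons analysed, binned into 1–10, 11–20, 21–30,
31–40 and 41+, each bin priced at the arithmetic mean of the authoritative
entries it contains. Two deliberate edges:

* **Empty bins error** rather than borrow a neighbouring bin's mean; a
  silent borrow would fabricate a price with no members behind it.
* **Matching is exact** after case/whitespace normalisation. Illegible or
  unidentifiable test names make a proband *uncostable*; following the
  source study's practice, such probands are excluded whole (no partial
  totals) and logged, rather than guessed at.

Money is held at full double precision throughout and rounded only at
presentation (2 dp for money and percentage shares, nearest pound for
headline totals). This matters: percentage shares recompute correctly only
from the full-precision stage sum.

Historical prices are re-expressed in 2018 pounds with an RPI-style index
ratio; the shipped index is the ONS RPI annual-average series 2013–2018 and
is an editable fixture, not a hard-coded constant.

### Attendances and summaries

Each costed proband additionally receives a fixed attendance cost: by
default two general outpatient visits at £295.61 and one genetics clinic
visit at £236.78, i.e. £828.00 per proband. The two per-visit unit costs
are solved from the pair of published scenario totals (base £828.00;
doubled-genetics £1064.78) because the underlying reference-cost lines are
not printed; both counts and both unit costs are configuration, not
constants. Whether the "two outpatient appointments" represent one
reference-cost code or a case-mix average is unknowable from the source;
we treat each as a single configurable unit cost.

Cohort summaries (n, mean, SD, median, min, max, IQR) are reported overall
and per rare-disease category. Conventions, each configurable or documented:

* quartiles by linear interpolation between order statistics
  (`quantile(type = 7)`) — no convention was stated in the source;
* Tukey fences at 1.5 × IQR, with **on-fence values not outliers** (strict
  inequality), requiring at least 4 observations;
* outliers are flagged but **never removed** from statistics;
* single-member groups report SD 0 with a degeneracy flag; groups of ≤ 2
  are summarised but flagged `small_group` (box plots conventionally start
  at n = 3);
* costs are never annualised — test dates are absent from screening-form
  data, so date columns are ignored with a warning rather than modelled.

## Costing trio WGS

The WGS pathway is a 13-stage ledger. Each stage is costed by exactly one
method:

* **micro** — built from components: staff tasks (minutes × salary-grade
  midpoint × overhead multiplier / annual working minutes), batch-amortised
  consumables (run cost / batch size × 3 samples per trio), and capital
  items;
* **charge** — an external provider's invoice price passed through, with
  VAT (default 20%) added when flagged;
* **calibrated** — a per-trio stage total taken as given.

Capital enters as an *annual equivalent cost*: the purchase price (inflated
to the base year if bought earlier) converted to a constant annual charge
with the annuity factor \(r / (1 - (1+r)^{-L})\) at discount rate
\(r = 0.035\) and lifetime \(L\); at \(r = 0\) this reduces to straight-line
\(K/L\), and the implementation treats that limit exactly. The annual
charge plus maintenance is scaled by the fraction of equipment time used
for WGS and divided by annual trio throughput (whole trios:
`floor(samples / 3)`, so 100 samples/year is 33 trios).

Probability-weighted branches (e.g. an MDT review in 50% of cases, a
separate blood-draw visit for 75% of the 60% needing a new sample) are
expressed as per-component probabilities plus a stage-level branch
probability. Staff time ranges ("15 min to 1 h", "5–20 min") are costed at
the midpoint by default with a low/mid/high switch for sensitivity runs —
the midpoint is our estimator choice, as the source gives ranges without
one. Default overhead multiplier and annual working minutes are
illustrative configuration values, not published figures.

The packaged stage file `wgs_stages_sgp_2018.yaml` encodes the 2018
13-stage pathway of one Scottish regional genetics centre. Because the
staff rates and consumable prices inside the micro-costed stages were
never published, those stages carry `calibrated` per-trio totals; the
micro-costing machinery itself is validated against closed forms and
synthetic stage definitions in the test suite rather than by re-deriving
the centre's internal numbers. Sequencing is stored *net* (£850/sample ×
3) with VAT applied at costing time — the gross/net pair published for
that stage pins the 20% rate — while the data-analysis and storage charges
are VAT-inclusive pass-throughs, the printed per-trio prices being all
that is known about them. Patient feedback is costed for 100% of trios,
the stated assumption in the absence of attendance data. The ledger total
is reported to the nearest pound; summing full-precision stages or
pre-rounded rows gives the same headline figure here, so the distinction
is moot.

## Preference summaries

The interview module is deliberately descriptive: willingness-to-pay (WTP)
statistics are computed over quantified responses only, with
"would-pay-but-can't-quantify" answers counted and their narrative codes
retained rather than imputed — conditional statements ("if quality of life
improved") are classified non-quantified, never converted to numbers. The
even-n median is the mean of the central pair. The rating exercise reports
per-attribute score distributions and the count of participants rating all
five attributes at the maximum; only complete five-attribute responders
enter that count's denominator. The packaged WTP file reproduces the nine
published interview responses exactly; the ratings file is synthetic by
necessity (only the "four of nine rated everything 5" margin was
published) and is named accordingly.

## The synthetic cohort generator

The generator's defaults encode the study conditions it emulates: 393
submitted screening forms of which 259 are costable and 134 carry an
unidentifiable test name; category mix 37% intellectual disability, 21%
neurodevelopmental/neurological, with the 17 remaining categories sharing
the residual 42% uniformly (only the top two proportions were published);
per-proband test counts on {1..16} with mean 2.32 and SD 2.08; per-proband
total test costs with mean £1013.03, median £850 and range
[£90, £6784.39].

Calibration choices:

* **Costs** are lognormal, calibrated in closed form to mean *m* and
  median *q*: \(\mu = \ln q\), \(\sigma = \sqrt{2\ln(m/q)}\), then
  truncated to the published range by rejection sampling. A two-parameter
  lognormal cannot also match the published SD (£942.01): matching mean
  and median implies SD ≈ £657. We prioritise mean and median; the
  understated spread is a known limitation, and the published note that
  outliers were "patients with many single-gene tests" suggests a
  cost–test-count dependence the default generator does not model (costs
  are drawn independently of counts and then apportioned across tests with
  uniform Dirichlet weights). The truncation shifts the moments by under
  £5 at these parameters (tail masses < 3 × 10⁻⁴), well inside the
  sampling noise at n = 259.
* **Test counts** are a negative binomial renormalised onto {1..16}
  (equivalently zero-truncated with above-ceiling draws resampled), its
  two parameters solved by Nelder–Mead so the truncated mean and SD match
  2.32 and 2.08 within 10⁻³. The published IQR of 2 is not a calibration
  target — with mean and SD fixed the two-parameter family is fully
  determined — but is reproduced descriptively.
* **Determinism**: a single seed drives every draw; the same configuration
  yields identical cohorts, and the seed is recorded in the emitted
  metadata.

Each costable proband's drawn total is split across its tests and those
per-test prices are emitted as the cohort's costbook, so running the
pathway-costing pipeline over the generated files recovers the generator's
ground truth exactly (to floating-point) — a round-trip identity the test
suite asserts. What passing these tests shows is that the *pipeline*
computes the statistics it claims on data with the published marginal
structure; it does not show that real screening-form data share the
lognormal shape, the independence of cost and test count, or the uniform
residual category mix.

## Problem sizes and numerical checks

The test suite runs at desk scale, chosen as the sizes that make each
property informative: brute-force summary and Tukey-fence equivalence on
random fixtures of n ≤ 20; truncation-bound checks over 100 seeds at
n = 50; calibration checks at the published n = 259; a χ² goodness-of-fit
of category proportions at n = 10⁴ (α = 0.001); annuity continuity checked
at r = 10⁻⁸ against the r = 0 limit within 10⁻⁴ relative. The acceptance
script regenerates the default 393-record cohort and recomputes its mean
and median test cost and mean test count through the full costing
pipeline.

## Known limitations

* The generated cost SD is ≈ £657, not the published £942.01 (see above).
* Stage-internal compositions of the calibrated WGS stages are opaque;
  sensitivity switches (time point, overheads) only act on stages defined
  with `method: micro`.
* No cost-effectiveness, budget-impact or diagnostic-yield modelling:
  this package prices pathways, it does not value outcomes.
* Confirmatory cascade testing in relatives, WES, and the non-genetic
  parts of the odyssey appear only as pass-through unit costs if the user
  prices them in the costbook.
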