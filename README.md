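# odysseycost

Micro-costing tools for health-economic evaluation of genomic diagnostics
in rare disease, for analysts costing diagnostic pathways from an NHS (or
similar payer) perspective.

Undiagnosed rare-disease patients typically pass through a "diagnostic
odyssey" whose second-line genetic portion — repeated single-gene tests,
gene panels, epigenetic assays — is the *sub-odyssey* that trio
whole-genome sequencing (WGS) could replace. `odysseycost` answers the two
costing questions that comparison needs:

* **What does the standard pathway cost per proband?** Each proband's
  tests are priced from a unit-cost registry (*costbook*) with a tiered
  source preference (Scottish laboratory price, then UK laboratory price)
  and a workload-proxy fallback for unpriced tests: the mean cost of
  authoritative entries in the same amplicon/exon-count bin (1–10, 11–20,
  21–30, 31–40, 41+). Probands with unidentifiable tests are excluded and
  logged, not guessed. Hospital attendances are added at configurable
  counts and unit costs (default 2 × £295.61 general + 1 × £236.78
  genetics = £828.00), and cohorts are summarised overall and by
  rare-disease category with Tukey-fence (1.5 × IQR, type-7 quartiles)
  outlier flagging.
* **What does trio WGS cost per family?** A 13-stage ledger where each
  stage is *micro-costed* (staff minutes at salary-grade midpoint with
  overheads, batch-amortised consumables, capital as an annual equivalent
  cost `K·r/(1−(1+r)^−L)` at discount rate r = 3.5%), a pass-through
  *charge* (with VAT where applicable), or a *calibrated* per-trio total —
  with probability-weighted branches for conditional steps.

It also summarises stated-preference interview data (willingness-to-pay
and 1–5 attribute ratings) and ships a seeded synthetic-cohort generator —
truncated-lognormal costs calibrated in closed form to a target mean and
median, zero-truncated negative-binomial test counts moment-matched on
{1..16} — so the whole pipeline runs end-to-end with no patient-level
data.

## Worked example

```r
library(odysseycost)

ctx <- read_economic_context(odysseycost_example("context_sgp_2018.yaml"))
cb  <- read_costbook(odysseycost_example("costbook_demo_synthetic.csv"), context = ctx)
h   <- read_histories(odysseycost_example("histories_demo_synthetic.csv"))

split <- filter_costable(h, cb)   # proband D007 has an illegible test -> excluded
costs <- cost_pathways(split$included, cb)
costs
#> # A tibble: 7 × 6
#>   proband_id category            n_tests test_total attendance_total grand_total
#> 1 D001       intellectual disab…       3      1055               828       1883
#> 2 D002       neurodevelopmental…       2      1860               828       2688
#> 3 D003       cardiovascular dis…       1      1469.              828       2297.
#> ...
```

Each row decomposes a proband's pathway: `test_total` sums the resolved
unit costs (D003's 2016 panel price has been inflated to 2018 pounds;
D005's second test had no listed price and was costed from its amplicon
bin), `attendance_total` is the fixed £828, and `grand_total` is their
sum.

```r
summarize_cohort(costs, by = "overall")
#>   grouping group     n  mean    sd median   min   max   iqr
#> 1 overall  all       7 2095.  801.  2110.   918  3348  842.
```

The trio WGS ledger from the packaged 2018 stage configuration:

```r
led <- cost_wgs_pipeline(read_wgs_stages(odysseycost_example("wgs_stages_sgp_2018.yaml")), ctx)
glance(led)
#>   n_stages total_per_trio total_gbp largest_stage     largest_share_pct
#> 1       13          6625.      6625 Sequencing of DNA              46.2
```

Sequencing dominates at 46.19% of the £6625 per-trio total (£850/sample
net of VAT, £3060/trio gross), followed by data analysis (25.42%) and
storage (8.15%); `tidy(led)` returns the full 13-row stage table and
`autoplot(led)` draws it.

```r
summarize_wtp(read_wtp(odysseycost_example("wtp_interviews.csv")))
#>   n_total n_quantified n_non_quantified   min median  mean   max
#> 1       9            7                2   200   2000 2243.  5000
```

Seven of nine interviewees quantified a willingness to pay for WGS
(£200–£5000, median £2000); the two conditional "would pay but can't
quantify" answers are counted and their wording retained, never imputed.

A synthetic cohort at the study scale:

```r
coh <- simulate_cohort(cohort_config(seed = 1))   # 393 records, 259 costable
pc  <- cost_pathways(filter_costable(coh$histories, coh$costbook)$included, coh$costbook)
mean(pc$test_total); median(pc$test_total)
#> [1] 987.3085
#> [1] 780.3929
```

A thin command-line wrapper over the same functions lives at
`inst/cli/odysseycost.R` (subcommands `cost-pathways`, `cost-wgs`,
`simulate-cohort`, `summarize-preferences`, `validate`).

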