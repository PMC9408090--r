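# wpaicost

Health-related work productivity loss costing for fly-in fly-out (FIFO)
workforces.

Occupational health economists and workplace-health researchers routinely
need to translate survey measures of worker health into money: how much
productive time is lost to poor sleep, risky drinking, smoking, poor diet,
weight problems, physical inactivity, poor physical health and
psychological distress — and what that loss costs an employer per worker
and per 1000 workers each year. `wpaicost` implements that pipeline end to
end for WPAI-GH survey data collected under a 4-week recall, with a
calibrated synthetic cohort generator so every stage can be exercised and
tested without access to survey microdata.

## The model

Each worker is classified **high or low risk** on eight conditions using
standard screening cut-offs (K10 ≥ 22, SF-8 PCS < 50, sleep < 7 h and/or
bad quality, AUDIT-C ≥ 4 men / ≥ 3 women, current smoking, IPAQ < 600
MET-min/week, BMI outside [18.5, 25), < 2 fruit and/or < 5 vegetable
serves). Co-occurring conditions are tiered low (0–2), medium (3–4), high
(5+).

Productivity loss comes from the WPAI-GH items (hours reported over 4
weeks are divided by 4 to return to the weekly metric):

- absenteeism `a = missed / (missed + worked)`
- presenteeism `p = rating / 10` (0–10 impairment rating)
- total loss `t = a + (1 − a)·p`

all reported as percentages. Costs follow the human-capital approach with
an annual salary `S` (default AUD 134,323.20 = average weekly mining
earnings × 48 working weeks):

- unadjusted per-worker cost: `(x̄_high − x̄_low) / 100 × S`
- adjusted per-1000 cost: `prev/100 × β/100 × S × 1000`, where `β` is the
  condition's coefficient from an OLS regression of loss on age, gender,
  work characteristics, the eight condition flags and the multiple-risk
  tier.

Group differences are tested with tie-corrected Mann–Whitney,
Kruskal–Wallis and Dunn–Bonferroni tests; predictors of any loss and of
loss magnitude with a two-part (hurdle) model (logistic + OLS on the
positive subsample, with VIF diagnostics); and cost uncertainty with a
Monte-Carlo probabilistic sensitivity analysis (normal draws for
coefficients, moment-matched beta draws for prevalences, percentile 95%
certainty intervals).

## Worked example

```r
library(wpaicost)

bundle <- run_pipeline(cohort_config(n_workers = 216), seed = 2024,
                       n_sims = 1000)
bundle
#> Productivity-loss costing report: 216 workers analyzed (0 incomplete, 0 undefined loss)
#>
#> Loss summary:
#> # A tibble: 1 × 9
#>       n any_absenteeism_pct any_presenteeism_pct absenteeism_mean absenteeism_sd
#>   <int>               <dbl>                <dbl>            <dbl>          <dbl>
#> 1   216                22.7                 49.5             3.30           8.49
#>
#> Annual cost per 1000 workers (by measure):
#> # A tibble: 3 × 4
#>   measure      n_contributing total_cost mean_cost
#>   <chr>                 <int>      <dbl>     <dbl>
#> 1 absenteeism               4   3696475.   924119.
#> 2 presenteeism              8  38716031.  4839504.
#> 3 total                     8  38164218.  4770527.
#>
#> PSA 95% certainty intervals:
#> # A tibble: 3 × 4
#>   measure           mean    ci_low   ci_high
#>   <chr>            <dbl>     <dbl>     <dbl>
#> 1 absenteeism   3726542. -7464554. 15036943.
#> 2 presenteeism 38857961.  9830257. 65931729.
#> 3 total        36933534.  6369696. 65321734.
```

Here 216 synthetic workers were generated (22.7% reported any absenteeism,
49.5% any presenteeism), classified, scored and costed: the eight health
conditions account for an estimated AUD 38.2M of total productivity loss
per 1000 workers per year in this simulated cohort, with wide certainty
intervals reflecting the regression SEs at n = 216. `bundle$prevalence`,
`bundle$excess_costs`, `bundle$adjusted_costs`, `bundle$tiers` and
`bundle$two_part` hold the intermediate tables;
`write_report_bundle(bundle, "out/")` writes them all as CSV with a JSON
manifest.

The package also bundles the published cost tables of a real FIFO mining
survey as plain-text fixtures and can re-derive every figure from its
printed inputs:

```r
g <- golden_tables_check()
sum(g$pass)
#> [1] 55   # of 56; one published cell is internally inconsistent by AUD 9
```

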