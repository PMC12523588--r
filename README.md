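# mcdaval

Multicriteria decision analysis (MCDA) for assessing the comprehensive
value of a medicine, written for health-technology-assessment analysts
and hospital formulary committees who need a transparent, reproducible
alternative to spreadsheet scoring.

The package covers the full workflow around a weighted-sum MCDA model:

* **AHP weighting** — criterion weights from expert pairwise-comparison
  matrices on the Saaty 1–9 scale: principal-eigenvector priorities
  (power iteration, with the row-geometric-mean method as a
  cross-check), consistency diagnostics (CI, CR against Saaty's random
  indices, acceptability at CR < 0.1), geometric-mean group aggregation
  optionally weighted by expert authority coefficients
  *Cr = (Ca + Cs)/2*, and two-level hierarchy composition
  (global weight = domain weight × local weight).
* **Evidence scoring** — expert panels score each strategy on each
  criterion from 1–10; the comprehensive score of a criterion is
  *CS = W<sub>c</sub> × ESc* (global weight × mean expert score) and a
  strategy's overall value is *CS = Σ W<sub>c</sub> × ESc* over all
  criteria, with domain subtotals and rankings.
* **Sensitivity analysis** — overall values recomputed under alternative
  domain-weight scenarios, with rank-stability assessment and top-two
  margins.
* **Pharmacovigilance signals** — disproportionality screening of
  spontaneous adverse-event reports: PRR with Pearson χ² (Yates by
  default), ROR with 95% Wald CI, and the dual signal rule
  (PRR > 2 ∧ χ² ≥ 4) ∧ (N ≥ 3 ∧ CI low > 1).
* **Economics & access** — annual/daily treatment cost from a dosing
  regimen, affordability as a share of household disposable income
  (with a brute-force calibrator for the household-size parameter), and
  formulary coverage rates.
* **Simulators** — seeded generators for expert judgments, score panels
  and case-level report tables, so every stage can be exercised and
  calibrated end-to-end without confidential expert or patient data.

A complete published case study — omalizumab plus standard of care (SOC)
versus SOC alone for moderate-to-severe pediatric asthma — ships as an
in-code fixture (`omalizumab_case_study()`).

## Worked example

Score the bundled case study and check rank stability:

```r
library(mcdaval)

fx <- omalizumab_case_study()
report <- value_report(fx$criterion_weights, fx$scores,
                       domains = setNames(fx$scores$domain,
                                          fx$scores$criterion))
report
#> MCDA value report
#>
#> Overall strategy scores:
#>  strategy overall_cs rank
#>   OMZ+SOC       7.40    1
#>       SOC       7.20    2
#>
#> Domain comprehensive-score subtotals:
#>  strategy        domain domain_cs
#>   OMZ+SOC        safety      2.81
#>   OMZ+SOC effectiveness      2.35
#>   OMZ+SOC     economics      0.57
#>   OMZ+SOC    innovation      0.70
#>   OMZ+SOC applicability      0.47
#>   OMZ+SOC accessibility      0.50
#>       SOC        safety      2.83
#>       SOC effectiveness      1.94
#>       SOC     economics      0.72
#>       SOC    innovation      0.51
#>       SOC applicability      0.54
#>       SOC accessibility      0.66
```

Adding omalizumab scores 7.40 points overall against 7.20 for SOC alone:
it wins on effectiveness (2.35 vs 1.94) and innovation (0.70 vs 0.51),
loses on economics, applicability and accessibility, and the safety
domains are nearly tied. The ranking survives all six published
alternative weightings:

```r
ds <- domain_effective_scores(from_totals = fx$domain_cs_printed,
                              domain_weights = fx$domain_weights_percent / 100)
check_rank_stability(fx$domain_weights_percent,
                     weight_scenarios(fx$scenarios, allow_reorder = TRUE),
                     ds)
#> Rank stability across 6 scenarios: STABLE
#> Baseline ranking: OMZ+SOC > SOC
#>
#>            OMZ+SOC  SOC margin
#> scenario_1    7.37 7.21 0.1641
#> scenario_2    7.46 7.15 0.3114
#> scenario_3    7.34 7.18 0.1575
#> scenario_4    7.47 7.12 0.3557
#> scenario_5    7.40 7.20 0.1968
#> scenario_6    7.37 7.23 0.1383
```

Screen a drug-event pair for a disproportionality signal:

```r
flag_signal(contingency_2x2(223, 1455, 5000, 600000, event = "urticaria"))
#> urticaria: N = 223 | PRR = 16.08, chi2 = 3030.79 (+) | ROR = 18.39 [15.93, 21.23] (+) -> signal: YES
```

Affordability of the annual regimen (2 × 150 mg vials monthly at
¥1,319.39 per vial) against the national per-capita disposable income:

```r
round_half_up(affordability(annual_cost(1319.39, 2, 12), 41314))
#> [1] 29.25
```

i.e. a year of treatment costs 29.25% of an average household's
disposable income before reimbursement.

The methods vignette (`vignettes/comprehensive-drug-value.Rmd`) explains
the model, its assumptions, the calibrated parameters and the known
rounding quirks of the published tables.

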