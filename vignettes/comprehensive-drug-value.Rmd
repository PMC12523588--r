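---
title: "Assessing comprehensive drug value with mcdaval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing comprehensive drug value with mcdaval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdaval)
```

## The problem

Formulary and reimbursement decisions about a medicine rarely hinge on a
single outcome. A biologic such as omalizumab for moderate-to-severe
pediatric asthma is more effective than standard of care (SOC) but far
more expensive, harder to distribute (cold chain, subcutaneous
injection), and has its own safety profile. Multicriteria decision
analysis (MCDA) makes the trade-off explicit: a panel of experts agrees
on a hierarchy of value criteria, weights them, scores each treatment
strategy on each criterion against an evidence matrix, and aggregates
weights and scores into one comparable value per strategy.

`mcdaval` implements that workflow end to end:

1. **Weighting** — analytic hierarchy process (AHP) on expert pairwise
   judgments, with consistency diagnostics and group aggregation;
2. **Scoring** — summarizing expert score panels and combining them with
   the weights into comprehensive scores;
3. **Sensitivity** — recomputing the ranking under alternative domain
   weightings;
4. **Safety evidence** — disproportionality screening of spontaneous
   adverse-event reports (PRR and ROR);
5. **Economics and access** — affordability and formulary-coverage
   calculators;
6. **Simulation** — seeded generators for every input, so the pipeline
   can be exercised and calibrated without confidential expert data.

## The model

### Criterion weights (AHP)

Experts compare elements pairwise on the Saaty scale (1 = equally
important, 9 = extremely more important, reciprocals for the converse),
giving a reciprocal matrix $A$ with $a_{ij} a_{ji} = 1$. The priority
vector $w$ is the principal right eigenvector of $A$, normalized to sum
to 1. We compute it by power iteration (tolerance $10^{-10}$, at most
10,000 sweeps); the row-geometric-mean vector is available as a
cross-check and coincides with the eigenvector whenever the matrix is
consistent ($a_{ij} = w_i / w_j$). Judgment coherence is measured by the
consistency index $CI = (\lambda_{\max} - n)/(n - 1)$ scaled by Saaty's
random index into the consistency ratio $CR$; matrices with $CR < 0.1$
(the conventional bar, configurable) are accepted. A reciprocal
$2 \times 2$ matrix is always consistent, so $CR \equiv 0$ there.

Multiple experts are combined *before* weight extraction by the
element-wise geometric mean, optionally weighted by each expert's
authority coefficient $Cr = (Ca + Cs)/2$ — the mean of an influence and
a familiarity coefficient, each on $[0,1]$; panels with every
$Cr > 0.8$ are flagged authoritative. The geometric mean is the only
averaging rule that preserves reciprocity exactly, which is why it is
the default here; the unweighted variant is used unless authority
coefficients are supplied.

The hierarchy has two levels: domains (safety, effectiveness,
economics, innovation, applicability, accessibility in the bundled case
study) and criteria within domains. A criterion's global weight is its
domain weight times its local weight, so global weights sum to 1.
Weight vectors that miss the simplex by more than $10^{-6}$ — printed
tables often sum to 100.01% after rounding — are renormalized with a
warning.

### Comprehensive scores

Each expert scores each strategy on each criterion on a 1–10 integer
scale (poor 1–3, moderate 4–7, excellent 8–10; non-integer means are
banded by rounding half-up). With $ESc$ the mean expert score of a
criterion and $W_c$ its global weight, the criterion's comprehensive
score is

$$CS_c = W_c \times ESc_c,$$

and a strategy's overall value is the sum over all criteria,

$$CS_{\text{strategy}} = \sum_{c} W_c \times ESc_c,$$

which lies in $[1, 10]$ whenever weights sum to 1. All arithmetic is
done on unrounded values; rounding (half-up, two decimals) happens only
at display. Standard deviations use the sample ($n-1$) denominator.
Missing expert scores are excluded pairwise with a reported count.

### Sensitivity analysis

A domain's *effective score* for a strategy is the local-weight-weighted
mean of its criteria's $ESc$ — equivalently, the domain's $CS$ subtotal
divided by the domain weight. Alternative weight scenarios (percent per
domain, summing to 100) are applied as
$\sum_d (\text{weight}_d / 100) \times \text{score}_d$; the analysis is
*stable* when every scenario reproduces the baseline ranking. The
scenario validator refuses weight sets that break the baseline
hierarchical order of the domains unless explicitly overridden — the
bundled published scenarios themselves bump one domain at a time out of
order, so they are loaded with the override. Margins between the top
two strategies are reported to four decimals so near-ties stay visible.

### Pharmacovigilance signals

For one drug-event pair in a spontaneous-report database, with $a$
reports mentioning both, $b$ the drug with other events, $c$ other
drugs with the event and $d$ the rest:

$$PRR = \frac{a/(a+b)}{c/(c+d)}, \qquad ROR = \frac{ad}{bc},$$

with a Wald interval on the log odds ratio,
$\exp(\ln ROR \pm z_{0.975} \sqrt{1/a + 1/b + 1/c + 1/d})$. A signal
requires **both** published rules: $PRR > 2$ (strict) with Pearson
$\chi^2 \ge 4$, and case count $N = a \ge 3$ with the lower 95% limit
of the ROR $> 1$ (strict). The $\chi^2$ uses the Yates continuity
correction by default (the convention of the PRR criterion and of
common screening tools); the uncorrected statistic is a flag away.
Zero cells raise an error by default; an optional Haldane–Anscombe
$+0.5$ correction on all four cells is available for both estimators.
`screen_events()` tabulates the $2\times2$ per event at report level
(a report mentioning a pair twice counts once) from
(`report_id`, `drug`, `event`) rows, normalizing names only by case
folding and trimming.

### Economics and accessibility

Annual cost is price per vial × vials per administration ×
administrations per year; the bundled case study uses 12 monthly
administrations of 2 × 150 mg vials, which is what reproduces the
published course cost of ¥31,665.36 at ¥1,319.39 per vial (13
every-4-weeks administrations would not). Daily cost divides by 365.
Affordability is the annual cost as a percentage of household
disposable income, i.e. per-capita income × household size. The
published table never prints the household size; the package recovers
it by a brute-force grid search (1.00–4.00 in steps of 0.01,
minimizing the maximum absolute deviation over all six published
percentages), which lands at **2.62** persons and reproduces every cell
to two decimals. That value is the documented default, overridable
everywhere it is used. Formulary coverage is stocked/total per
institution type; the overall rate uses summed counts and therefore
equals the count-weighted mean of the per-type rates.

## The bundled case study

`omalizumab_case_study()` returns the published evaluation of
omalizumab + SOC versus SOC alone as a fixture: printed domain weights,
the expert score table (mean ± SD and comprehensive scores), six
sensitivity scenarios with their printed results, the economics inputs
and the top adverse-event signal statistics.

Two honest caveats about that table, reflected in the package's
choices:

* The raw expert judgment matrices were never published, so the printed
  weights **cannot** be derived from first principles; they enter as
  inputs. What the package demonstrates instead is *recovery*: synthetic
  judgments generated around a known weight vector are aggregated and
  the AHP path returns that vector within tight tolerance.
* The printed table is internally rounded: criterion comprehensive
  scores sum to 7.38 while the printed domain totals sum to 7.40, and
  one printed criterion weight (guideline recommendations, 15.34%) is
  irreconcilable with its own printed $CS/ESc$ ratio (≈14.4%). The
  fixture therefore derives each criterion's weight from the table's own
  arithmetic — the mean of $CS/ESc$ over the two strategy columns —
  which pins the printed cells but sums to 0.9916 rather than 1. The
  vector is deliberately left unnormalized in fixture mode, and all
  regression comparisons against printed values use a 0.02 band.

```{r case-study}
fx <- omalizumab_case_study()
report <- value_report(fx$criterion_weights, fx$scores,
                       domains = setNames(fx$scores$domain,
                                          fx$scores$criterion))
report$overall
```

```{r sensitivity}
ds <- domain_effective_scores(from_totals = fx$domain_cs_printed,
                              domain_weights = fx$domain_weights_percent / 100)
st <- check_rank_stability(fx$domain_weights_percent,
                           weight_scenarios(fx$scenarios,
                                            allow_reorder = TRUE),
                           ds)
st
```

## What the simulators emulate — and what they do not

`simulate_judgments()` draws each upper-triangle entry as
$(w_i / w_j)\,e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, with
exact reciprocals below the diagonal, optionally snapped to the nearest
Saaty value in log space. Snapping bounds attainable recovery: ratios
below about 1.41 collapse to 1, so domains with near-equal true weights
become exact ties and only the weak ordering is recoverable.
`simulate_scores()` draws integer scores as rounded, clipped
$N(\text{mean}, \text{sd})$ — note the clip and the integer grid bias
the expectation by a few hundredths for means near the scale ends, so
large-panel convergence is asserted against the exact discretized
expectation, not the continuous mean. `simulate_reports()` assigns each
report a drug (target with a set share) and an event from a background
distribution, multiplying the target drug's probabilities by a
reporting-rate ratio $\lambda$ for implanted signals.

Each generator consumes its own RNG stream derived from the master seed
by a fixed offset, so outputs are bit-reproducible and adding a
generator never shifts existing draws.

These simulators emulate elicitation noise and reporting
disproportionality — they do **not** emulate real spontaneous-report
data (duplicate case versions, MedDRA coding, drug-name variants,
co-medication confounding) or real expert behaviour (anchoring,
correlated judgments across criteria). Passing recovery tests shows the
estimators are correctly implemented and calibrated under the stated
generative model, not that the published study's expert process was
unbiased.

## Numerical choices and problem sizes

* Power iteration: tolerance $10^{-10}$, max 10,000 sweeps; matrices up
  to order 15 (the extent of the random-index table).
* Rounding half-up at two decimals for display only; JSON exports carry
  17 significant digits so reports round-trip exactly.
* Ranking ties share the minimum rank and are reported as ties.
* Test-suite simulation sizes: 200 random matrices for the eigensolver
  cross-check, 1,000 random tables for the disproportionality oracles,
  10,000 replicates for confidence-interval coverage, report tables of
  5,000–50,000 rows for signal power and null calibration — each chosen
  as the smallest size at which the checked property is statistically
  clear-cut.

## Limitations

Two hierarchy levels only; no fuzzy or interval AHP; no imputation of
missing judgments; no Bayesian disproportionality (BCPNN/GPS); no
cost-effectiveness modelling (published ICERs are treated as evidence
to be scored, not recomputed); no currency conversion. Probabilistic
sensitivity analysis over weights (e.g. Dirichlet sampling) is a
natural extension but deliberately out of scope.
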