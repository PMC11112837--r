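---
title: "Methods: agreement, accuracy and cost-minimization for two-grader DR screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, accuracy and cost-minimization for two-grader DR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscreen)
```

## The problem

A diabetic retinopathy (DR) screening program photographs both eyes of each
patient and grades the images twice: once by an ophthalmologist (the
reference standard) and once by an autonomous AI system (the index test).
`drscreen` answers three questions about such a program:

1. **Do the graders agree?** Ordinal agreement on the 4-level ICDR-derived
   scale and binary agreement on any-DR and on maculopathy.
2. **How accurate is the AI grader?** Sensitivity, specificity, accuracy and
   prevalence against the manual reference, with binomial confidence
   intervals.
3. **Which screening strategy is cheaper?** A cost-minimization model —
   appropriate because the diagnostic evaluation treats the strategies as
   equally effective — with deterministic sensitivity analyses.

## Grade coding and eligibility

Grades are coded 0 (no DR), 1 (mild NPDR), 2 (moderate NPDR) and
3 (severe NPDR/PDR). Severe non-proliferative and proliferative disease are
collapsed into one top category because the agreement analysis is defined on
a four-category scale. Maculopathy is a separate binary outcome, not a grade
level. An eye flagged ungradable by *either* grader is excluded from all
paired analyses (`filter_gradable()`): an eye one grader cannot assess
cannot contribute a pair. Binarization uses "any DR" (grade ≥ 1) for the
headline analysis; "referable DR" (grade ≥ 2) is available via
`threshold = 2`.

## Inter-grader agreement

For a $k \times k$ table of cell proportions $p_{ij}$ with marginals $r_i$,
$c_j$ and agreement weights $w_{ij}$ ($w_{ii} = 1$),

$$P_o = \sum_{ij} w_{ij} p_{ij}, \qquad
  P_e = \sum_{ij} w_{ij} r_i c_j, \qquad
  \kappa_w = \frac{P_o - P_e}{1 - P_e}.$$

Identity weights give Cohen's unweighted kappa; linear weights
$w_{ij} = 1 - |i-j|/(k-1)$ are the package default for the 4-level scale,
giving partial credit for near-miss grades. Linear rather than quadratic
weighting is the default because one-step disagreements on a 4-level
clinical scale are penalised proportionally to their distance, and it is the
scheme under which the packaged fixture reproduces its published statistic
(quadratic weighting yields a higher value; both are selectable).

Standard errors use the asymptotic large-sample variance of weighted kappa
(Fleiss–Cohen–Everitt form); the p-value tests $\kappa = 0$ with the
null-hypothesis variant of the same variance. The scheme and sample size are
recorded in the result so the choice is always auditable. Kappa is undefined
when $P_e = 1$ (all mass in one marginal pair); the package raises an error
rather than returning a conventional value. Unused categories keep their
rows and columns: weights remain defined over the full scale.

Verbal interpretation follows the Landis–Koch convention with
upper-inclusive bands: ≤ 0.20 poor, 0.21–0.40 fair, 0.41–0.60 moderate,
0.61–0.80 good, 0.81–1.00 very good. Spearman's rank correlation (average
ranks for ties, via `stats::cor.test`) is reported alongside kappa as a
scale-free check on the ordinal association.

## Diagnostic accuracy and confidence intervals

From a 2×2 table with the manual grading as reference:
prevalence $(tp+fn)/n$, sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$,
accuracy $(tp+tn)/n$. A metric with a zero denominator is reported as
undefined (`NA`), never as 0.

Three binomial interval methods are available:

* **Wald**: $\hat p \pm z_{\alpha/2}\sqrt{\hat p(1-\hat p)/n}$, clipped to
  $[0,1]$. Symmetric, anti-conservative for small $n$ or extreme $\hat p$.
* **Clopper–Pearson**: exact beta-quantile bounds
  $\mathrm{qbeta}(\alpha/2;\,x,\,n-x+1)$ and
  $\mathrm{qbeta}(1-\alpha/2;\,x+1,\,n-x)$, with bound 0 at $x=0$ and 1 at
  $x=n$. Guarantees at-least-nominal coverage (verified by exhaustive
  enumeration in the test suite for all $n \le 25$).
* **Wilson**: the score interval, inside $[0,1]$ by construction.

Defaults: the DR analysis uses the Wald interval for prevalence and
Clopper–Pearson for sensitivity, specificity and accuracy; the maculopathy
analysis — a much rarer outcome, where the normal approximation is
unreliable — uses the exact interval for every metric. Any method can be
forced per call. Reported percentages round half-up to one decimal.

## The cost-minimization model

Each strategy's per-patient total is affine in its parameters:

$$C = v \, (\text{fee} + m \cdot \text{transport}
      + \text{hours} \times \text{rate}),$$

with $v$ visits (default 1) and transport multiplier $m$ (default 1: the
transport figure is already a round trip). Baselines (USD): manual
screening fee \$164 (fundus-photography DRG weight), AI fee \$33 (US 2021
reimbursement), round-trip transport \$73, patient time valued at \$24/h for
1.5 h (manual) or 1 h (AI), giving totals \$273 and \$130 and a per-patient
difference of \$143 in favour of AI. Grader labor is excluded: it is assumed
equal across strategies and cancels from the difference. Amounts quoted in
NOK convert at 9.89 NOK/USD (`nok_to_usd()`). All arithmetic is exact
double precision; rounding to whole dollars happens only in printed reports.

Cohort totals scale linearly in the number of patients, and a mixed program
screening a fraction $f$ of patients with one strategy costs the convex
combination of the two cohort totals.

## Sensitivity analyses

One-way and two-way deterministic sweeps substitute grid values into fresh
copies of the base strategies (bases are never mutated) and record both
totals and their difference; two-way sweeps evaluate the full cartesian
product with inclusive endpoints. Default grids mirror the plausible ranges
of the inputs: AI fee \$33–\$164 (up to the manual DRG weight), manual
patient time 0.5–2 h, AI patient time 5 min (1/12 h, stored unrounded) to
2 h. Because the model is affine, swept differences are exactly linear in
the varied parameter — the test suite checks that second differences vanish.
`break_even()` exploits the same affinity: two evaluations determine the
root in closed form; a bisection fallback covers any non-affine extension,
and `NA` is returned when no root lies in the bracket.

## The synthetic cohort generator

`generate_cohort()` emulates a two-grader screening day: manual grades drawn
from a four-category distribution (default shares 81/3/11/5 %), AI grades
drawn from a row-stochastic confusion matrix conditioned on the manual grade
(default: identity except moderate eyes down-graded to mild with probability
2/7), a per-eye maculopathy probability (default 3.1 %, flagged identically
by both graders — the evaluated cohort showed perfect maculopathy
concordance, and the parameter set deliberately has no separate maculopathy
confusion), and a small per-eye ungradable rate (default 2/66) flagged
concordantly by the AI with probability 1. Each call uses its own seeded RNG
stream and restores the global state.

The generator reproduces the *structure* of a real screening cohort —
marginal grade distribution, grader confusion, paired eyes, ungradable
images — but not everything real data carries: no within-patient correlation
between eyes, no association between DR grade and maculopathy or
gradability, and no image-level covariates. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
sampling model, not robustness to those real-world dependencies.

`oslo_fixture()` is the deterministic reconstruction of the evaluated
66-eye cohort: the printed percentage shares, converted to integer counts
over 64 gradable eyes by largest-remainder rounding, admit exactly one
contingency structure consistent with both graders' marginals and perfect
binary agreement — two eyes graded moderate manually and mild by the AI.
The two ungradable eyes (one eye in each of two patients) and the two
concordant maculopathy-positive eyes complete the table.

## Problem sizes and numerical choices

The packaged analyses are desk-scale: the fixture has 66 eyes and every
published statistic recomputes in well under a second. The test suite's
stochastic checks use cohorts of 2,000 patients for distributional
convergence and 200 replicates of 5,000 patients for confidence-interval
parameter recovery (generating sensitivity 0.9 / specificity 0.95 and
requiring ≥ 90 % CI coverage), which completes in a few seconds. Tolerances:
probability-vector and weight-matrix validation at $10^{-9}$; kappa
identity-equivalence and permutation/scaling invariances at $10^{-12}$;
closed-form vs bisection break-even agreement at $10^{-6}$.

## Known limitations

* Two raters only: no multi-rater kappa, Krippendorff's alpha, or bootstrap
  kappa intervals.
* Categorical graders: no ROC/AUC, and no predictive values re-weighted to
  an external prevalence.
* The economic model is cost-minimization with a single visit horizon — no
  discounting, QALYs, or probabilistic sensitivity analysis.
* Eyes, not patients, are the analysis unit; confidence intervals ignore
  the pairing of eyes within patients (as is common in small screening
  evaluations, but anticonservative if eyes within a patient are highly
  correlated).
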