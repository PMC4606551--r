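---
title: "Dynamic association rules: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic association rules: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darules)
```

## The problem

Association rule mining asks, for a rule *A → B* over *n* baskets, whether the
joint frequency (*support* = n~AB~/n) and the conditional frequency
(*confidence* = n~AB~/n~A~) are large enough to matter. Classical miners take
the two thresholds as user knobs; different knob settings give different gene
lists and there is no principled way to pick them. `darules` replaces the
knobs with *dynamic* thresholds: the one-sided (1 − α) upper bounds of the
null distributions of support and confidence when antecedent and consequent
are independent. A rule is **meaningful** only if both of its estimates
strictly exceed its own thresholds — strictly, so a rule sitting exactly on
a bound fails.

In the transcriptomic setting a basket is a sample, the antecedent is one or
two gene-level items such as `+1:geneA` (gene A over-expressed), and the
consequent is a phenotype class. The pipeline is: normalize, discretize to
labels in {−1, 0, +1}, mine with per-rule dynamic thresholds, screen out
ambiguous rules, and report the final gene set.

## Null models

**Support.** With antecedent indicator ~ Bernoulli(p₁) and consequent
indicator ~ Bernoulli(p₂) independently, n~AB~ ~ Bin(n, p₁p₂), so the
estimated support is approximately Normal(p₁p₂, √(p₁p₂(1 − p₁p₂)/n)) and

  s_min = p₁p₂ + z~α~ √(p₁p₂(1 − p₁p₂)/n).

`minimum_support()` implements this closed form (with an exact-binomial
quantile as an option, `method = "exact-binomial"`). Marginals are estimated
per rule: p̂₁ = n~A~/n, p̂₂ = n~B~/n, with the consequent marginal taken as
the class frequency among **all** samples. When p₁p₂ is 0 or 1 the variance
term vanishes and the bound degenerates to p₁p₂ rather than erroring, which
keeps the miner total.

**Confidence.** Writing Z ~ Bin(n, p₁) for the number of antecedent baskets
and X | Z = z ~ Bin(z, p₂), the confidence is C = X/Z with exact null pmf

  P(C = c) = Σ~z~ Bin(z, cz, p₂) · Bin(n, z, p₁),

supported on the achievable ratios x/z. C is *defective* — the event Z = 0
carries probability (1 − p₁)ⁿ but no ratio — so `confidence_distribution()`
conditions on Z ≥ 1 and renormalises by 1 − (1 − p₁)ⁿ; for any realistic
n·p₁ the conditioned and unconditioned laws are practically identical. There
is no closed-form quantile: E(1/Z) does not exist, hence neither does
Var(X/Z), and the threshold must be computed numerically. The pmf reflects
atom-by-atom under c → 1 − c when p₂ → 1 − p₂ (at fixed p₁), a property the
test suite checks on a grid of marginal combinations. (Descriptions of this
symmetry sometimes attribute it to p₁; the reflection is in p₂, which is
what the package implements and verifies.)

Equal ratios such as 1/3 and 333/999 are merged by exact integer arithmetic
on reduced fractions, never by floating-point comparison, so the atom list
is deterministic at any n.

## Quantile conventions for a discrete distribution

Because the null confidence distribution is discrete, "the (1 − α) upper
quantile" needs a reporting convention. The package implements two and the
choice matters only in the last printed digit:

* **`convention = "grid"` (default).** Achievable ratios are binned to the
  *nearest* point of a 0.001 grid; the critical value is the first grid
  point whose binned CDF reaches 1 − α, minus half a step (so reported
  values end in 5 at the fourth decimal). This convention was calibrated
  against the reference critical-value table at n = 1000 and reproduces all
  100 of its cells exactly (`critical_value_table()`), including the worked
  example value 0.7425 at (n = 1000, p₁ = 0.3, p₂ = 0.7, α = 0.05). Two
  nearby alternatives — binning atoms at or strictly below each grid point —
  reproduce only about half the cells, each off by one grid step.
* **`convention = "atom"`.** No grid: the smallest achievable ratio *a* with
  P(C ≥ a) ≤ α is located and the midpoint between *a* and the preceding
  achievable ratio is reported. This gives the exact guarantee
  P(C > c_min) ≤ α and reproduces the reference small-cohort values at
  n = 16, p₁ = 10/16, p₂ = 8/16: (10/13 + 7/9)/2 = 0.7735 at the 95% level
  and (7/10 + 5/7)/2 = 0.70714 ≈ 0.707 at 90%.

The two conventions disagree slightly at small n — the grid default gives
0.7685 and 0.6995 for the n = 16 case above — because with sparse atoms the
0.001 binning can place the crossing a few grid points away from the
atom-midpoint. We keep the grid convention as the default (it is the one the
large-n reference table defines) and expose the atom convention for exact
small-sample work; mining conclusions are insensitive to the choice in all
cases we examined (e.g. an observed confidence of 0.8 clears both variants
of the n = 16 threshold, and one of 1.0 clears any discrete threshold).

**Normal quantiles.** Printed worked values use z rounded to three decimals
(1.645, 1.282). `z_alpha(alpha, compat = "printed")` mirrors that and is the
default so reproduced numbers match print; `compat = "exact"` uses the
full-precision quantile. The difference is below 10⁻⁴ on every threshold.

## Back-solving and candidate pruning

Inverting the support bound for a target level s gives the quadratic
(n + z²)p² − (2ns + z²)p + ns² = 0 in the joint probability p = p₁p₂;
`back_solve_joint_probability()` returns the smaller root (the larger one is
an artefact of squaring) and the round-trip s → p\* → s is exact to 10⁻⁹.
The discriminant z²(z² + 4ns(1 − s)) is positive for every s in (0, 1), so
the no-root branch is defensive only.

`mine_rules(prune_by_backsolve = TRUE)` uses this inversion idea as a
candidate screen: a candidate whose maximum achievable support
min(n~A~, n~B~)/n cannot strictly exceed its own dynamic minimum support can
never be meaningful, whatever n~AB~ turns out to be, and is skipped before
the joint count is taken. Phrasing the screen through the *observed*
marginals (rather than through a fixed p\*/p₁ cutoff on the consequent
marginal alone) is what makes it exact; the test suite asserts the
meaningful rule set is bit-identical with and without pruning on batches of
random datasets.

## Discretization schemes

Five presets cover the case-study designs; each is exactly one normalization
followed by one labelling, and the preset used is recorded on the result:

| preset | normalization | labels |
|---|---|---|
| `threshold` | none (input already normalized, e.g. lowess MA) | value ≥ 1 → +1, ≤ −1 → −1 (inclusive) |
| `fold2` | per-gene baseline-group mean | ratio > 2 → +1, < 0.5 → −1 (strict) |
| `fold1.5` | per-gene baseline-group mean | ratio > 1.5 → +1, < 2/3 → −1 (strict) |
| `maqc-log` | per-gene baseline-group mean (log scale) | difference > 1 → +1, < −1 → −1 |
| `tsd` | per-sample median/IQR | per-gene z ≥ 1 → +1, z ≤ −1 → −1 (inclusive) |

Boundary strictness deliberately differs across schemes — the
threshold/z-score schemes are inclusive ("≥ 1"), the fold-change schemes
strict ("larger than") — preserving each scheme's own stated convention
rather than unifying them. The z-score labeller (transitional state
discrimination, TSD) uses the sample (n − 1) standard deviation by default
(`sd_type` switches to the population form); its labels are invariant to
positive affine transforms of a gene row, and zero-variance rows get label 0.
Missing values always label 0 ("not differentially expressed"), keeping the
basket semantics total; the fixed cutoffs treat every value in (−1, 1) as
not differentially expressed rather than distinguishing "no expression".
Two-colour data are normalized with `normalize_ma_lowess()` (M minus the
lowess trend of M on A); the smoother span is unstated in the source
procedures, so the conventional 2/3 is the exposed default.

## Screening ambiguous rules

Two conflict patterns among meaningful rules are removed by
`screen_rules()`:

* the identical antecedent itemset meaningful towards different consequents;
* the same gene meaningful at both +1 and −1 towards the same consequent
  (single-antecedent rules only — inside double antecedents a gene may
  legitimately act at both levels through interactions; level-0 items never
  conflict with either direction).

Both members of a conflict are removed; no ranking retains one side. Only
identical antecedent itemsets count as consequent conflicts: a single- and a
double-antecedent rule with overlapping items are not treated as
conflicting, an interpretation we document rather than extrapolate.
Screening is idempotent and never edits a surviving rule's fields; the final
gene set is the sorted union of surviving antecedent genes.

## The synthetic generator and what the tests do (and do not) show

`simulate_two_group_matrix()` emulates a small two-condition expression
screen: Gaussian noise, additive shifts of `effect` standard deviations in
the case group for planted genes, ids encoding ground truth, and full
reproducibility from the seed. Defaults are 100 genes (5 up, 5 down planted),
8 samples per group, unit noise, effect 4 — a deliberately clean caricature.
It does not model probe effects, dye bias, count overdispersion, batch
structure or gene–gene correlation, so green calibration tests demonstrate
statistical correctness of the thresholds, not robustness to real-data
artefacts. `simulate_independent_baskets()` (and its vectorised tally form
`simulate_rule_counts()`) draws the independence null itself and is the
Monte-Carlo oracle for the exact confidence distribution and for type-I
calibration: at (n = 200, p₁ = 0.3, p₂ = 0.5) the probability of exceeding
s_min is 0.0498 and of exceeding c_min 0.0515, both within the nominal
α = 0.05 plus discreteness, which the suite verifies over 50,000 replicates.

**A structural limitation of the TSD preset.** For a clean two-group shift
Δ with equal group sizes, the pooled per-gene standard deviation is inflated
by the separation itself: as Δ grows, every standardized value converges to
±(Δ/2)/(2Δ/√60) ≈ ±0.97 (8 v 8 samples), strictly inside the ±1 cutoffs.
Consequently TSD labelling cannot flag an arbitrarily strong clean shift —
planted-gene recovery through the full pipeline peaks near 10% at *any*
effect size under the generator's two-group design, and the corresponding
end-to-end recovery check in the acceptance suite documents this as a
failing expectation rather than hiding it. The same pipeline with the
`threshold` preset (cutoffs on the shifted values directly) recovers
essentially all planted genes at effect 4. TSD is best suited to designs
with minority subgroups, where the subgroup barely moves the pooled moments.

## Numerical choices

* Confidence CDFs sum Binomial terms over a z-range truncated where
  Bin(n, p₁) puts mass below 10⁻¹⁶ per tail; at n = 10⁵ the threshold agrees
  with the normal approximation p₂ + z~α~√(p₂(1 − p₂)/(np₁)) to within
  0.002.
* Grid-CDF comparisons use pure integer arithmetic
  (x < z(2k + 1)/(2K) ⇔ x ≤ ⌈z(2k + 1)/(2K)⌉ − 1), so no cell of the
  critical-value table depends on floating-point rounding.
* Per-rule confidence thresholds are memoised over distinct (n, n~A~, n~B~)
  pairs inside `mine_rules()`; thresholds depend on the marginals only,
  never on n~AB~.
* Thresholds are kept at full precision internally and rounded only at
  serialization (6 decimals in rule tables).
* Test problem sizes: the calibration experiment uses 50,000 replicates at
  n = 200; the recovery experiment 100 seeds of a 100 × 16 matrix; the
  Monte-Carlo oracle 200,000 basket sets at n = 30. These sizes give
  Monte-Carlo standard errors an order of magnitude below the tolerances
  they are tested against.

## Known limitations

* No multiple-testing correction, by design: with thousands of candidate
  rules the per-rule α is not a family-wise guarantee. `mine_rules()`
  reports the number of candidates evaluated so users can judge the testing
  burden.
* The dynamic thresholds assume independent samples; correlated replicates
  (e.g. paired designs) are not modelled.
* Antecedents are limited to one or two gene items, consequents to class
  labels; gene → gene rules and higher-order itemsets are out of scope.
* The confidence atom enumeration is O(n²) and intended for n up to a few
  thousand; quantiles at larger n go through the binned CDF, which is O(n)
  per grid point.
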