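# darules — dynamic association rules for gene expression data

`darules` mines association rules of the form *gene-level itemset →
phenotype class* (for example `+1:geneA → disease`) from discretized
expression data, and decides which rules matter **statistically** instead of
by user-chosen support/confidence knobs. It is aimed at analysts who want a
rule-based, interpretable complement to t-test-style gene selection for
two-class microarray, single-channel or RNA-seq expression matrices.

## The statistic at the core

For a rule *A → B* over *n* samples, with tallies n_A (antecedent), n_B
(consequent) and n_AB (both), the estimates are

    support = n_AB / n        confidence = n_AB / n_A

Under independence of A and B with marginals p1 = n_A/n and p2 = n_B/n:

* the support is Bin(n, p1·p2)/n, giving the closed-form one-sided bound

      s_min = p1·p2 + z_alpha * sqrt( p1·p2 (1 − p1·p2) / n )

* the confidence C = X/Z (X ~ Bin(Z, p2) given Z ~ Bin(n, p1), conditioned
  on Z ≥ 1) has the exact discrete null pmf

      P(C = c) = sum_z Bin(z, cz, p2) · Bin(n, z, p1)

  whose one-sided upper quantile has no closed form and is computed exactly.

A rule is **meaningful** only if support > s_min *and* confidence > c_min,
with both thresholds recomputed per rule from its own marginals ("dynamic").
Ambiguous rules — the same antecedent implying two classes, or one gene both
up and down towards the same class — are screened out, and the final gene
set is the union of the surviving antecedents.

## Worked example

```r
library(darules)

# the dynamic thresholds for a rule with n = 1000, n_A = 300, n_B = 700
minimum_support(0.3, 0.7, n = 1000, alpha = 0.05)
#> [1] 0.231188
minimum_confidence(1000, 0.3, 0.7, alpha = 0.05)
#> [1] 0.7425
```

Any rule with those marginals must exceed support 0.2312 **and** confidence
0.7425 to be meaningful at the 95% level. The full pipeline on synthetic
data with planted signal:

```r
sim    <- simulate_two_group_matrix(n_genes = 50, n_per_group = 8,
                                    n_planted_up = 3, n_planted_down = 3,
                                    effect = 5, seed = 42)
labels <- discretize(sim$expr, preset = "threshold")
rules  <- mine_rules(labels, sim$groups, alpha = 0.05)
#> evaluated 200 candidate rules without multiple-testing correction
glance(rules)
#> # A tibble: 1 × 6
#>   n_candidates n_rules n_meaningful n_final n_final_genes alpha
#>          <int>   <int>        <int>   <int>         <int> <dbl>
#> 1          200     184            4      NA             4  0.05

survivors <- screen_rules(rules)
dplyr::select(tidy(survivors), antecedent:confidence, s_min, c_min)
#> # A tibble: 4 × 6
#>   antecedent   consequent support confidence s_min c_min
#>   <chr>        <chr>        <dbl>      <dbl> <dbl> <dbl>
#> 1 +1:up_0002   case           0.5      1     0.428 0.800
#> 2 +1:up_0003   case           0.5      1     0.428 0.800
#> 3 -1:down_0001 case           0.5      1     0.428 0.800
#> 4 -1:down_0003 case           0.5      0.889 0.466 0.778
final_gene_set(survivors)
#> [1] "down_0001" "down_0003" "up_0002"   "up_0003"
```

Each surviving rule reads, e.g., "over-expression of `up_0002` implies the
case group": it holds in 8 of 16 samples (support 0.5 > s_min 0.428) and in
all samples showing the antecedent (confidence 1 > c_min 0.800). Planted
genes with weaker-than-threshold label patterns (here 2 of 6) are the ones
the dynamic thresholds decline to call.

Five discretization presets cover common designs (`threshold`, `fold2`,
`fold1.5`, `maqc-log`, `tsd`); `autoplot()` visualises rule sets and exact
null confidence distributions; `critical_value_table()` regenerates
reference threshold tables. A command-line wrapper is bundled:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dar.R", package="darules"))')" \
    thresholds --n 1000 --p1 0.3 --p2 0.7 --alpha 0.05
# s_min   0.2312
# c_min   0.7425
```

with subcommands `thresholds`, `table`, `simulate`, `mine`, `screen`, `run`.
See the methods vignette (`vignettes/dynamic-association-rules.Rmd`) for the
null models, the discrete-quantile reporting conventions and design
rationale.

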