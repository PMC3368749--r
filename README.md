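# ecpred

Is the top-level EC (Enzyme Commission) class of an enzyme-catalysed
reaction predictable from its stepwise chemical *mechanism*, or only
from the *overall* chemical transformation? `ecpred` is an R package
for researchers in cheminformatics and enzymology who want to run that
comparison as a controlled benchmark: it implements descriptor
encodings of both views of a reaction, the classifiers and the
cross-validation protocol used to compare them, balanced multi-class
metrics, an exact significance test for classifier pairs, and a
synthetic generator of MACiE-like reaction entries in which the degree
of mechanism conservation is a tunable parameter.

## What is inside

All chemistry is expressed in bond-change tokens `X.Y_a.b` — a bond
between elements X and Y changing order from a to b (0 = absent), so
`C.N_0.1` is a carbon–nitrogen single bond formed. On top of that
grammar the package provides five descriptor sets:

| set | view | encoding |
|---|---|---|
| `overall-bond` | overall | token counts, substrates → products |
| `composite-bond` | mechanism | token counts summed over every step (transient bonds register twice) |
| `human` | overall | 28 engineered features (`f:X-H`, `dv:C`, `water.OH-.su`, `Mod_Diff`, …) |
| `overall-sim` | overall | count-vector Tanimoto similarity to each reference entry |
| `mech-sim` | mechanism | Needleman–Wunsch step-alignment similarity, better of the two directions |

The count-vector Tanimoto is
`T(a, b) = Σ min(a_t, b_t) / (Σ a_t + Σ b_t − Σ min(a_t, b_t))`,
and the mechanism similarity aligns step sequences globally with
Tanimoto substitution scores, normalised by the longer mechanism.
Evaluation uses accuracy and Gorodkin's K-category correlation

```
R_K = (N·c − Σ_k t_k p_k) / sqrt((N² − Σ_k p_k²)(N² − Σ_k t_k²)),
```

the multi-class Matthews coefficient. Classifier pairs are compared
with an exhaustive fold-wise permutation test: all 2^10 = 1024 sign
assignments of the per-fold correct-count differences, two-sided,
`p = n/1024` with `n ≥ 2` structurally. Cross-validation applies the
leakage guard for similarity sets (test-entry *columns* are deleted
before training) and per-fold z-scaling for count sets; an
external-validation split keeps the test set non-redundant at the
third EC level.

## Worked example

Generate a 160-entry synthetic dataset with the default class priors
and mechanism heterogeneity 0.8, then ask whether the overall
bond-change encoding beats the mechanistic (composite) one:

```r
library(ecpred)

entries <- generate_dataset(generator_config(n_entries = 160, seed = 42))
spec <- classifier_spec("rf", grid = list(mtry = 6, n_trees = 300))

cv_overall <- benchmark_cell(entries, "overall-bond", spec, seed = 42)
cv_comp    <- benchmark_cell(entries, "composite-bond", spec, seed = 42)
cv_overall
#> 10-fold cross-validation (seed 42): accuracy 0.912, R_K 0.892
cv_comp
#> 10-fold cross-validation (seed 42): accuracy 0.812, R_K 0.768

round(cv_overall$per_class_accuracy, 3)
#>     1     2     3     4     5     6
#> 1.000 0.853 0.966 0.938 0.909 0.667

permutation_test(cv_overall, cv_comp)
#> fold-wise permutation test (two-sided): D0 = 16, n = 32 of 1024, p = 0.03125
```

Reading the output: the overall encoding classifies 91.2% of entries
correctly (R_K 0.892, so the success is not an artefact of class
imbalance) against 81.2% for the per-step encoding; oxidoreductases
(class 1) and hydrolases (class 3) are recognised almost perfectly
while transferases (class 2) — generated without a clear chemical
signature — lag. The permutation test says the 16-prediction gap
between the two encodings would arise by chance with probability
0.031, i.e. the overall view is significantly more predictive at the
5% level under this dataset's high mechanism heterogeneity. Published
baseline values for the real 260-entry benchmark are available via
`reference_cv_accuracies()`.

A thin command-line front end covering generation, benchmarking,
comparison and external splitting is installed at
`inst/scripts/ecpred` (see `system.file("scripts", "ecpred",
package = "ecpred")`).

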