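---
title: "Predicting EC class from reactions and mechanisms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting EC class from reactions and mechanisms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecpred)
```

## The question

Enzyme Commission (EC) numbers classify enzyme reactions by the overall
chemical transformation they catalyse: oxidoreductases (class 1),
transferases (2), hydrolases (3), lyases (4), isomerases (5) and
ligases (6). A reaction's *mechanism* — the ordered sequence of bond
making and breaking steps by which the transformation actually
proceeds — is a different object. If similar reactions tended to
proceed by similar mechanisms, descriptors of mechanism would predict
EC class about as well as descriptors of the overall transformation.
`ecpred` provides the machinery to test this: encodings of both views
of a reaction, classifiers and a leakage-safe cross-validation
protocol, balanced multi-class metrics, a significance test for
classifier comparisons, and a synthetic data generator in which the
degree of mechanism conservation is a controlled parameter rather than
an unknown of nature.

## Reaction entries and the bond-change grammar

An entry is an EC-labelled reaction record in the style of a MACiE
database entry: species (name, molecular formula, substrate/product
role), the overall bond changes, and a stepwise mechanism. All
chemistry is expressed in bond-change tokens `X.Y_a.b`: a bond between
elements `X` and `Y` changing order from `a` to `b`, with 0 meaning the
bond is absent. `C.N_0.1` is therefore the formation of a
carbon–nitrogen single bond, `O.O_2.1` an oxygen–oxygen double bond
becoming single. Tokens are canonicalised (elements alphabetical) and
restricted to integer orders 0–3; aromatic or partial orders are out of
scope, as every pattern the descriptor sets use is expressible with
integer orders. Species are identity-plus-formula records — there is
deliberately no SMILES/InChI parsing or atom mapping; the features that
reference particular species (water, NAD(P)(H), FAD(H2), O2, ATP,
ADP/AMP) do so by a fixed name registry.

The stored direction of an entry is taken as its canonical direction;
no direction inference is attempted. `reverse_entry()` implements the
reversal semantics needed by the mechanism similarity: roles swap,
every token `X.Y_a.b` becomes `X.Y_b.a`, and the step order reverses
with each step inverted. Validation enforces that the signed
composition of the mechanism steps equals the overall change, so a
*transient* bond — formed in one step, broken in a later one — cancels
from the net transformation while remaining visible to mechanistic
encodings.

## The five descriptor sets

* **Overall bond change** — token counts of the net transformation.
* **Composite bond change** — the same counts summed over every
  mechanism step; transient bonds register twice (formation plus
  cleavage), which is exactly what makes this a mechanistic encoding.
* **Human designed** — a registry of 28 engineered features of the
  overall reaction. Four anchors define the design intent: `f:X-H`
  (bonds to hydrogen formed), `dv:C` (total change in the sum of bond
  orders to carbon; a C–C token counts twice because both atoms are
  carbon), `water.OH-.su` (1 whenever water or hydroxide is a
  substrate — true for every hydrolase, though not only for
  hydrolases) and `Mod_Diff` (absolute molecular-weight difference
  between the largest substrate and largest product, 0.000 for
  isomerases by design; the absolute value is used because the sign
  would depend on the arbitrary stored direction). The remaining 24
  are documented analogues: cleaved-to-hydrogen totals, `dv:` for N,
  O, P, S, formed/cleaved totals for the C-C, C-N, C-O, C-S, P-O and
  O-H element pairs, flags for redox-cofactor, O2 and ATP-to-ADP/AMP
  involvement, an isomer flag, substrate/product counts and the net
  bond-order change. The exact published feature list is not
  reproduced here — this registry is an approximation with the same
  design intent, and `default_feature_registry()` can be replaced
  wholesale by any named list of entry functions.
* **Overall reaction similarity** — each entry described by its
  Tanimoto similarity to every reference entry, in the stored
  direction only.
* **Mechanistic similarity** — each entry described by the normalised
  Needleman–Wunsch alignment similarity of its step sequence to every
  reference entry's, with the better of the stored and reversed
  directions selected.

The Tanimoto coefficient is the count-vector (min-sum) form, not the
binary-fingerprint form, because the descriptors are occurrence
counts; on 0/1 vectors the two coincide. Degenerate conventions:
`T(∅,∅) = 1` and `T(∅, x≠∅) = 0` (such inputs only arise in edge
tests, not from the generator).

## Alignment choices

The mechanism alignment is a global Needleman–Wunsch over steps, with
the substitution score of step *i* against step *j* equal to their
Tanimoto similarity and a linear gap penalty. Defaults and rationale:

* **Gap penalty 0** — length mismatch is then penalised only through
  the normaliser, and the score is guaranteed non-negative.
* **Normaliser `max(n_a, n_b)`** — gives self-similarity exactly 1 and
  keeps values in [0, 1].
* With a strictly positive gap penalty the raw optimal score can go
  negative (a fully mismatched pair of different lengths); the score
  is floored at 0 before normalising so the reported similarity stays
  in [0, 1]. With the default penalty the floor never binds.
* Traceback ties prefer the diagonal (match) move; this affects only
  the reported step pairing, never the score.

These are explicit knobs, not claims about the original alignment
method for enzyme mechanisms, whose internals are not restated in the
sources available to this package. The implementation is verified
against an exhaustive enumeration of all monotone global alignments
for mechanisms of up to four steps.

## Evaluation

Accuracy is the proportion of correct predictions (the pooled
confusion-matrix trace over its total — with near-equal fold sizes the
difference from a fold-average is negligible). Because the six classes
are unbalanced and the tuner selects on accuracy, the package also
reports Gorodkin's K-category correlation coefficient
$$R_K = \frac{N\,c - \sum_k t_k p_k}
{\sqrt{(N^2 - \sum_k p_k^2)(N^2 - \sum_k t_k^2)}},$$
the multi-class generalisation of the Matthews coefficient (`N` total,
`t_k` row sums, `p_k` column sums, `c` the trace). On 2×2 tables it
equals binary MCC exactly; when a denominator factor vanishes (all
truth or all predictions in one class) it is defined as 0. Per-class
accuracy is class recall; classes absent from the truth are reported
missing, not 0.

Classifier pairs are compared with an exhaustive fold-wise permutation
test. With per-fold correct counts `NA_i`, `NB_i`, the observed
difference is `D0 = Σ(NA_i − NB_i)` and all `2^F` sign assignments are
enumerated (1024 for ten folds). The default criterion is two-sided,
`n = #{|Dp| ≥ |D0|}`, because that is the only reading under which the
structural bound `n ≥ 2` holds for `D0 ≠ 0`: both `D0` and `−D0` always
occur among the permuted values. Zero-difference folds count toward
`n` on equality (`≥`, not `>`). A one-sided option is retained.
Comparisons are reported as significant at the 5% level.

## The benchmark protocol

`cross_validate()` reproduces the full experiment for one
descriptor-set/classifier cell:

1. Entries are distributed into 10 folds uniformly at random
   (unstratified, as plain random distribution is the protocol;
   a stratified option exists but is off by default).
2. **Column deletion** for similarity sets: the columns corresponding
   to the fold's test entries are deleted from both partitions before
   any tuning or training, so the model never sees similarities *to*
   test entries. The Random Forest out-of-bag estimate, being defined
   on the training data, does not reflect these deletions — it is an
   internal estimate only.
3. **Scaling**: count/feature sets are z-scaled to mean 0, sd 1 using
   the *training-fold* distributions, which are then applied to the
   held-out fold; similarity values already live in [0, 1] and are not
   rescaled. The sd is the population form; constant columns map to 0
   and are kept, so matrix shapes are stable across folds.
4. **Tuning**: every grid point is scored by 5-fold cross-validated
   accuracy inside the training fold (the outer test fold is never
   touched); ties break to the earlier grid point. The resampling
   depth is the package's choice — the original tuning tool is named
   in the sources but not its depth.
5. The model is refitted at the chosen setting and the held-out fold
   predicted; per-fold correct counts feed the permutation test.

Default grids (fixed-step, in the style of caret):
`C ∈ {0.25, 1, 4, 16, 64, 256}`; RBF width `σ ∈ {2^-6 … 2^2}` by
powers of 4; polynomial `scale ∈ {0.01, 0.1, 1}`, `degree ∈ {2, 3}`;
`k ∈ {1, 3, 5, 7, 9, 11}`; RF `mtry ∈ {⌊√M/2⌋, ⌈√M⌉, 2⌈√M⌉}` with 500
trees (`M` = number of descriptors; `√M` is the conventional default).
Multi-class SVM uses the standard one-vs-one reduction. kNN is
Euclidean on the scaled features and deliberately treats similarity
columns as plain coordinates; vote ties break to the nearest
neighbour's class and distance ties to training order, making
prediction fully deterministic. RF voting ties are broken at random
inside the forest implementation, with every stochastic step seeded.

`external_split()` implements the external-validation construction:
candidate entries are scanned in order, and any candidate repeating an
earlier candidate's first-three-level EC code is moved to the training
set, leaving a test set non-redundant at the third level. Whether
deduplication should also run against the base training set is
ambiguous in the protocol description; both modes exist
(`also_dedup_vs_training`), with within-candidate deduplication the
default, since that mode forces the worked sizes 43 test / 277
training from 260 + 60 entries with 17 third-level duplicates.
External test descriptors are built on the training feature space
(similarity columns are the training entries, so the matrix width
equals the training-set size) and scaled with the training
distributions.

## The synthetic generator

Real descriptor tables for the curated mechanism database are not
bundled; the generator emulates their statistical structure so every
pipeline stage is testable end to end, and its defaults are the study
conditions:

* **Class priors** (84, 63, 73, 49, 30, 21)/320 — the six-class
  make-up of the 320-entry benchmark; the ligase count is derived as
  the remainder, not an independently reported number.
* **Signatures**: class 1 gets C-H cleavage, O-H formation and a C-C
  order change, plus NAD(+)/NADH or NADP(+)/NADPH substrate/product
  pairs at rates 10/84 and 14/84; class 3 the amide-hydrolysis pattern
  (C-N cleavage, C-O and N-H formation) and always a water substrate;
  class 4 C-C cleavage with C-H formation; class 5 exactly one
  substrate and one isomeric product (so `Mod_Diff` is 0 and the
  overall change is a cancelling O-H shift); class 6 both formation
  and cleavage of P-O bonds with an ATP substrate and ADP or AMP
  product; class 2 draws two tokens from a mixed group-transfer pool,
  modelling its lack of a clear signature. Each signature token is
  included with probability `signature_strength` (default 0.9 — strong
  but imperfect signatures), and Poisson-distributed noise tokens
  (mean 1.5) are added from a fixed alphabet over {C,H,N,O,P,S} and
  transitions {0→1, 1→0, 1→2, 2→1}.
* **Mechanisms** are built by `expand_mechanism()`: overall tokens are
  scattered over steps and 1–3 transient formation/cleavage pairs are
  inserted (formation strictly before cleavage), so composition is
  exact by construction. With probability `1 − h` the step count and
  transient chemistry come from a class-linked template; with
  probability `h` (`mechanism_heterogeneity`, default 0.8) from a
  shared class-agnostic pool whose transient tokens deliberately
  overlap several classes' cues. `h` is the package's handle on the
  scientific question: at `h = 0` mechanism is fully class-determined,
  at `h = 1` it carries no class information beyond what leaks through
  the distributed overall tokens.

What the generator does **not** emulate: real chemistry (formulas are
random; mechanisms are token multisets, not curated catalytic steps),
class exceptions such as reverse-annotated hydrolases or
hydroxide-using entries (only reachable through the noise channel),
stereochemistry (isomerism is equal formulas, which suffices for every
implemented feature), and the long-tailed token vocabulary of real
data. Passing tests on generator output therefore demonstrate that the
pipeline recovers structure it was built to recover — protocol
correctness and sensitivity — not that real mechanism data behave this
way. One negative-control option reproduces the known isomerase edge
case of a near-isomer pair one protonation state apart, by giving the
product formula one extra hydrogen.

## What the synthetic benchmark shows

With heterogeneous mechanisms (`h = 1`), classifiers trained on
overall-transformation encodings beat their mechanistic counterparts
consistently (overall vs composite bond change, and overall vs
mechanistic similarity, each winning every seed in the packaged runs;
sign tests over 12 and 10 seeds). At `h = 0` the advantage vanishes —
indeed the composite encoding then *overtakes* the overall one,
because class-linked transient bonds are extra class signal that the
net transformation discards. This asymmetry is worth stating plainly:
"mechanism hurts prediction" is a statement about mechanism
heterogeneity, not about mechanistic encodings as such, and the
generator reproduces exactly that dependence. Isomerases illustrate
the mechanism-invisibility pattern: their one shared property (isomer
substrate/product) lives in the species, so under shared-pool
mechanisms the mechanistic sets have nothing class-specific to see.

The packaged test runs use deliberately modest problem sizes — 120
entries for the bond-change contrasts, 100 for the similarity
contrasts, Random Forests of 150 trees at a fixed `mtry` — chosen as
the smallest configurations at which the contrasts are decisive and
stable across seeds.

## Numerical and degenerate-input conventions

* Constant descriptor columns: scaled to 0, kept.
* Empty bond-change vectors: valid; Tanimoto conventions above.
* Single-class training folds: a warning is recorded and the fold is
  still predicted (possible only under extreme priors at small n).
* Tuning-accuracy ties: first grid point wins, making tuning
  deterministic given the seed.
* All stochastic steps (fold assignment, inner resampling, SVM/RF
  fitting, generation) derive from explicit seeds; reports record
  them.

## Limitations

The human-designed registry is an approximation of a list whose exact
composition is external to this package; conclusions about that set's
ceiling should be drawn on the real features (drop-in replaceable).
The alignment defaults are reasonable, verified choices rather than a
reconstruction of the original mechanism-comparison method. And the
acceptance-grade contrasts quantify behaviour on synthetic data whose
generating process is known; they bound what the pipeline can detect,
not what real enzymes do.
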