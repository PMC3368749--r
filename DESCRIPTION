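Package: ecpred
Title: Predicting Enzyme Commission Class from Overall Reactions and
    Mechanistic Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A benchmarking pipeline asking whether the top-level Enzyme
    Commission (EC) class of an enzyme-catalysed reaction is predictable
    from its stepwise chemical mechanism, or only from the overall
    chemical transformation.  Provides bond-change token descriptors
    (overall and composite over mechanism steps), a configurable set of
    human-designed reaction features, count-vector Tanimoto similarity of
    overall transformations, Needleman-Wunsch alignment similarity of
    stepwise mechanisms, a cross-validation harness with
    similarity-column deletion and per-fold scaling, multi-class
    evaluation including Gorodkin's K-category correlation coefficient,
    an exhaustive fold-wise permutation test for comparing classifiers,
    an external-validation split that is non-redundant at the third EC
    level, and a generator of synthetic MACiE-like reaction entries with
    class-dependent chemical signatures and tunable mechanism
    conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
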