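test_that("fold assignment is balanced, seeded and validated", {
  a <- make_folds(260, 10, seed = 6)
  expect_equal(unname(table(a)), rep(26L, 10), ignore_attr = TRUE)
  expect_equal(make_folds(260, 10, seed = 6), a)
  expect_false(identical(make_folds(260, 10, seed = 7), a))
  ids <- sprintf("e%02d", 1:23)
  b <- make_folds(ids, 10, seed = 1)
  expect_equal(names(b), ids)
  expect_true(all(table(b) %in% 2:3))  # sizes differ by at most 1
  expect_error(make_folds(7, 10), "cannot make")
})

test_that("grid tuning selects by inner accuracy with first-order ties", {
  sep <- separable_data(n1 = 10, n2 = 20)
  spec1 <- classifier_spec("knn", grid = list(k = 3))
  expect_equal(tune(spec1, sep$X, sep$y)$k, 3)  # single point: returned as-is
  # a perfectly separating setting wins on separable data: k = 1 vs a k
  # spanning the whole training set, which always votes the larger class
  spec2 <- classifier_spec("knn", grid = list(k = c(29, 1)))
  expect_equal(tune(spec2, sep$X, sep$y, seed = 2)$k, 1)
  expect_error(tune(spec2, sep$X, rep(1, nrow(sep$X))), "single-class")
})

test_that("cross-validation learns separable six-class synthetic data", {
  cfg <- generator_config(n_entries = 120, signature_strength = 1,
                          noise_tokens = 0, mechanism_heterogeneity = 0,
                          seed = 17)
  d <- generate_dataset(cfg)
  X <- descriptor_set_matrix(d, "overall-bond")
  y <- vapply(d, `[[`, 1L, "ec_class")
  spec <- classifier_spec("rf", grid = list(mtry = 4, n_trees = 150))
  cv <- cross_validate(X, y, spec, n_folds = 10, seed = 5)
  expect_gt(cv$accuracy, 0.9)
  expect_equal(sum(cv$fold_sizes), length(d))
  expect_equal(sum(cv$confusion), length(d))
  expect_equal(sum(cv$fold_correct) / length(d), cv$accuracy)
  # shuffled labels collapse accuracy to about the largest-class prior
  set.seed(99)
  cvnull <- cross_validate(X, sample(y), spec, n_folds = 10, seed = 5)
  prior <- max(table(y)) / length(y)
  expect_lt(cvnull$accuracy, prior + 3 * sqrt(prior * (1 - prior) / length(y)))
})

test_that("similarity cross-validation never trains on test columns", {
  d <- generate_dataset(generator_config(n_entries = 40, seed = 23))
  S <- descriptor_set_matrix(d, "overall-sim")
  y <- vapply(d, `[[`, 1L, "ec_class")
  spec <- classifier_spec("knn", grid = list(k = 3))
  cv <- cross_validate(S, y, spec, n_folds = 5, seed = 3, is_similarity = TRUE)
  ids <- rownames(S)
  for (f in seq_along(cv$train_columns)) {
    test_ids <- ids[cv$fold_assign == f]
    expect_length(intersect(cv$train_columns[[f]], test_ids), 0L)
    expect_setequal(cv$train_columns[[f]], setdiff(ids, test_ids))
  }
})

test_that("held-out entries never influence their fold's trained model", {
  # no-leak spot check: a fold's model must be a deterministic function
  # of the training folds only, so refitting it from scratch without
  # one of the fold's test entries reproduces the CV predictions for
  # the remaining test entries exactly
  d <- generate_dataset(generator_config(n_entries = 30, seed = 41))
  X <- descriptor_set_matrix(d, "overall-bond")
  y <- vapply(d, `[[`, 1L, "ec_class")
  spec <- classifier_spec("knn", grid = list(k = 1))
  cv <- cross_validate(X, y, spec, n_folds = 3, seed = 2)
  fold1 <- which(cv$fold_assign == 1L)
  rest <- fold1[-1]             # fold 1 with one test entry removed
  tr <- which(cv$fold_assign != 1L)  # unchanged by dropping a test entry
  sp <- zscale_fit(X[tr, , drop = FALSE])
  m <- ecpred:::fit_classifier(spec, data.frame(k = 1),
                               zscale_apply(X[tr, , drop = FALSE], sp),
                               y[tr], seed = 1)
  pred <- ecpred:::predict_classifier(spec, m,
                                      zscale_apply(X[rest, , drop = FALSE], sp))
  expect_equal(pred, cv$predictions[rest])
})

test_that("random forest out-of-bag accuracy is seeded and close to CV", {
  cfg <- generator_config(n_entries = 100, signature_strength = 1,
                          noise_tokens = 0.5, mechanism_heterogeneity = 0,
                          seed = 29)
  d <- generate_dataset(cfg)
  X <- descriptor_set_matrix(d, "overall-bond")
  y <- vapply(d, `[[`, 1L, "ec_class")
  oob1 <- rf_oob_accuracy(X, y, list(n_trees = 200), seed = 8)
  expect_equal(oob1, rf_oob_accuracy(X, y, list(n_trees = 200), seed = 8))
  cv <- cross_validate(X, y, classifier_spec("rf", grid = list(mtry = 6, n_trees = 200)),
                       n_folds = 5, seed = 8)
  expect_lt(abs(oob1 - cv$accuracy), 0.15)
  expect_error(rf_oob_accuracy(X, rep(1, length(y))), "two classes")
})

test_that("external split reproduces the worked 260 + 60 -> 277/43 example", {
  sc <- split_scenario_entries(n_base = 260, n_unique = 43, n_dup = 17)
  sp <- external_split(sc$base, sc$candidates)
  expect_length(sp$test, 43L)
  expect_length(sp$training, 277L)
  expect_length(sp$moved_ids, 17L)
  # non-redundancy invariant: no two test entries share a 3-level code
  codes <- ecpred:::ec_third_level(vapply(sp$test, `[[`, "", "ec"))
  expect_false(anyDuplicated(codes) > 0)
  # edge cases: no duplicates / all duplicates
  uniq <- lapply(1:5, function(i) make_entry(sprintf("U%d", i),
                                             ec = sprintf("1.%d.1.1", i)))
  expect_length(external_split(list(), uniq)$test, 5L)
  same <- lapply(1:4, function(i) make_entry(sprintf("D%d", i), ec = "2.1.1.9"))
  spd <- external_split(uniq, same)
  expect_length(spd$test, 1L)
  expect_length(spd$moved_ids, 3L)
  # deduplication against the base training set is opt-in
  clash <- list(make_entry("C1", ec = "1.1.1.99"))
  base <- list(make_entry("B1", ec = "1.1.1.1"))
  expect_length(external_split(base, clash)$test, 1L)
  expect_length(external_split(base, clash,
                               also_dedup_vs_training = TRUE)$test, 0L)
})

test_that("external validation scales with training parameters only", {
  cfg <- generator_config(n_entries = 80, signature_strength = 1,
                          noise_tokens = 0, mechanism_heterogeneity = 0,
                          seed = 37)
  d <- generate_dataset(cfg)
  split <- structure(list(training = d[1:60], test = d[61:80],
                          moved_ids = character(0)),
                     class = "external_split")
  spec <- classifier_spec("rf", grid = list(mtry = 4, n_trees = 150))
  res <- external_validate(split, "overall-bond", spec, seed = 4)
  expect_gt(res$accuracy, 0.9)  # separable synthetic split
  expect_equal(res$n_train, 60L)
  expect_equal(res$n_test, 20L)
  # similarity sets: column count equals the training-set size
  knn1 <- classifier_spec("knn", grid = list(k = 1))
  dup_split <- structure(list(training = d[1:30],
                              test = d[c(31:40, 1)],  # last test = a training entry
                              moved_ids = character(0)),
                         class = "external_split")
  # an identical twin of a training entry must be predicted correctly by 1-NN
  res2 <- external_validate(dup_split, "overall-sim", knn1, seed = 4)
  expect_equal(res2$predictions[11],
               vapply(d[1], `[[`, 1L, "ec_class"))
  expect_error(external_validate(structure(list(training = d[1:5], test = list(),
                                                moved_ids = character(0)),
                                           class = "external_split"),
                                 "overall-bond", spec),
               "empty external test")
})
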