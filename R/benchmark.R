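#' Randomly assign entries to cross-validation folds
#'
#' Plain (unstratified) uniform random partition into folds of
#' near-equal size (sizes differ by at most 1), reproducible from the
#' seed. A stratified option is available but off by default.
#'
#' @param x entry ids (character) or a single count.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @param stratify_by optional class labels; when given, the partition
#'   is drawn within each class.
#' @return integer fold assignment (named by ids when ids were given).
#' @export
make_folds <- function(x, n_folds, seed = 1L, stratify_by = NULL) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
  if (n_folds > n) stop(sprintf("cannot make %d folds from %d entries", n_folds, n))
  assign_ <- with_seed(seed, {
    if (is.null(stratify_by)) {
      rep_len(seq_len(n_folds), n)[sample.int(n)]
    } else {
      out <- integer(n)
      for (cl in unique(stratify_by)) {
        idx <- which(stratify_by == cl)
        out[idx] <- rep_len(sample.int(n_folds), length(idx))[sample.int(length(idx))]
      }
      out
    }
  })
  if (is.character(x)) names(assign_) <- x
  assign_
}

#' Cross-validate a classifier on a descriptor matrix
#'
#' The full evaluation protocol for one (descriptor set, classifier)
#' pair: entries are randomly distributed into `n_folds` folds; for each
#' fold the remaining folds form the training set. For similarity
#' descriptor sets (`is_similarity = TRUE`) the columns corresponding to
#' the fold's test entries are deleted before any training
#' ([delete_test_columns()]), so the model never sees similarities to
#' test entries. For count/feature sets, z-scaling is fitted on the
#' training fold and applied to both partitions. Hyperparameters are
#' tuned by inner cross-validation on the training fold only, the model
#' is refitted at the chosen setting, and the held-out fold predicted.
#'
#' @param X descriptor matrix with entry ids as rownames (for
#'   similarity sets, columns named by reference entry ids).
#' @param labels integer class labels (1..K) aligned with rows.
#' @param spec a [classifier_spec()].
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed; fold assignment and every stochastic fit
#'   derive from it.
#' @param is_similarity apply the column-deletion rule instead of
#'   scaling.
#' @param scale z-scale per fold (default: exactly when not a
#'   similarity set — similarity values already live in `[0, 1]`).
#' @param inner_folds inner resampling depth for [tune()].
#' @param K number of classes for the pooled confusion matrix.
#' @return object of class `cv_result`: `fold_correct`, `fold_sizes`,
#'   `fold_assign`, pooled `confusion`, `accuracy`, `rk`,
#'   `per_class_accuracy`, `chosen` (per-fold hyperparameters),
#'   `train_columns` (per-fold training column names, for protocol
#'   audits), `seed`.
#' @export
cross_validate <- function(X, labels, spec, n_folds = 10L, seed = 1L,
                           is_similarity = FALSE, scale = !is_similarity,
                           inner_folds = 5L, K = 6L) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  ids <- rownames(X)
  assign_ <- make_folds(if (is.null(ids)) nrow(X) else ids, n_folds, seed = seed)
  pred <- integer(nrow(X))
  fold_correct <- integer(n_folds)
  fold_sizes <- integer(n_folds)
  chosen <- vector("list", n_folds)
  train_columns <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- which(assign_ == f)
    tr <- which(assign_ != f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (is_similarity) {
      test_ids <- ids[te]
      Xtr <- delete_test_columns(Xtr, test_ids)
      Xte <- delete_test_columns(Xte, test_ids)
    }
    if (scale) {
      sp <- zscale_fit(Xtr)
      Xtr <- zscale_apply(Xtr, sp)
      Xte <- zscale_apply(Xte, sp)
    }
    if (length(unique(labels[tr])) < 2L)
      warning(sprintf("fold %d: training data has a single class", f))
    fseed <- seed * 1000L + f
    prm <- tune(spec, Xtr, labels[tr], inner_folds = inner_folds, seed = fseed)
    model <- fit_classifier(spec, prm, Xtr, labels[tr], seed = fseed)
    pred[te] <- predict_classifier(spec, model, Xte)
    fold_correct[f] <- sum(pred[te] == labels[te])
    fold_sizes[f] <- length(te)
    chosen[[f]] <- prm
    train_columns[[f]] <- colnames(Xtr)
  }
  cm <- confusion_matrix(labels, pred, K = K)
  structure(list(fold_correct = fold_correct, fold_sizes = fold_sizes,
                 fold_assign = assign_, predictions = pred, confusion = cm,
                 accuracy = accuracy(cm), rk = gorodkin_rk(cm),
                 per_class_accuracy = per_class_accuracy(cm),
                 chosen = chosen, train_columns = train_columns, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d): accuracy %.3f, R_K %.3f\n",
              length(x$fold_sizes), x$seed, x$accuracy, x$rk))
  invisible(x)
}

#' Random Forest out-of-bag accuracy
#'
#' Grows a forest on the full matrix and scores each entry with the
#' trees whose bootstrap sample omitted it (roughly a fraction
#' `(1 - 1/N)^N -> e^-1 ~ 0.37` of the forest). Note that for
#' similarity descriptor sets the out-of-bag estimate does not apply
#' the cross-validation column-deletion rule, so it is an internal
#' estimate only.
#'
#' @param X descriptor matrix.
#' @param labels integer class labels (>= 2 classes).
#' @param rf_params list with `mtry` (default `floor(sqrt(M))`) and
#'   `n_trees` (default 500).
#' @param seed RNG seed.
#' @return out-of-bag accuracy in `[0, 1]`.
#' @export
rf_oob_accuracy <- function(X, labels, rf_params = list(), seed = 1L) {
  if (length(unique(labels)) < 2L) stop("need at least two classes")
  mtry <- rf_params$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  ntree <- rf_params$n_trees
  if (is.null(ntree)) ntree <- 500L
  rf <- with_seed(seed, randomForest::randomForest(
    x = X, y = factor(labels, levels = sort(unique(labels))),
    mtry = mtry, ntree = ntree))
  mean(as.integer(as.character(rf$predicted)) == labels)
}

#' External-validation split, non-redundant at the third EC level
#'
#' Scans the candidate entries in input order: a candidate whose
#' first-three-level EC code has already been seen among the kept test
#' entries (and, optionally, the base training set) is moved into the
#' training set; the rest form the external test set. The resulting
#' test set contains no two entries sharing a third-level EC code.
#'
#' @param base_training list of [reaction_entry()] objects (the
#'   existing benchmark set).
#' @param new_entries candidate entries for the external test set.
#' @param also_dedup_vs_training also treat third-level codes present in
#'   the base training set as seen (default `FALSE`: deduplication
#'   within the candidates only).
#' @return object of class `external_split`: `training` (base plus
#'   moved candidates), `test`, `moved_ids`.
#' @export
external_split <- function(base_training, new_entries,
                           also_dedup_vs_training = FALSE) {
  seen <- if (also_dedup_vs_training)
    unique(ec_third_level(vapply(base_training, `[[`, "", "ec"))) else character(0)
  test <- list(); moved <- list()
  for (e in new_entries) {
    key <- ec_third_level(e$ec)
    if (key %in% seen) moved <- c(moved, list(e))
    else { test <- c(test, list(e)); seen <- c(seen, key) }
  }
  structure(list(training = c(base_training, moved), test = test,
                 moved_ids = vapply(moved, `[[`, "", "entry_id")),
            class = "external_split")
}

#' @export
print.external_split <- function(x, ...) {
  cat(sprintf("external split: %d training (%d moved duplicates), %d test\n",
              length(x$training), length(x$moved_ids), length(x$test)))
  invisible(x)
}

#' Build the descriptor matrix of a named descriptor set
#'
#' Maps the five benchmark descriptor-set names onto the builders:
#' `"human"`, `"overall-bond"` and `"composite-bond"` use
#' [build_descriptor_matrix()]; `"overall-sim"` and `"mech-sim"` use
#' [similarity_matrix()] with the given reference entries as columns.
#'
#' @param entries entries forming the rows.
#' @param set one of `"human"`, `"overall-bond"`, `"composite-bond"`,
#'   `"overall-sim"`, `"mech-sim"`.
#' @param reference_entries reference entries for the similarity sets
#'   (default: `entries` themselves).
#' @param registry feature registry for the human set.
#' @param features optional fixed feature list for the bond-change sets.
#' @param gap_penalty alignment gap penalty for `"mech-sim"`.
#' @return numeric matrix.
#' @export
descriptor_set_matrix <- function(entries, set = c("human", "overall-bond",
                                                   "composite-bond",
                                                   "overall-sim", "mech-sim"),
                                  reference_entries = entries,
                                  registry = default_feature_registry(),
                                  features = NULL, gap_penalty = 0) {
  set <- match.arg(set)
  switch(set,
    "human" = build_descriptor_matrix(entries, "human", registry = registry),
    "overall-bond" = build_descriptor_matrix(entries, "overall", features = features),
    "composite-bond" = build_descriptor_matrix(entries, "composite", features = features),
    "overall-sim" = similarity_matrix(entries, reference_entries, "overall"),
    "mech-sim" = similarity_matrix(entries, reference_entries, "mechanism",
                                   gap_penalty = gap_penalty))
}

#' Is a descriptor set a similarity set?
#'
#' @param set descriptor set name as in [descriptor_set_matrix()].
#' @return `TRUE` for `"overall-sim"` and `"mech-sim"`.
#' @export
is_similarity_set <- function(set) set %in% c("overall-sim", "mech-sim")

#' Evaluate a classifier on an external split
#'
#' Builds the chosen descriptor set on the training entries (similarity
#' columns are the training entries only, so the matrix width equals the
#' training-set size), projects the test entries onto the training
#' feature space, scales the test matrix with the training-set scaling
#' parameters for count/feature sets, tunes on the training set, and
#' predicts the external test set.
#'
#' @param split an [external_split()].
#' @param set descriptor set name (see [descriptor_set_matrix()]).
#' @param spec a [classifier_spec()].
#' @param seed RNG seed.
#' @param registry feature registry for the human set.
#' @param gap_penalty alignment gap penalty for `"mech-sim"`.
#' @param inner_folds inner resampling depth for [tune()].
#' @param K number of classes.
#' @return list with `accuracy`, `rk`, `per_class_accuracy`,
#'   `confusion`, `predictions`, `chosen`, `n_train`, `n_test`.
#' @export
external_validate <- function(split, set, spec, seed = 1L,
                              registry = default_feature_registry(),
                              gap_penalty = 0, inner_folds = 5L, K = 6L) {
  stopifnot(inherits(split, "external_split"))
  if (length(split$test) == 0L) stop("empty external test set")
  train <- split$training; test <- split$test
  y_tr <- vapply(train, `[[`, 1L, "ec_class")
  y_te <- vapply(test, `[[`, 1L, "ec_class")
  if (is_similarity_set(set)) {
    Xtr <- descriptor_set_matrix(train, set, reference_entries = train,
                                 gap_penalty = gap_penalty)
    Xte <- descriptor_set_matrix(test, set, reference_entries = train,
                                 gap_penalty = gap_penalty)
  } else {
    Xtr <- descriptor_set_matrix(train, set, registry = registry)
    Xte <- descriptor_set_matrix(test, set, registry = registry,
                                 features = colnames(Xtr))
    sp <- zscale_fit(Xtr)
    Xtr <- zscale_apply(Xtr, sp)
    Xte <- zscale_apply(Xte, sp)
  }
  prm <- tune(spec, Xtr, y_tr, inner_folds = inner_folds, seed = seed)
  model <- fit_classifier(spec, prm, Xtr, y_tr, seed = seed)
  pred <- predict_classifier(spec, model, Xte)
  cm <- confusion_matrix(y_te, pred, K = K)
  list(accuracy = accuracy(cm), rk = gorodkin_rk(cm),
       per_class_accuracy = per_class_accuracy(cm), confusion = cm,
       predictions = pred, chosen = prm,
       n_train = length(train), n_test = length(test))
}

#' Run one benchmark cell (descriptor set x classifier)
#'
#' Convenience wrapper reproducing one cell of the cross-validation
#' accuracy table: builds the descriptor set from the entries and runs
#' the full [cross_validate()] protocol.
#'
#' @param entries list of [reaction_entry()] objects.
#' @param set descriptor set name.
#' @param spec a [classifier_spec()] (or family name).
#' @param n_folds,seed,inner_folds passed to [cross_validate()].
#' @param registry,gap_penalty passed to [descriptor_set_matrix()].
#' @return a `cv_result`.
#' @export
benchmark_cell <- function(entries, set, spec, n_folds = 10L, seed = 1L,
                           inner_folds = 5L,
                           registry = default_feature_registry(),
                           gap_penalty = 0) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  X <- descriptor_set_matrix(entries, set, registry = registry,
                             gap_penalty = gap_penalty)
  labels <- vapply(entries, `[[`, 1L, "ec_class")
  cross_validate(X, labels, spec, n_folds = n_folds, seed = seed,
                 is_similarity = is_similarity_set(set),
                 inner_folds = inner_folds)
}
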