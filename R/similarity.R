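#' Count-vector Tanimoto similarity
#'
#' The min-sum (histogram-intersection) form of the Tanimoto
#' coefficient on token counts:
#' `T = sum_t min(a_t, b_t) / (sum_t a_t + sum_t b_t - sum_t min(a_t, b_t))`.
#' It reduces to the familiar binary Tanimoto on 0/1 vectors. By
#' convention two empty vectors have similarity 1; an empty and a
#' non-empty vector have similarity 0.
#'
#' @param a,b [bond_change_vector()]s (or coercibles).
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c("C.N_0.1", "C.N_0.1"), c("C.N_0.1", "H.O_0.1"))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- bond_change_vector(a); b <- bond_change_vector(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  common <- intersect(names(a), names(b))
  inter <- sum(pmin(as.integer(a[common]), as.integer(b[common])))
  inter / (sum(a) + sum(b) - inter)
}

#' Overall reaction similarity
#'
#' Tanimoto similarity of the overall bond-change vectors of two
#' entries, computed in the stored (canonical) direction only — no
#' direction search is performed for overall reactions.
#'
#' @param a,b [reaction_entry()] objects.
#' @return similarity in `[0, 1]`.
#' @export
overall_reaction_similarity <- function(a, b) {
  tanimoto(overall_bond_change_vector(a), overall_bond_change_vector(b))
}

#' Needleman-Wunsch alignment of two mechanisms
#'
#' Global alignment of two ordered step sequences, analogous to
#' biological sequence alignment: the substitution score of step i
#' against step j is their count-vector [tanimoto()] similarity, and
#' gaps incur a linear penalty (default 0, so length mismatch is
#' penalised only through the normaliser). The normalised similarity is
#' the optimal score divided by `max(n_a, n_b)`, which makes
#' self-similarity exactly 1 and keeps values in `[0, 1]` for any
#' non-negative gap penalty (negative raw scores are floored at 0).
#'
#' @param steps_a,steps_b non-empty lists of bond-change vectors.
#' @param gap_penalty linear gap penalty, >= 0.
#' @return list of class `alignment_result`: `score` (optimal raw
#'   score), `pairs` (two-column matrix of aligned step indices, NA for
#'   a gap), `normalized_similarity`.
#' @export
align_mechanisms <- function(steps_a, steps_b, gap_penalty = 0) {
  if (length(steps_a) == 0L || length(steps_b) == 0L)
    stop("cannot align an empty mechanism")
  stopifnot(gap_penalty >= 0)
  steps_a <- lapply(steps_a, bond_change_vector)
  steps_b <- lapply(steps_b, bond_change_vector)
  na <- length(steps_a); nb <- length(steps_b)
  s <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    s[i, j] <- tanimoto(steps_a[[i]], steps_b[[j]])
  M <- matrix(0, na + 1L, nb + 1L)
  M[1L, ] <- -gap_penalty * (0:nb)
  M[, 1L] <- -gap_penalty * (0:na)
  for (i in seq_len(na)) for (j in seq_len(nb))
    M[i + 1L, j + 1L] <- max(M[i, j] + s[i, j],
                             M[i, j + 1L] - gap_penalty,
                             M[i + 1L, j] - gap_penalty)
  # traceback
  pairs <- matrix(NA_integer_, 0L, 2L)
  i <- na; j <- nb
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        isTRUE(all.equal(M[i + 1L, j + 1L], M[i, j] + s[i, j]))) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               isTRUE(all.equal(M[i + 1L, j + 1L], M[i, j + 1L] - gap_penalty))) {
      pairs <- rbind(c(i, NA_integer_), pairs); i <- i - 1L
    } else {
      pairs <- rbind(c(NA_integer_, j), pairs); j <- j - 1L
    }
  }
  colnames(pairs) <- c("index_a", "index_b")
  score <- M[na + 1L, nb + 1L]
  structure(list(score = score, pairs = pairs,
                 normalized_similarity = max(score, 0) / max(na, nb)),
            class = "alignment_result")
}

#' Mechanistic similarity of two entries
#'
#' Normalised alignment similarity of the stepwise mechanisms, computed
#' in the stored direction and recomputed with one entry reversed; the
#' higher of the two is returned (a mechanism annotated in the opposite
#' direction should still match).
#'
#' @param a,b [reaction_entry()] objects.
#' @param gap_penalty passed to [align_mechanisms()].
#' @return similarity in `[0, 1]`.
#' @export
mechanism_similarity <- function(a, b, gap_penalty = 0) {
  fwd <- align_mechanisms(a$mechanism, b$mechanism, gap_penalty)
  rev_b <- rev(lapply(b$mechanism, bcv_invert))
  bwd <- align_mechanisms(a$mechanism, rev_b, gap_penalty)
  max(fwd$normalized_similarity, bwd$normalized_similarity)
}

#' Similarity matrix of entries against reference entries
#'
#' Each row is an entry, each column the similarity of that entry to one
#' reference entry; the columns are named by reference entry ids so the
#' cross-validation column-deletion rule can target them. When `entries`
#' and `reference_entries` are the same set the diagonal is 1 and the
#' symmetric half is reused rather than recomputed.
#'
#' @param entries list of [reaction_entry()] objects (rows).
#' @param reference_entries list of reference entries (columns).
#' @param mode `"overall"` (Tanimoto of overall changes) or
#'   `"mechanism"` (direction-searched alignment similarity).
#' @param gap_penalty passed to [align_mechanisms()] for mechanism mode.
#' @return numeric matrix in `[0, 1]`, rownames = entry ids, colnames =
#'   reference entry ids.
#' @export
similarity_matrix <- function(entries, reference_entries,
                              mode = c("overall", "mechanism"),
                              gap_penalty = 0) {
  mode <- match.arg(mode)
  if (length(entries) == 0L || length(reference_entries) == 0L)
    stop("need non-empty entry and reference lists")
  ids <- vapply(entries, `[[`, "", "entry_id")
  ref_ids <- vapply(reference_entries, `[[`, "", "entry_id")
  simfun <- if (mode == "overall") overall_reaction_similarity else
    function(a, b) mechanism_similarity(a, b, gap_penalty)
  mat <- matrix(NA_real_, length(entries), length(reference_entries),
                dimnames = list(ids, ref_ids))
  same <- identical(ids, ref_ids)
  if (same) {
    for (i in seq_along(entries)) {
      mat[i, i] <- 1
      for (j in seq_len(i - 1L))
        mat[i, j] <- mat[j, i] <- simfun(entries[[i]], entries[[j]])
    }
  } else {
    for (i in seq_along(entries)) for (j in seq_along(reference_entries))
      mat[i, j] <- simfun(entries[[i]], reference_entries[[j]])
  }
  mat
}

#' Delete test-entry columns from a similarity matrix
#'
#' The cross-validation leakage guard for similarity descriptor sets:
#' before training on a fold, every column corresponding to an entry in
#' that fold's test set is removed, so the model never sees similarities
#' to test entries. Rows are left untouched.
#'
#' @param mat similarity matrix with reference entry ids as colnames.
#' @param test_ids character vector of entry ids to remove.
#' @return the matrix without the named columns.
#' @export
delete_test_columns <- function(mat, test_ids) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  keep <- !(colnames(mat) %in% test_ids)
  if (!any(keep)) stop("deleting these columns would leave an empty matrix")
  mat[, keep, drop = FALSE]
}
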