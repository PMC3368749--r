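#' Overall bond-change vector of an entry
#'
#' The counts of bonds formed, cleaved or changed in order on going from
#' the starting materials to the products — the validated
#' `overall_changes` field of the entry.
#'
#' @param entry a [reaction_entry()].
#' @return a [bond_change_vector()].
#' @export
overall_bond_change_vector <- function(entry) {
  stopifnot(inherits(entry, "reaction_entry"))
  bond_change_vector(entry$overall_changes)
}

#' Composite bond-change vector of an entry
#'
#' The same token counts summed over every mechanism step instead of
#' over the net transformation. A transient bond — formed in one step
#' and broken in a later one — therefore registers twice (once as a
#' formation token and once as its cleavage inverse) even though it is
#' absent from the overall change.
#'
#' @param entry a [reaction_entry()].
#' @return a [bond_change_vector()].
#' @export
composite_bond_change_vector <- function(entry) {
  stopifnot(inherits(entry, "reaction_entry"))
  if (length(entry$mechanism) == 0L) stop("entry has an empty mechanism")
  bcv_sum(entry$mechanism)
}

# token fields of a bond-change vector as a small table
token_table <- function(v) {
  v <- bond_change_vector(v)
  if (length(v) == 0L)
    return(data.frame(el_a = character(0), el_b = character(0),
                      a = integer(0), b = integer(0), count = integer(0)))
  m <- regmatches(names(v), regexec(.TOKEN_RE, names(v)))
  data.frame(el_a = vapply(m, `[`, "", 2L), el_b = vapply(m, `[`, "", 3L),
             a = as.integer(vapply(m, `[`, "", 4L)),
             b = as.integer(vapply(m, `[`, "", 5L)),
             count = as.integer(v), stringsAsFactors = FALSE)
}

#' Evaluate the human-designed features for one entry
#'
#' @param entry a [reaction_entry()].
#' @param registry a feature registry from [default_feature_registry()]
#'   (or a compatible named list of functions of an entry).
#' @return named numeric vector, one value per registry feature.
#' @export
human_designed_vector <- function(entry, registry = default_feature_registry()) {
  stopifnot(inherits(entry, "reaction_entry"))
  vapply(registry, function(f) as.numeric(f(entry)), numeric(1))
}

#' Build a descriptor matrix
#'
#' Assembles an entries-by-features numeric matrix for one of the three
#' non-similarity descriptor sets. For the bond-change kinds the feature
#' set is the sorted union of tokens observed across the entries (or a
#' caller-supplied feature list, used to project test entries onto
#' training features); absent tokens are 0. For the human kind the
#' columns follow the registry order.
#'
#' @param entries list of [reaction_entry()] objects.
#' @param kind `"overall"`, `"composite"` or `"human"`.
#' @param registry feature registry for `kind = "human"`.
#' @param features optional character vector fixing the column set (non-
#'   human kinds); tokens outside it are dropped.
#' @return numeric matrix, rownames = entry ids, colnames = features.
#' @export
build_descriptor_matrix <- function(entries,
                                    kind = c("overall", "composite", "human"),
                                    registry = default_feature_registry(),
                                    features = NULL) {
  kind <- match.arg(kind)
  if (length(entries) == 0L) stop("need at least one entry")
  ids <- vapply(entries, `[[`, "", "entry_id")
  if (anyDuplicated(ids)) stop("duplicate entry ids")
  if (kind == "human") {
    rows <- lapply(entries, human_designed_vector, registry = registry)
    mat <- do.call(rbind, rows)
  } else {
    vecs <- lapply(entries, if (kind == "overall") overall_bond_change_vector
                   else composite_bond_change_vector)
    if (is.null(features))
      features <- sort(unique(unlist(lapply(vecs, names))))
    mat <- matrix(0, nrow = length(entries), ncol = length(features),
                  dimnames = list(NULL, features))
    for (i in seq_along(vecs)) {
      v <- vecs[[i]]
      keep <- intersect(names(v), features)
      mat[i, keep] <- as.integer(v[keep])
    }
  }
  rownames(mat) <- ids
  mat
}
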