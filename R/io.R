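#' Write reaction entries to JSON
#'
#' Serialises a list of [reaction_entry()] objects as a UTF-8 JSON array
#' of objects `{entry_id, ec, species:[{name, formula, role}],
#' overall_changes:{token:count}, mechanism:[{token:count}, ...]}`, all
#' tokens in canonical form. [read_entries()] inverts this exactly.
#'
#' @param entries list of `reaction_entry` objects.
#' @param path output file path.
#' @export
write_entries <- function(entries, path) {
  as_count_obj <- function(v) {
    if (length(v) == 0L) return(structure(list(), names = character(0)))
    as.list(setNames(as.integer(v), names(v)))
  }
  payload <- lapply(entries, function(e) {
    list(entry_id = e$entry_id, ec = e$ec,
         species = lapply(e$species, function(s)
           list(name = s$name, formula = s$formula, role = s$role)),
         overall_changes = as_count_obj(e$overall_changes),
         mechanism = lapply(e$mechanism, as_count_obj))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reaction entries from JSON
#'
#' Parses and validates the entry format written by [write_entries()].
#' Schema violations are reported naming the offending entry and field.
#'
#' @param path input file path.
#' @return list of validated `reaction_entry` objects.
#' @export
read_entries <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    id <- if (is.null(r$entry_id)) "<missing entry_id>" else r$entry_id
    for (f in c("entry_id", "ec", "species", "overall_changes", "mechanism"))
      if (is.null(r[[f]]))
        stop(sprintf("entry '%s': missing required field '%s'", id, f),
             call. = FALSE)
    sp <- lapply(r$species, function(s) {
      for (f in c("name", "formula", "role"))
        if (is.null(s[[f]]))
          stop(sprintf("entry '%s': species missing field '%s'", id, f),
               call. = FALSE)
      species(s$name, s$formula, s$role)
    })
    reaction_entry(r$entry_id, r$ec, sp,
                   bond_change_vector(r$overall_changes),
                   lapply(r$mechanism, bond_change_vector))
  })
}

#' Write a descriptor or similarity matrix as CSV
#'
#' First column `entry_id`, remaining columns named by features (or by
#' reference entry ids for similarity matrices).
#'
#' @param mat numeric matrix with entry ids as rownames and feature
#'   names as colnames.
#' @param path output file path.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(entry_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor or similarity matrix from CSV
#'
#' @param path input file path (format of [write_matrix_csv()]).
#' @return numeric matrix with entry ids as rownames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "entry_id") stop("first CSV column must be 'entry_id'")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$entry_id
  storage.mode(mat) <- "double"
  mat
}
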