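#' Construct and validate a reaction entry
#'
#' One MACiE-like record: an EC-labelled enzyme reaction with its
#' species, the overall bond changes from substrates to products, and an
#' ordered stepwise mechanism (one bond-change vector per step).
#' Validation enforces the invariants: the top-level class (first EC
#' field) lies in 1..6, the mechanism is non-empty, and the signed
#' composition of the mechanism steps equals the overall change (a bond
#' formed in one step and broken in a later one — a transient bond —
#' cancels out).
#'
#' @param entry_id entry identifier text.
#' @param ec four-level EC code text; partial codes such as `"1.1.1.-"`
#'   are allowed. The stored direction is taken as the canonical
#'   direction; no direction inference is performed.
#' @param species list of [species()] objects.
#' @param overall_changes a [bond_change_vector()] (or coercible).
#' @param mechanism list of bond-change vectors, one per step, in order.
#' @return an object of class `reaction_entry` with fields `entry_id`,
#'   `ec`, `ec_class`, `species`, `overall_changes`, `mechanism`.
#' @export
reaction_entry <- function(entry_id, ec, species, overall_changes, mechanism) {
  if (!is.character(entry_id) || length(entry_id) != 1L || !nzchar(entry_id))
    stop("entry_id must be a non-empty string")
  ctx <- function(msg) stop(sprintf("entry '%s': %s", entry_id, msg), call. = FALSE)
  if (!is.character(ec) || length(ec) != 1L || !grepl("^[0-9]+\\.", ec))
    ctx(sprintf("invalid EC code '%s'", ec))
  ec_class <- as.integer(sub("\\..*$", "", ec))
  if (is.na(ec_class) || ec_class < 1L || ec_class > 6L)
    ctx(sprintf("EC class %s outside 1-6 in '%s'", ec_class, ec))
  if (!is.list(species) || !all(vapply(species, inherits, logical(1), "species")))
    ctx("species must be a list of species objects")
  overall_changes <- tryCatch(bond_change_vector(overall_changes),
                              error = function(e) ctx(conditionMessage(e)))
  if (!is.list(mechanism) || length(mechanism) == 0L)
    ctx("mechanism must be a non-empty list of steps")
  mechanism <- tryCatch(lapply(mechanism, bond_change_vector),
                        error = function(e) ctx(conditionMessage(e)))
  comp <- bcv_net(bcv_sum(mechanism))
  net <- bcv_net(overall_changes)
  if (!isTRUE(all.equal(comp, net)))
    ctx("signed composition of mechanism steps does not equal the overall change")
  structure(list(entry_id = entry_id, ec = ec, ec_class = ec_class,
                 species = species, overall_changes = overall_changes,
                 mechanism = mechanism),
            class = "reaction_entry")
}

#' @export
print.reaction_entry <- function(x, ...) {
  cat(sprintf("reaction entry %s  EC %s (class %d)\n", x$entry_id, x$ec, x$ec_class))
  cat(sprintf("  %d species, %d overall bond changes, %d mechanism steps\n",
              length(x$species), sum(x$overall_changes), length(x$mechanism)))
  invisible(x)
}

#' Reverse a reaction entry
#'
#' Produces the same chemistry read in the opposite direction:
#' substrate and product roles are swapped, every overall token
#' `X.Y_a.b` becomes `X.Y_b.a`, and the mechanism's step order is
#' reversed with each step's tokens inverted. Reversal is an
#' involution: `reverse_entry(reverse_entry(e))` equals `e`.
#'
#' @param entry a [reaction_entry()].
#' @return the reversed `reaction_entry`.
#' @export
reverse_entry <- function(entry) {
  stopifnot(inherits(entry, "reaction_entry"))
  sp <- lapply(entry$species, function(s) {
    s$role <- if (s$role == "substrate") "product" else "substrate"
    s
  })
  reaction_entry(entry$entry_id, entry$ec, sp,
                 bcv_invert(entry$overall_changes),
                 rev(lapply(entry$mechanism, bcv_invert)))
}

# Convenience accessors used across modules.
substrates_of <- function(entry)
  Filter(function(s) s$role == "substrate", entry$species)
products_of <- function(entry)
  Filter(function(s) s$role == "product", entry$species)

# First three levels of an EC code ("1.2.3.4" -> "1.2.3").
ec_third_level <- function(ec)
  vapply(strsplit(ec, ".", fixed = TRUE),
         function(p) paste(p[seq_len(min(3L, length(p)))], collapse = "."),
         character(1))
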