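#' @keywords internal
.TOKEN_RE <- "^([A-Z][a-z]?)\\.([A-Z][a-z]?)_([0-3])\\.([0-3])$"

#' Parse a bond-change token
#'
#' A bond-change token `X.Y_a.b` records a covalent bond between elements
#' `X` and `Y` whose order changes from `a` to `b` over a reaction or a
#' mechanism step; order 0 means the bond is absent, so `C.N_0.1` is the
#' formation of a carbon-nitrogen single bond and `C.O_1.0` the cleavage
#' of a carbon-oxygen single bond. Tokens are canonicalised so that the
#' two element symbols appear in alphabetical order.
#'
#' @param token a single token string, e.g. `"C.N_0.1"`.
#' @return an object of class `bond_change_token`: a list with fields
#'   `element_a`, `element_b` (alphabetical), `order_before`,
#'   `order_after`.
#' @examples
#' parse_bond_change_token("N.C_0.1")  # canonicalises to C.N_0.1
#' @export
parse_bond_change_token <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token))
    stop("token must be a single character string")
  m <- regmatches(token, regexec(.TOKEN_RE, token))[[1]]
  if (length(m) == 0L)
    stop(sprintf("malformed bond-change token '%s' (expected <El>.<El>_<order>.<order>)",
                 token))
  el <- m[2:3]
  known <- names(atomic_masses())
  bad <- setdiff(el, known)
  if (length(bad))
    stop(sprintf("unknown element symbol '%s' in token '%s'", bad[1L], token))
  a <- as.integer(m[4]); b <- as.integer(m[5])
  if (a == b)
    stop(sprintf("token '%s' has no change in bond order (%d.%d)", token, a, b))
  if (el[1] > el[2]) el <- rev(el)  # bond order is symmetric in the pair
  structure(list(element_a = el[1], element_b = el[2],
                 order_before = a, order_after = b),
            class = "bond_change_token")
}

#' @export
format.bond_change_token <- function(x, ...) {
  sprintf("%s.%s_%d.%d", x$element_a, x$element_b, x$order_before, x$order_after)
}

#' @export
print.bond_change_token <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Canonicalise bond-change token strings
#'
#' Vectorised: alphabetises the element pair of each token and validates
#' the grammar. Idempotent.
#'
#' @param tokens character vector of token strings.
#' @return character vector of canonical tokens.
#' @export
canonical_tokens <- function(tokens) {
  vapply(tokens, function(t) format(parse_bond_change_token(t)), character(1),
         USE.NAMES = FALSE)
}

#' Invert bond-change tokens
#'
#' Maps each token `X.Y_a.b` to `X.Y_b.a`: formations become cleavages
#' and vice versa. Used when a reaction is considered in the reverse
#' direction.
#'
#' @param tokens character vector of canonical token strings.
#' @return character vector of inverted canonical tokens.
#' @export
invert_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  sub("^([A-Z][a-z]?\\.[A-Z][a-z]?)_([0-3])\\.([0-3])$", "\\1_\\3.\\2", tokens)
}

#' Construct a bond-change vector
#'
#' A bond-change vector is the multiset of bond-change tokens describing
#' a transformation (overall reaction or one mechanism step). It is
#' stored as a named integer vector of counts over canonical tokens,
#' with zero counts dropped and names sorted.
#'
#' @param x either a character vector of tokens (a multiset: repeats
#'   count), or a named numeric vector / named list of token counts.
#' @return an object of class `bond_change_vector`.
#' @examples
#' bond_change_vector(c("C.N_0.1", "C.N_0.1", "H.O_0.1"))
#' bond_change_vector(c("N.C_0.1" = 2))
#' @export
bond_change_vector <- function(x = character(0)) {
  if (inherits(x, "bond_change_vector")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(x) || length(x) == 0L) {
    out <- integer(0); names(out) <- character(0)
    class(out) <- "bond_change_vector"
    return(out)
  }
  if (is.character(x) && is.null(names(x))) {
    toks <- canonical_tokens(x)
    tab <- table(toks)
    counts <- as.integer(tab); names(counts) <- names(tab)
  } else {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("counts must be named by bond-change tokens")
    counts <- as.numeric(x)
    if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
      stop("token counts must be non-negative integers")
    nm <- canonical_tokens(names(x))
    counts <- as.integer(tapply(counts, nm, sum))
    names(counts) <- sort(unique(nm))
  }
  counts <- counts[counts > 0L]
  counts <- counts[order(names(counts))]
  class(counts) <- "bond_change_vector"
  counts
}

#' @export
print.bond_change_vector <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<empty bond-change vector>\n")
  } else {
    cat("bond-change vector:\n")
    print(setNames(as.integer(x), names(x)))
  }
  invisible(x)
}

#' Sum bond-change vectors token-wise
#'
#' @param steps a list of `bond_change_vector`s (or things coercible).
#' @return a `bond_change_vector` with token-wise summed counts.
#' @export
bcv_sum <- function(steps) {
  steps <- lapply(steps, bond_change_vector)
  all <- unlist(lapply(steps, function(s) setNames(as.integer(s), names(s))))
  if (is.null(all) || length(all) == 0L) return(bond_change_vector())
  bond_change_vector(tapply(all, names(all), sum))
}

#' Invert a bond-change vector
#'
#' @param x a `bond_change_vector`.
#' @return the vector with every token inverted (X.Y_a.b -> X.Y_b.a).
#' @export
bcv_invert <- function(x) {
  x <- bond_change_vector(x)
  if (length(x) == 0L) return(x)
  bond_change_vector(setNames(as.integer(x), invert_tokens(names(x))))
}

#' Signed net of a bond-change vector
#'
#' Cancels inverse token pairs: for each token direction pair
#' `X.Y_a.b` / `X.Y_b.a` only the net excess is kept, on whichever side
#' is positive. Two transformations have the same net effect iff their
#' nets are identical; a mechanism's steps compose to the overall change
#' iff `bcv_net(bcv_sum(steps)) == bcv_net(overall)`.
#'
#' @param x a `bond_change_vector`.
#' @return a `bond_change_vector` with no inverse pairs.
#' @export
bcv_net <- function(x) {
  x <- bond_change_vector(x)
  if (length(x) == 0L) return(x)
  counts <- setNames(as.integer(x), names(x))
  inv <- invert_tokens(names(counts))
  net <- counts - ifelse(inv %in% names(counts), counts[inv], 0L)
  bond_change_vector(net[net > 0L])
}

#' @method all.equal bond_change_vector
#' @export
all.equal.bond_change_vector <- function(target, current, ...) {
  t <- setNames(as.integer(target), names(target))
  c_ <- setNames(as.integer(current), names(current))
  if (identical(t, c_)) TRUE else
    paste("bond-change vectors differ:", paste(names(t), collapse = ","),
          "vs", paste(names(c_), collapse = ","))
}
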