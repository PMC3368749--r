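# Standard atomic masses (IUPAC 2021 conventional values, Da) for the
# elements that occur in enzyme reaction records. Extend here if a
# formula uses something rarer.
.ATOMIC_MASSES <- c(
  H = 1.008,  B = 10.81,  C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, V = 50.942, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, Mo = 95.95, I = 126.904,
  W = 183.84
)

#' Standard atomic masses
#'
#' @return named numeric vector of standard atomic masses in Daltons.
#' @export
atomic_masses <- function() .ATOMIC_MASSES

#' Molecular weight from a Hill-style formula
#'
#' @param formula element-count string such as `"C6H12O6"` or `"H2O"`.
#'   A count of 1 may be omitted.
#' @return molecular weight in Daltons.
#' @examples
#' molecular_weight("H2O")
#' @export
molecular_weight <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula))
    stop("formula must be a non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop(sprintf("cannot parse formula '%s'", formula))
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(sub("^[A-Z][a-z]?", "", paste0(parts, "")))
  cnt[is.na(cnt)] <- 1L
  bad <- setdiff(els, names(.ATOMIC_MASSES))
  if (length(bad))
    stop(sprintf("unknown element '%s' in formula '%s'", bad[1L], formula))
  sum(.ATOMIC_MASSES[els] * cnt)
}

# Element-count map of a formula, for isomer comparison.
formula_counts <- function(formula) {
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(sub("^[A-Z][a-z]?", "", parts))
  cnt[is.na(cnt)] <- 1L
  out <- tapply(cnt, els, sum)
  out[order(names(out))]
}

# Fixed name registry: species the feature set recognises by identity.
# Names are matched case-insensitively after trimming.
.SPECIES_REGISTRY <- list(
  water_or_hydroxide = c("water", "h2o", "oh-", "hydroxide", "hydroxide ion"),
  redox_cofactor = c("nad+", "nadh", "nadp+", "nadph", "fad", "fadh2"),
  dioxygen = c("o2", "dioxygen", "oxygen"),
  atp = c("atp"),
  adp_or_amp = c("adp", "amp")
)

#' Construct a reaction species
#'
#' A species is a name + molecular-formula record with a role in the
#' reaction. Identity flags (water/hydroxide, redox cofactor, ATP,
#' ADP/AMP, O2) are derived from a fixed name registry, because the
#' feature set references these species by identity rather than by
#' structure.
#'
#' @param name species name (free text; registry names are recognised).
#' @param formula Hill-style molecular formula.
#' @param role `"substrate"` or `"product"`.
#' @param weight molecular weight in Daltons; computed from `formula`
#'   when omitted.
#' @return an object of class `species`.
#' @export
species <- function(name, formula, role = c("substrate", "product"),
                    weight = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || !nzchar(name)) stop("species needs a name")
  if (is.null(weight)) weight <- molecular_weight(formula)
  if (!is.numeric(weight) || weight <= 0) stop("species weight must be > 0")
  key <- tolower(trimws(name))
  in_reg <- function(group) key %in% .SPECIES_REGISTRY[[group]]
  structure(list(
    name = name, formula = formula, role = role, weight = weight,
    flags = list(
      is_water_or_hydroxide = in_reg("water_or_hydroxide"),
      is_redox_cofactor = in_reg("redox_cofactor"),
      is_dioxygen = in_reg("dioxygen") || identical(formula, "O2"),
      is_atp = in_reg("atp"),
      is_adp_or_amp = in_reg("adp_or_amp")
    )), class = "species")
}
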