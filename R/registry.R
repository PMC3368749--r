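# Helpers shared by the feature definitions -------------------------------

# total count of tokens involving the given unordered element pair,
# restricted to formations (order increases) or cleavages (decreases)
pair_total <- function(entry, e1, e2, direction = c("formed", "cleaved")) {
  direction <- match.arg(direction)
  tt <- token_table(entry$overall_changes)
  pair <- sort(c(e1, e2))
  sel <- tt$el_a == pair[1] & tt$el_b == pair[2] &
    (if (direction == "formed") tt$b > tt$a else tt$b < tt$a)
  sum(tt$count[sel])
}

# total change in the sum of bond orders to the given element; a token
# is counted once per atom of that element in the pair, so C.C tokens
# contribute twice to dv:C
dv_element <- function(entry, el) {
  tt <- token_table(entry$overall_changes)
  mult <- (tt$el_a == el) + (tt$el_b == el)
  sum(tt$count * (tt$b - tt$a) * mult)
}

any_substrate_flag <- function(entry, flag) {
  any(vapply(substrates_of(entry), function(s) isTRUE(s$flags[[flag]]),
             logical(1)))
}

#' The default human-designed feature registry
#'
#' Named, ordered list of 28 feature definitions, each a function of a
#' [reaction_entry()] returning one number. The set is built around four
#' anchor features — `f:X-H` (total bonds to hydrogen formed), `dv:C`
#' (total change in the sum of bond orders to carbon, counted per carbon
#' atom), `water.OH-.su` (1 iff water or hydroxide is a substrate, a cue
#' for hydrolases) and `Mod_Diff` (absolute difference in molecular
#' weight between the largest substrate and largest product, designed to
#' be 0.000 for isomerases) — plus analogues deliberately engineered to
#' correlate with EC classes: redox-species involvement (class 1),
#' isomer substrate/product pairs (class 5), and ATP hydrolysis
#' (class 6). The registry is replaceable: pass any compatible named
#' list to the descriptor builders to swap in a different feature set.
#'
#' @return named list of feature functions, class `feature_registry`.
#' @export
default_feature_registry <- function() {
  tt_of <- token_table
  reg <- list(
    # formed / cleaved bonds to hydrogen, any partner element
    `f:X-H` = function(e) {
      tt <- tt_of(e$overall_changes)
      sum(tt$count[(tt$el_a == "H" | tt$el_b == "H") & tt$b > tt$a])
    },
    `c:X-H` = function(e) {
      tt <- tt_of(e$overall_changes)
      sum(tt$count[(tt$el_a == "H" | tt$el_b == "H") & tt$b < tt$a])
    },
    `dv:C` = function(e) dv_element(e, "C"),
    `dv:N` = function(e) dv_element(e, "N"),
    `dv:O` = function(e) dv_element(e, "O"),
    `dv:P` = function(e) dv_element(e, "P"),
    `dv:S` = function(e) dv_element(e, "S"),
    `f:C-C` = function(e) pair_total(e, "C", "C", "formed"),
    `c:C-C` = function(e) pair_total(e, "C", "C", "cleaved"),
    `f:C-N` = function(e) pair_total(e, "C", "N", "formed"),
    `c:C-N` = function(e) pair_total(e, "C", "N", "cleaved"),
    `f:C-O` = function(e) pair_total(e, "C", "O", "formed"),
    `c:C-O` = function(e) pair_total(e, "C", "O", "cleaved"),
    `f:C-S` = function(e) pair_total(e, "C", "S", "formed"),
    `c:C-S` = function(e) pair_total(e, "C", "S", "cleaved"),
    `f:P-O` = function(e) pair_total(e, "P", "O", "formed"),
    `c:P-O` = function(e) pair_total(e, "P", "O", "cleaved"),
    `f:O-H` = function(e) pair_total(e, "O", "H", "formed"),
    `c:O-H` = function(e) pair_total(e, "O", "H", "cleaved"),
    `water.OH-.su` = function(e)
      as.numeric(any_substrate_flag(e, "is_water_or_hydroxide")),
    `redox.su` = function(e)
      as.numeric(any_substrate_flag(e, "is_redox_cofactor")),
    `O2.su` = function(e) as.numeric(any_substrate_flag(e, "is_dioxygen")),
    `ATP.su.ADP.AMP.pr` = function(e) {
      atp <- any_substrate_flag(e, "is_atp")
      out <- any(vapply(products_of(e),
                        function(s) isTRUE(s$flags$is_adp_or_amp), logical(1)))
      as.numeric(atp && out)
    },
    `isomer` = function(e) {
      su <- substrates_of(e); pr <- products_of(e)
      if (length(su) != 1L || length(pr) != 1L) return(0)
      as.numeric(identical(formula_counts(su[[1]]$formula),
                           formula_counts(pr[[1]]$formula)))
    },
    `Mod_Diff` = function(e) {
      su <- substrates_of(e); pr <- products_of(e)
      if (length(su) == 0L || length(pr) == 0L)
        stop(sprintf("entry '%s': Mod_Diff needs at least one substrate and one product",
                     e$entry_id))
      abs(max(vapply(su, `[[`, 0, "weight")) -
            max(vapply(pr, `[[`, 0, "weight")))
    },
    `n.substrates` = function(e) length(substrates_of(e)),
    `n.products` = function(e) length(products_of(e)),
    `net.dv` = function(e) {
      tt <- tt_of(e$overall_changes)
      sum(tt$count * (tt$b - tt$a))
    }
  )
  stopifnot(!anyDuplicated(names(reg)))
  structure(reg, class = c("feature_registry", "list"))
}
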