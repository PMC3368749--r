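# Class-dependent overall-change signatures (canonical tokens). These
# encode the chemical cues characteristic of each EC class: class 1
# (oxidoreductases) C-H cleavage, O-H formation and C-C bond-order
# change; class 3 (hydrolases) the amide-hydrolysis pattern of C-N
# cleavage with C-O and N-H formation; class 4 (lyases) C-C cleavage
# with C-H formation; class 5 (isomerases) an intramolecular O-H
# shift, so formation and cleavage cancel and substrate and product
# are isomers; class 6 (ligases) both formation and cleavage of P-O
# single bonds from ATP turnover. Class 2 (transferases) has no clear
# signature and draws from a mixed group-transfer pool instead.
.CLASS_SIGNATURES <- list(
  `1` = c("C.H_1.0", "H.O_0.1", "C.C_2.1"),
  `2` = character(0),
  `3` = c("C.N_1.0", "C.O_0.1", "H.N_0.1"),
  `4` = c("C.C_1.0", "C.H_0.1"),
  `5` = c("H.O_1.0", "H.O_0.1"),
  `6` = c("O.P_0.1", "O.P_1.0")
)

.TRANSFER_POOL <- c("C.O_0.1", "C.O_1.0", "C.N_0.1", "C.N_1.0",
                    "C.S_0.1", "C.S_1.0", "O.P_0.1", "O.P_1.0",
                    "C.C_0.1", "C.C_1.0")

# Noise-token alphabet: all element pairs over {C,H,N,O,P,S} combined
# with the order transitions 0->1, 1->0, 1->2, 2->1.
.NOISE_ALPHABET <- local({
  els <- c("C", "H", "N", "O", "P", "S")
  pairs <- t(combn(els, 2))
  pairs <- rbind(pairs, cbind(els, els))
  trans <- c("0.1", "1.0", "1.2", "2.1")
  sort(as.vector(outer(paste0(pairs[, 1], ".", pairs[, 2]),
                       paste0("_", trans), paste0)))
})

# Class-linked mechanism templates: fixed step counts and transient
# formation tokens, distinct per class so that conserved mechanisms
# carry a class signal.
.CLASS_MECH_TEMPLATES <- list(
  `1` = list(n_steps = 3L, transient = c("C.O_0.1")),
  `2` = list(n_steps = 2L, transient = c("C.S_0.1")),
  `3` = list(n_steps = 4L, transient = c("C.O_0.1", "H.O_0.1")),
  `4` = list(n_steps = 2L, transient = c("C.N_0.1")),
  `5` = list(n_steps = 3L, transient = c("H.N_0.1")),
  `6` = list(n_steps = 4L, transient = c("O.P_0.1"))
)

# Shared (class-agnostic) mechanism template pool: transient tokens
# deliberately overlap several classes' cues, so mechanisms drawn from
# here carry no class information.
.SHARED_MECH_TEMPLATES <- list(
  list(n_steps = 2L, transient = c("C.O_0.1")),
  list(n_steps = 3L, transient = c("H.O_0.1")),
  list(n_steps = 3L, transient = c("C.N_0.1")),
  list(n_steps = 4L, transient = c("C.S_0.1", "H.N_0.1")),
  list(n_steps = 2L, transient = c("O.P_0.1")),
  list(n_steps = 4L, transient = c("C.C_0.1")),
  list(n_steps = 3L, transient = c("C.O_0.1", "H.O_0.1")),
  list(n_steps = 5L, transient = c("H.S_0.1"))
)

#' Default EC class priors
#'
#' Class proportions of the 320-entry MACiE 3.0 benchmark: 84
#' oxidoreductases, 63 transferases, 73 hydrolases, 49 lyases, 30
#' isomerases, and — derived as the remainder of the 320, not an
#' independently reported count — 21 ligases.
#'
#' @return named vector of 6 proportions summing to 1.
#' @export
default_class_priors <- function() {
  counts <- c(`1` = 84, `2` = 63, `3` = 73, `4` = 49, `5` = 30, `6` = 21)
  counts / sum(counts)
}

#' Configuration for the synthetic MACiE-like generator
#'
#' @param n_entries number of entries to generate.
#' @param class_priors 6 class proportions (default
#'   [default_class_priors()]).
#' @param signature_strength probability in `[0, 1]` that each
#'   class-signature token is included in an entry's overall change.
#' @param noise_tokens Poisson mean count of random extra bond-change
#'   tokens per entry.
#' @param mechanism_heterogeneity `h` in `[0, 1]`: probability that an
#'   entry's mechanism template is drawn from the shared pool instead
#'   of its class-linked template. At `h = 0` mechanism is fully
#'   class-determined; at `h = 1` mechanisms carry no class signal —
#'   modelling the finding that similar reactions can proceed by
#'   dissimilar mechanisms.
#' @param steps_range `(min, max)` mechanism step count for shared-pool
#'   templates drawn outside the fixed template list.
#' @param transient_pairs_range `(min, max)` number of transient
#'   formation/cleavage token pairs inserted per mechanism.
#' @param seed RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_entries = 320L,
                             class_priors = default_class_priors(),
                             signature_strength = 0.9,
                             noise_tokens = 1.5,
                             mechanism_heterogeneity = 0.8,
                             steps_range = c(2L, 5L),
                             transient_pairs_range = c(1L, 3L),
                             seed = 1L) {
  stopifnot(n_entries >= 0, length(class_priors) == 6L,
            abs(sum(class_priors) - 1) < 1e-8, all(class_priors >= 0),
            signature_strength >= 0, signature_strength <= 1,
            noise_tokens >= 0,
            mechanism_heterogeneity >= 0, mechanism_heterogeneity <= 1,
            length(steps_range) == 2L, steps_range[1] >= 1L,
            steps_range[1] <= steps_range[2],
            length(transient_pairs_range) == 2L,
            transient_pairs_range[1] >= 0L,
            transient_pairs_range[1] <= transient_pairs_range[2])
  structure(list(n_entries = as.integer(n_entries), class_priors = class_priors,
                 signature_strength = signature_strength,
                 noise_tokens = noise_tokens,
                 mechanism_heterogeneity = mechanism_heterogeneity,
                 steps_range = as.integer(steps_range),
                 transient_pairs_range = as.integer(transient_pairs_range),
                 seed = as.integer(seed)),
            class = "generator_config")
}

random_formula <- function() {
  sprintf("C%dH%dN%dO%d", sample(2:12, 1L), sample(4:20, 1L),
          sample(0:3, 1L) + 1L, sample(1:6, 1L))
}

#' Distribute an overall change over mechanism steps
#'
#' Spreads each overall token occurrence onto a random step, then
#' inserts `n_transient` transient bonds: for each, a formation token is
#' added to an earlier step and its cleavage inverse to a later step, so
#' the pair cancels from the net transformation but registers twice in
#' the composite (per-step summed) description. The signed composition
#' of the returned steps always equals the overall change.
#'
#' @param overall a [bond_change_vector()].
#' @param n_steps number of steps (>= 1; >= 2 if `n_transient` > 0).
#' @param n_transient number of transient token pairs to insert.
#' @param transient_tokens optional formation tokens (order increases)
#'   to use for the transients, recycled as needed; random formation
#'   tokens from the noise alphabet otherwise.
#' @return list of `n_steps` bond-change vectors.
#' @export
expand_mechanism <- function(overall, n_steps, n_transient = 0L,
                             transient_tokens = NULL) {
  overall <- bond_change_vector(overall)
  if (n_steps < 1L) stop("need at least one step")
  if (n_transient > 0L && n_steps < 2L)
    stop("transient bonds need at least two steps")
  step_tokens <- vector("list", n_steps)
  occ <- rep(names(overall), as.integer(overall))
  if (length(occ)) {
    where <- sample.int(n_steps, length(occ), replace = TRUE)
    for (s in unique(where))
      step_tokens[[s]] <- c(step_tokens[[s]], occ[where == s])
  }
  if (n_transient > 0L) {
    if (is.null(transient_tokens)) {
      formations <- grep("_0\\.1$|_1\\.2$", .NOISE_ALPHABET, value = TRUE)
      transient_tokens <- sample(formations, n_transient, replace = TRUE)
    } else {
      transient_tokens <- rep_len(transient_tokens, n_transient)
    }
    for (t in transient_tokens) {
      ij <- sort(sample.int(n_steps, 2L))
      step_tokens[[ij[1]]] <- c(step_tokens[[ij[1]]], t)
      step_tokens[[ij[2]]] <- c(step_tokens[[ij[2]]], invert_tokens(t))
    }
  }
  lapply(step_tokens, function(tk)
    bond_change_vector(if (is.null(tk)) character(0) else tk))
}

#' Generate one synthetic reaction entry
#'
#' Draws the overall change from the class signature (each signature
#' token kept with probability `signature_strength`; class 2 samples a
#' mixed group-transfer pool) plus Poisson noise tokens, attaches
#' class-consistent species — class 3 always has a water substrate,
#' class 1 carries NAD(+)/NADH or NADP(+)/NADPH pairs at the benchmark
#' rates 10/84 and 14/84, class 5 has exactly one substrate and one
#' isomeric product (so Mod_Diff is 0), class 6 has an ATP substrate
#' with an ADP or AMP product — and expands a mechanism whose steps
#' compose to the overall change, using the class-linked mechanism
#' template with probability `1 - h` and a shared-pool template
#' otherwise.
#'
#' @param class_id EC class 1..6.
#' @param config a [generator_config()]. The caller controls the RNG
#'   (see [generate_dataset()] for seeded generation).
#' @param entry_id id for the new entry.
#' @return a validated [reaction_entry()].
#' @export
generate_entry <- function(class_id, config = generator_config(),
                           entry_id = "S0001") {
  if (!class_id %in% 1:6) stop("class_id must be in 1..6")
  p <- config$signature_strength
  sig <- .CLASS_SIGNATURES[[as.character(class_id)]]
  if (class_id == 2L)
    sig <- sample(.TRANSFER_POOL, 2L)
  keep <- sig[stats::runif(length(sig)) < p]
  n_noise <- stats::rpois(1L, config$noise_tokens)
  noise <- if (n_noise > 0L) sample(.NOISE_ALPHABET, n_noise, replace = TRUE)
           else character(0)
  overall <- bond_change_vector(c(keep, noise))

  sp <- list()
  if (class_id == 5L) {
    f <- random_formula()
    sp <- list(species("substrate A", f, "substrate"),
               species("isomer of A", f, "product"))
  } else {
    for (i in seq_len(sample(1:2, 1L)))
      sp <- c(sp, list(species(sprintf("substrate %d", i), random_formula(),
                               "substrate")))
    for (i in seq_len(sample(1:2, 1L)))
      sp <- c(sp, list(species(sprintf("product %d", i), random_formula(),
                               "product")))
  }
  if (class_id == 3L)
    sp <- c(sp, list(species("water", "H2O", "substrate")))
  if (class_id == 6L)
    sp <- c(sp, list(species("ATP", "C10H16N5O13P3", "substrate"),
                     if (stats::runif(1) < 0.5)
                       species("ADP", "C10H15N5O10P2", "product")
                     else species("AMP", "C10H14N5O7P", "product")))
  if (class_id == 1L) {
    u <- stats::runif(1)
    if (u < 10 / 84)
      sp <- c(sp, list(species("NAD+", "C21H27N7O14P2", "substrate"),
                       species("NADH", "C21H28N7O14P2", "product")))
    else if (u < 24 / 84)
      sp <- c(sp, list(species("NADP+", "C21H28N7O17P3", "substrate"),
                       species("NADPH", "C21H29N7O17P3", "product")))
  }

  shared <- stats::runif(1) < config$mechanism_heterogeneity
  tmpl <- if (shared)
    .SHARED_MECH_TEMPLATES[[sample.int(length(.SHARED_MECH_TEMPLATES), 1L)]]
  else .CLASS_MECH_TEMPLATES[[as.character(class_id)]]
  tp <- config$transient_pairs_range
  n_transient <- if (tp[1] == tp[2]) tp[1] else
    sample(seq.int(tp[1], tp[2]), 1L)
  sr <- config$steps_range
  n_steps <- min(max(tmpl$n_steps, sr[1]), sr[2])
  n_steps <- max(n_steps, if (n_transient > 0L) 2L else 1L)
  mech <- expand_mechanism(overall, n_steps, n_transient,
                           transient_tokens = tmpl$transient)
  reaction_entry(entry_id, sprintf("%d.%d.%d.%d", class_id,
                                   sample(1:9, 1L), sample(1:9, 1L),
                                   sample(1:99, 1L)),
                 sp, overall, mech)
}

#' Generate a synthetic MACiE-like dataset
#'
#' Samples class labels from the configured priors and generates one
#' entry per label, reproducibly from the configuration seed. Every
#' entry passes full [reaction_entry()] validation, including the
#' step-composition invariant.
#'
#' @param config a [generator_config()].
#' @return list of `n_entries` [reaction_entry()] objects.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_entries == 0L) return(list())
  with_seed(config$seed, {
    classes <- sample.int(6L, config$n_entries, replace = TRUE,
                          prob = config$class_priors)
    lapply(seq_len(config$n_entries), function(i)
      generate_entry(classes[i], config, entry_id = sprintf("S%04d", i)))
  })
}

#' Generate a near-isomer isomerase edge case
#'
#' Negative-control variant of a class-5 entry: the product is one
#' protonation state away from being an isomer of the substrate (one
#' extra hydrogen), so the isomer flag is 0 and Mod_Diff is the mass of
#' a hydrogen rather than 0. Mirrors the known failure mode of
#' weight-difference features on real isomerase data, where a single
#' entry breaks the "isomerases have Mod_Diff exactly 0" rule.
#'
#' @param entry_id id for the new entry.
#' @param config a [generator_config()]; the caller controls the RNG.
#' @return a validated class-5 [reaction_entry()].
#' @export
near_isomer_entry <- function(entry_id = "X0001",
                              config = generator_config()) {
  e <- generate_entry(5L, config, entry_id = entry_id)
  f <- e$species[[1]]$formula
  h <- as.integer(sub(".*H([0-9]+).*", "\\1", f))
  f2 <- sub(paste0("H", h), paste0("H", h + 1L), f, fixed = TRUE)
  e$species[[2]] <- species(e$species[[2]]$name, f2, "product")
  reaction_entry(e$entry_id, e$ec, e$species, e$overall_changes, e$mechanism)
}
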