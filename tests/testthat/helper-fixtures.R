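# Small fixture builders and independent oracles shared across tests.

# Minimal valid entry; mechanism defaults to the single-step mechanism
# equal to the overall change (always satisfies step composition).
make_entry <- function(entry_id = "E1", ec = "3.1.1.1",
                       overall = c("C.O_1.0", "C.O_0.1"),
                       mechanism = NULL,
                       substrates = list(c("water", "H2O")),
                       products = list(c("prod", "C2H4O2"))) {
  ov <- bond_change_vector(overall)
  if (is.null(mechanism)) mechanism <- list(ov)
  sp <- c(lapply(substrates, function(s) species(s[1], s[2], "substrate")),
          lapply(products, function(s) species(s[1], s[2], "product")))
  reaction_entry(entry_id, ec, sp, ov, mechanism)
}

# Brute-force global alignment oracle: enumerates every monotone global
# alignment of the two step sequences by recursion (match / gap in a /
# gap in b) and returns the maximum total score. Independent of the
# dynamic-programming implementation under test.
brute_force_alignment_score <- function(steps_a, steps_b, gap_penalty = 0) {
  na <- length(steps_a); nb <- length(steps_b)
  s <- matrix(0, max(na, 1), max(nb, 1))
  for (i in seq_len(na)) for (j in seq_len(nb))
    s[i, j] <- tanimoto(steps_a[[i]], steps_b[[j]])
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) best <- max(best, s[i, j] + rec(i + 1, j + 1))
    if (i <= na) best <- max(best, -gap_penalty + rec(i + 1, j))
    if (j <= nb) best <- max(best, -gap_penalty + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Brute-force permutation-test oracle: explicit sign enumeration via
# expand.grid, separate from the bit-arithmetic implementation.
brute_force_permutation <- function(a, b, sidedness = "two") {
  d <- a - b
  F <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), F)))
  Dp <- as.vector(signs %*% d)
  D0 <- sum(d)
  n <- if (sidedness == "two") sum(abs(Dp) >= abs(D0)) else sum(Dp >= D0)
  list(D0 = D0, n = n, p = n / 2^F)
}

# Linearly separable two-class toy data for tuning tests; class sizes
# may be unbalanced so that an oversized k forces majority-class votes.
separable_data <- function(n1 = 15, n2 = 15, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * 2, mean = -3), ncol = 2),
             matrix(rnorm(n2 * 2, mean = 3), ncol = 2))
  colnames(X) <- c("f1", "f2")
  rownames(X) <- sprintf("r%02d", seq_len(nrow(X)))
  list(X = X, y = rep(1:2, c(n1, n2)))
}

# Entries whose EC codes realise a prescribed external-split scenario:
# n_unique distinct third-level codes among the candidates plus
# n_dup repeats of earlier candidates' codes, shuffled.
split_scenario_entries <- function(n_base = 260, n_unique = 43, n_dup = 17,
                                   seed = 1) {
  set.seed(seed)
  base <- lapply(seq_len(n_base), function(i)
    make_entry(sprintf("B%03d", i),
               ec = sprintf("%d.%d.%d.%d", (i %% 6) + 1,
                            (i %% 9) + 1, (i %% 7) + 1, i)))
  # candidate third-level codes: unique ones use a high second field so
  # they cannot collide with each other or (for strictness) the base
  uniq <- sprintf("%d.%d.%d", rep(1:6, length.out = n_unique), 77,
                  seq_len(n_unique))
  codes <- c(uniq, sample(uniq, n_dup, replace = TRUE))
  codes <- sample(codes)  # order must not matter for the resulting sizes
  cand <- lapply(seq_along(codes), function(i)
    make_entry(sprintf("N%03d", i), ec = paste0(codes[i], ".", i)))
  list(base = base, candidates = cand)
}
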