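test_that("overall and composite bond-change vectors follow the step algebra", {
  # amide hydrolysis: C-N cleavage with C-O and N-H formation, count 1 each
  e <- make_entry(overall = c("C.N_1.0", "C.O_0.1", "H.N_0.1"))
  ov <- overall_bond_change_vector(e)
  expect_equal(setNames(as.integer(ov), names(ov)),
               c("C.N_1.0" = 1L, "C.O_0.1" = 1L, "H.N_0.1" = 1L))
  # a transient bond registers in the composite but not the overall set
  tr <- make_entry(overall = character(0),
                   mechanism = list(bond_change_vector("C.O_0.1"),
                                    bond_change_vector("C.O_1.0")),
                   ec = "5.1.1.1")
  expect_length(overall_bond_change_vector(tr), 0L)
  comp <- composite_bond_change_vector(tr)
  expect_equal(setNames(as.integer(comp), names(comp)),
               c("C.O_0.1" = 1L, "C.O_1.0" = 1L))
  # single-step mechanism: composite equals overall
  s <- make_entry(overall = c("C.O_0.1", "C.O_0.1"))
  expect_equal(composite_bond_change_vector(s), overall_bond_change_vector(s))
  # additivity over identical steps
  st <- bond_change_vector(c("C.H_1.0", "C.H_1.0"))
  m <- reaction_entry("E9", "1.1.1.1",
                      list(species("s", "CH4", "substrate"),
                           species("p", "CH4", "product")),
                      bond_change_vector(rep("C.H_1.0", 6)),
                      list(st, st, st))
  cm <- composite_bond_change_vector(m)
  expect_equal(unname(as.integer(cm["C.H_1.0"])), 6L)
})

test_that("composite minus inverse equals overall net on generated data", {
  d <- generate_dataset(generator_config(n_entries = 25, seed = 3))
  for (e in d) {
    comp <- composite_bond_change_vector(e)
    expect_equal(bcv_net(comp), bcv_net(overall_bond_change_vector(e)))
  }
})

test_that("human-designed features match their definitions", {
  reg <- default_feature_registry()
  expect_length(reg, 28L)
  expect_true(all(c("f:X-H", "dv:C", "water.OH-.su", "Mod_Diff") %in% names(reg)))

  # f:X-H counts bonds to hydrogen formed: O.H_0.1 x2 formed, C.H_1.0 cleaved
  e <- make_entry(overall = c("H.O_0.1", "H.O_0.1", "C.H_1.0"))
  v <- human_designed_vector(e, reg)
  expect_equal(unname(v["f:X-H"]), 2)
  expect_equal(unname(v["c:X-H"]), 1)

  # dv:C counts C.C tokens twice (both atoms are carbon)
  ecc <- make_entry(overall = c("C.C_1.2", "C.O_1.0"))
  vcc <- human_designed_vector(ecc, reg)
  expect_equal(unname(vcc["dv:C"]), 2 * (2 - 1) + 1 * (0 - 1))
  expect_equal(unname(vcc["dv:O"]), -1)
  expect_equal(unname(vcc["net.dv"]), 1 + (-1))

  # hydrolase cue: water substrate sets water.OH-.su
  expect_equal(unname(v["water.OH-.su"]), 1)
  dry <- make_entry(substrates = list(c("glucose", "C6H12O6")))
  expect_equal(unname(human_designed_vector(dry, reg)["water.OH-.su"]), 0)

  # isomerase: one substrate, one isomeric product -> Mod_Diff exactly 0
  iso <- make_entry(ec = "5.3.1.1", overall = c("H.O_0.1", "H.O_1.0"),
                    substrates = list(c("A", "C6H12O6")),
                    products = list(c("B", "C6H12O6")))
  viso <- human_designed_vector(iso, reg)
  expect_identical(unname(viso["Mod_Diff"]), 0)
  expect_equal(unname(viso["isomer"]), 1)

  # ATP hydrolysis flag needs both the substrate and the product side
  lig <- make_entry(ec = "6.1.1.1", overall = c("O.P_0.1", "O.P_1.0"),
                    substrates = list(c("ATP", "C10H16N5O13P3")),
                    products = list(c("ADP", "C10H15N5O10P2")))
  expect_equal(unname(human_designed_vector(lig, reg)["ATP.su.ADP.AMP.pr"]), 1)
  expect_equal(unname(human_designed_vector(iso, reg)["ATP.su.ADP.AMP.pr"]), 0)

  # Mod_Diff is an error without both sides
  noprod <- e
  noprod$species <- Filter(function(s) s$role == "substrate", noprod$species)
  expect_error(human_designed_vector(noprod, reg), "Mod_Diff")
})

test_that("every synthetic hydrolase has the water-substrate cue", {
  d <- generate_dataset(generator_config(n_entries = 60, seed = 9))
  reg <- default_feature_registry()
  for (e in d)
    if (e$ec_class == 3L)
      expect_equal(unname(human_designed_vector(e, reg)["water.OH-.su"]), 1)
  # the converse need not hold: a non-hydrolase with water substrate
  odd <- make_entry(ec = "2.1.1.1", substrates = list(c("water", "H2O")))
  expect_equal(unname(human_designed_vector(odd)["water.OH-.su"]), 1)
})

test_that("descriptor matrices are deterministic with stable feature sets", {
  e1 <- make_entry("A", overall = c("C.O_0.1"))
  e2 <- make_entry("B", overall = c("H.N_0.1", "C.C_1.0"))
  m <- build_descriptor_matrix(list(e1, e2), "overall")
  expect_equal(ncol(m), 3L)  # disjoint token sets: widths add
  expect_equal(rownames(m), c("A", "B"))
  m2 <- build_descriptor_matrix(list(e2, e1), "overall")
  expect_equal(m2[rownames(m), colnames(m)], m)
  # human kind: width = registry size
  h <- build_descriptor_matrix(list(e1, e2), "human")
  expect_equal(ncol(h), 28L)
  # feature projection drops unseen tokens
  p <- build_descriptor_matrix(list(e2), "overall", features = colnames(m)[1:2])
  expect_equal(colnames(p), colnames(m)[1:2])
})

test_that("z-scaling matches the population-sd hand computation", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  prm <- zscale_fit(m)
  sc <- zscale_apply(m, prm)
  expect_equal(sc[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-3,
               ignore_attr = TRUE)
  # constant column maps to zeros and is kept
  expect_equal(unname(sc[, "b"]), c(0, 0, 0))
  expect_equal(ncol(sc), 3L)
  # post-conditions: mean 0, population sd 1 within 1e-9
  expect_lt(max(abs(colMeans(sc[, c("a", "c")]))), 1e-9)
  expect_lt(max(abs(sqrt(colMeans(sweep(sc[, c("a", "c")], 2,
                                        colMeans(sc[, c("a", "c")]))^2)) - 1)),
            1e-9)
  # applying training parameters to new data need not centre it
  test <- cbind(a = c(10, 11), b = c(5, 6), c = c(1, 2))
  sct <- zscale_apply(test, prm)
  expect_gt(abs(mean(sct[, "a"])), 1)
  # scaling is invertible for non-constant columns
  back <- sweep(sweep(sc[, c("a", "c")], 2, prm$sd[c("a", "c")], `*`), 2,
                -prm$mean[c("a", "c")])
  expect_equal(back, m[, c("a", "c")], ignore_attr = TRUE)
  expect_error(zscale_apply(m[, 1:2], prm), "feature mismatch")
})
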