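test_that("hydrogen accounting of compiled patterns follows valence rules", {
  # dimethyl amine: 2 x CH3 + 1 x NH = 7 hydrogens on 3 heavy atoms
  p <- as.data.frame(compilePattern("CNC", "S1"))
  expect_equal(p$n_heavy, 3L)
  expect_equal(p$n_H_total, 7L)
  expect_equal(p$n_H_defined, 0L)
  expect_equal(p$n_H_variable, 7L)
  expect_equal(p$flexibility, 7 / 3)

  # para-H phenol: one written hydrogen is defined, five remain variable
  p <- as.data.frame(compilePattern("Oc1ccc([H])cc1", "S2"))
  expect_equal(p$n_heavy, 7L)
  expect_equal(p$n_H_total, 6L)
  expect_equal(p$n_H_defined, 1L)
  expect_equal(p$n_H_variable, 5L)
  expect_equal(p$flexibility, 5 / 7)

  # benzene: all hydrogens variable
  expect_equal(unname(flexibility(compilePattern("c1ccccc1", "S3"))), 1.0)

  # fully hydrogen-defined pattern has flexibility zero
  p <- as.data.frame(compilePattern("[H]C([H])([H])[H]", "S4"))
  expect_equal(p$n_H_defined, 4L)
  expect_equal(p$flexibility, 0)

  # a pattern with no [H] has flexibility n_H_total / n_heavy
  p <- as.data.frame(compilePattern("CCO", "S5"))
  expect_equal(p$flexibility, p$n_H_total / p$n_heavy)
})

test_that("uncompilable catalog SMILES are rejected with the id named", {
  expect_error(compilePattern("C1CC", "Substructure_0999"),
               "Substructure_0999")
  ps <- compileCatalog(c("A", "B"), c("c1ccccc1", "C1CC"))
  expect_equal(patternIds(ps), "A")
  expect_equal(rejections(ps)$substructure_id, "B")
})

test_that("defined-hydrogen positions are not substitutable in matching", {
  paraH <- compilePattern("Oc1ccc([H])cc1", "paraH")
  expect_true(matchesPattern(paraH, "Oc1ccccc1"))          # phenol itself
  # para position occupied: the defined H cannot be placed (oracle-checked)
  expect_false(matchesPattern(paraH, "Oc1ccc(Cl)cc1"))
  # no ring hydrogen anywhere
  expect_false(matchesPattern(paraH, "Oc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl"))
  # benzene in toluene, and self-matching for a spread of patterns
  expect_true(matchesPattern(compilePattern("c1ccccc1"), "Cc1ccccc1"))
  for (smi in fixturePatterns())
    expect_true(matchesPattern(compilePattern(smi), smi),
                info = paste("self-match:", smi))
})

test_that("matching is invariant under target SMILES rewriting", {
  benzene <- compilePattern("c1ccccc1")
  forms <- c("c1ccccc1", "C1=CC=CC=C1", "c1ccc(cc1)[H]")
  expect_true(all(matchesPattern(benzene, forms)))
  paraH <- compilePattern("Oc1ccc([H])cc1")
  expect_true(all(matchesPattern(paraH, c("Oc1ccccc1", "OC1=CC=CC=C1"))))
})

test_that("kekule-written patterns match aromatic targets (one perception model)", {
  kek <- compilePattern("C1=CC=CC=C1", "kekulized")
  expect_true(matchesPattern(kek, "Cc1ccccc1"))
})

test_that("removing defined hydrogens never shrinks the match set", {
  mols <- fixtureMolecules()
  withH <- c("Oc1ccc([H])cc1", "[H]c1ccccc1", "C([H])N([H])C")
  for (smi in withH) {
    strict <- matchesPattern(compilePattern(smi), mols)
    loose <- matchesPattern(compilePattern(gsub("([H])", "", smi,
                                                fixed = TRUE)), mols)
    expect_true(all(loose >= strict), info = smi)
  }
})

test_that("occurrence matrix is presence-based and order-independent", {
  cs <- CompoundSet(c("a", "b", "c"),
                    c("Cc1ccccc1", "c1ccccc1O", "CCCC"))
  ps <- compileCatalog("benzene", "c1ccccc1")
  occ <- occurrenceMatrix(cs, ps)
  expect_equal(unname(colSums(presence(occ))), 2)
  expect_equal(dim(occ), c(3L, 1L))

  # empty pattern set -> zero columns
  occ0 <- occurrenceMatrix(cs, compileCatalog(character(0), character(0)))
  expect_equal(dim(occ0), c(3L, 0L))

  # permuting compounds permutes rows, values unchanged
  perm <- c("c", "a", "b")
  occP <- occurrenceMatrix(cs[perm], ps)
  expect_equal(presence(occP)[perm, , drop = FALSE],
               presence(occ)[perm, , drop = FALSE])
})

test_that("occurrence matrix agrees with the independent RDKit oracle", {
  mols <- fixtureMolecules()
  pats <- fixturePatterns()
  cs <- CompoundSet(names(mols), mols)
  ps <- compileCatalog(names(pats), pats)
  mine <- presence(occurrenceMatrix(cs, ps))
  orc <- oracleOccurrence(unname(mols), unname(pats))
  dimnames(orc) <- dimnames(mine)
  expect_identical(mine, orc)
})

test_that("scaffold detection reports every contained core", {
  # flavone carries the chromone core
  expect_true("chromone" %in% detectScaffolds("O=C1C=C(c2ccccc2)Oc2ccccc21"))
  # the chromone core is embedded in xanthone: both are reported
  xs <- detectScaffolds("O=C1c2ccccc2Oc2ccccc21")
  expect_setequal(xs, c("chromone", "xanthone"))
  expect_length(detectScaffolds("C1CCCCC1"), 0L)
})
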