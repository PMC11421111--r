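## tiny catalog + signature used across the screening tests
screeningFixture <- function() {
  cat <- compileCatalog(c("S1", "S2", "S3"),
                        c("c1ccccc1", "CNC", "c1ccncc1"))
  fp <- data.frame(
    substructure_id = c("S1", "S2", "S3"),
    name = NA_character_, smiles = c("c1ccccc1", "CNC", "c1ccncc1"),
    n_hits = c(8L, 2L, 1L), f1 = c(0.8, 0.2, 0.05),
    n_class_hits = c(3L, 1L, 1L), f2 = c(1, 1 / 3, 1 / 3),
    n_H_total = c(6L, 7L, 5L), n_H_defined = 0L,
    n_H_variable = c(6L, 7L, 5L), n_heavy = c(6L, 3L, 6L),
    flexibility = c(1, 7 / 3, 5 / 6),
    q3 = c(0.8, 0.2 / (7 / 3), 0.05 / (5 / 6)),
    q4 = c(1, (1 / 3) / (7 / 3), (1 / 3) / (5 / 6)))
  sig <- buildSignature(fp)
  list(cat = cat, sig = sig)
}

test_that("scaffold filtering keeps core-bearing molecules with counts", {
  lib <- CompoundSet(c("chr", "pur", "alk"),
                     c("O=C1C=COc2ccccc21", "c1ncc2[nH]cnc2n1", "CCCCCC"))
  flt <- filterByScaffolds(lib)
  expect_equal(nrow(flt$hits), 2L)
  expect_equal(flt$counts[["chromone"]], 1L)
  expect_equal(flt$counts[["purine"]], 1L)
  expect_equal(flt$n_multi, 0L)

  # a molecule with two cores is listed under both scaffolds
  both <- CompoundSet("dual", "O=C1C=C(Cc3ncc4[nH]cnc4n3)Oc2ccccc21")
  flt2 <- filterByScaffolds(both)
  expect_equal(nrow(flt2$hits), 1L)
  expect_setequal(strsplit(flt2$hits$scaffolds, ";")[[1]],
                  c("chromone", "purine"))
  expect_equal(flt2$n_multi, 1L)

  # empty library
  empty <- CompoundSet(character(0), character(0))
  flt0 <- filterByScaffolds(empty)
  expect_equal(nrow(flt0$hits), 0L)
  expect_true(all(flt0$counts == 0L))

  # count identity: sum of per-scaffold counts >= distinct hits,
  # equality iff no multi-scaffold compound
  expect_equal(sum(flt$counts), nrow(flt$hits))
  expect_equal(sum(flt2$counts), nrow(flt2$hits) + flt2$n_multi)
})

test_that("compound scores sum distinct matched totals per tier", {
  fx <- screeningFixture()
  totals <- setNames(fx$sig$total, fx$sig$substructure_id)
  tiers <- setNames(fx$sig$tier, fx$sig$substructure_id)
  # aniline-like molecule: benzene + secondary amine, no pyridine
  sc <- scoreCompounds("CN(C)c1ccccc1", fx$cat, fx$sig, "combined")
  expect_equal(sc$score, unname(totals["S1"] + totals["S2"]))
  expect_equal(sc$n_matched, 2L)
  # nothing matches an alkane
  expect_equal(scoreCompounds("CCCC", fx$cat, fx$sig, "combined")$score, 0L)
  # additivity: combined = primary + secondary on a mixed set
  mols <- c("CN(C)c1ccccc1", "c1ccncc1", "CCO", "Cc1ccccc1")
  sP <- scoreCompounds(mols, fx$cat, fx$sig, "primary")$score
  sS <- scoreCompounds(mols, fx$cat, fx$sig, "secondary")$score
  sC <- scoreCompounds(mols, fx$cat, fx$sig, "combined")$score
  expect_equal(sC, sP + sS)
})

test_that("screening produces deterministic ranked lists per scaffold", {
  fx <- screeningFixture()
  lib <- generateLibrary(c(chromone = 8L, purine = 4L), n_decoys = 4L,
                         seed = 5L)
  res <- screenLibrary(lib, fx$cat, fx$sig)
  expect_s4_class(res, "ScreeningResult")
  expect_gte(scaffoldCounts(res)[["chromone"]], 8L)
  lists <- rankedLists(res)
  expect_true(all(c("chromone.primary", "chromone.combined",
                    "purine.secondary") %in% names(lists)))
  # combined = primary + secondary on every hit
  hits <- screeningHits(res)
  expect_equal(hits$score_combined, hits$score_primary + hits$score_secondary)
  # scores descend within a list
  for (l in lists) expect_true(all(diff(l$score) <= 0))

  # permuting the library leaves every ranked list identical
  perm <- withr::with_seed(42, sample(nCompounds(lib)))
  res2 <- screenLibrary(lib[perm], fx$cat, fx$sig)
  for (nm in names(lists))
    expect_equal(rankedLists(res2)[[nm]], lists[[nm]], info = nm)

  # top-k lists are prefixes of the full lists
  res3 <- screenLibrary(lib, fx$cat, fx$sig, topK = 3L)
  for (nm in names(lists))
    expect_equal(rankedLists(res3)[[nm]],
                 utils::head(lists[[nm]], 3L), info = nm)
})

test_that("a library without scaffolds yields empty lists and a warning", {
  fx <- screeningFixture()
  lib <- CompoundSet(c("a", "b"), c("CCCC", "CCO"))
  expect_warning(res <- screenLibrary(lib, fx$cat, fx$sig), "no compounds")
  expect_equal(nrow(screeningHits(res)), 0L)
  expect_length(rankedLists(res), 0L)
})

test_that("balanced shortlisting is a deterministic round-robin over cells", {
  cand <- data.frame(
    compound_id = c("A", "B", "C", "D"),
    score = c(50, 40, 30, 20),
    clogp = c(1, 1, 5, 5),      # two clogp cells
    mw = c(250, 260, 255, 245)) # same mw cell
  # k = 2: the best of each occupied cell
  sl <- shortlistBalanced(cand, 2)
  expect_setequal(sl$compound_id, c("A", "C"))
  # k >= n returns everything
  expect_equal(nrow(shortlistBalanced(cand, 10)), 4L)
  # each pick is cell-wise maximal among the then-unchosen
  sl3 <- shortlistBalanced(cand, 3)
  expect_equal(sl3$compound_id[1:2], c("A", "C"))
  expect_equal(sl3$compound_id[3], "B")
  # empty input
  expect_equal(nrow(shortlistBalanced(cand[0, ], 3)), 0L)
})
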