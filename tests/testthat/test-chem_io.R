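test_that("compound tables read cleanly and reject bad rows with reasons", {
  cs <- readCompoundTable(smallCompoundCsv())
  expect_equal(nCompounds(cs), 3L)
  expect_equal(nrow(rejections(cs)), 0L)
  expect_equal(compoundIds(cs), c("C1", "C2", "C3"))
  expect_equal(unname(chemClasses(cs)), c("arene", "alcohol", "azine"))

  # unclosed ring in row 3 -> 2 records, 1 rejection citing the row
  path <- writeTempCsv(data.frame(id = c("C1", "C2", "C3"),
                                  smiles = c("CCO", "c1ccccc1", "C1CC"),
                                  class = "x"))
  cs <- readCompoundTable(path)
  expect_equal(nCompounds(cs), 2L)
  expect_equal(rejections(cs)$row, 3L)
  expect_equal(rejections(cs)$compound_id, "C3")
  expect_match(rejections(cs)$reason, "SMILES")
  # accepted + rejected = input rows
  expect_equal(nCompounds(cs) + nrow(rejections(cs)), 3L)
  # strict mode fails instead
  expect_error(readCompoundTable(path, strict = TRUE), "C3")
})

test_that("duplicate compound ids are an error naming the id", {
  path <- writeTempCsv(data.frame(id = c("X1", "X2", "X1"),
                                  smiles = c("CCO", "CC", "CCC")))
  expect_error(readCompoundTable(path), "X1")
})

test_that("missing required columns are a configuration error", {
  path <- writeTempCsv(data.frame(notid = "A", smiles = "CC"))
  expect_error(readCompoundTable(path), "required column")
  path2 <- writeTempCsv(data.frame(id = character(0),
                                   smiles = character(0)))
  expect_error(readCompoundTable(path2), "empty")
})

test_that("TSV input is auto-detected and passthrough columns survive", {
  path <- writeTempCsv(data.frame(id = "A", smiles = "CCO", class = "x",
                                  PubChem_CID = "702"),
                       sep = "\t", ext = ".tsv")
  cs <- readCompoundTable(path)
  expect_equal(as.data.frame(cs)$PubChem_CID, "702")
})

test_that("substructure catalogs keep defined hydrogens through parsing", {
  path <- writeTempCsv(data.frame(substructure_id = c("S1", "S2"),
                                  name = c("benzene", "phenol para-H"),
                                  smiles = c("c1ccccc1", "Oc1ccc([H])cc1")))
  ps <- readSubstructureCatalog(path)
  expect_equal(patternIds(ps), c("S1", "S2"))
  expect_equal(as.data.frame(ps)$n_H_defined, c(0L, 1L))
  # the written hydrogen is not folded away in the stored canonical form
  expect_match(as.data.frame(ps)$canonical_smiles[2], "[H]", fixed = TRUE)

  dup <- writeTempCsv(data.frame(substructure_id = c("S1", "S1"),
                                 name = "n", smiles = c("CC", "CCC")))
  expect_error(readSubstructureCatalog(dup), "S1")
})

test_that("compound tables round-trip id, canonical SMILES and class", {
  cs <- readCompoundTable(smallCompoundCsv())
  df <- as.data.frame(cs)
  out <- writeTempCsv(data.frame(id = df$compound_id, smiles = df$smiles,
                                 class = df$chem_class))
  back <- readCompoundTable(out)
  expect_equal(compoundIds(back), compoundIds(cs))
  expect_equal(compoundSmiles(back), compoundSmiles(cs))
  expect_equal(chemClasses(back), chemClasses(cs))
})

test_that("smiles and sdf screening libraries are readable", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 mol_a", "CCO mol_b", "CCC"), smi)
  lib <- readLibrary(smi)
  expect_equal(nCompounds(lib), 3L)
  expect_equal(compoundIds(lib)[1:2], c("mol_a", "mol_b"))

  sdf <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(ChemmineR::smiles2sdf(c(m1 = "c1ccccc1", m2 = "CCO")),
                       sdf)
  lib2 <- readLibrary(sdf)
  expect_equal(nCompounds(lib2), 2L)
  expect_equal(unname(compoundSmiles(lib2)), canonicalSmiles(c("c1ccccc1", "CCO")))
})

test_that("ranked lists write with 1-based ranks and round-trip bit-exactly", {
  hits <- data.frame(compound_id = c("A", "B"),
                     smiles = c("CCO", "CCC"),
                     scaffolds = c("chromone", "purine"),
                     score = c(52L, 30L),
                     n_matched_primary = c(2L, 1L),
                     n_matched_secondary = c(0L, 1L))
  path <- tempfile(fileext = ".csv")
  writeRankedList(hits, path)
  back <- readRankedList(path)
  expect_equal(back$rank, c(1L, 2L))
  expect_identical(back$score, hits$score)
  expect_identical(back$compound_id, hits$compound_id)

  # empty hit list -> header-only file
  writeRankedList(hits[0, ], path)
  expect_equal(nrow(readRankedList(path)), 0L)
  expect_equal(length(readLines(path)), 1L)
})
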