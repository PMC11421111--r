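# Shared in-code fixtures for the test suite.

# small, chemically tame molecules on which OpenBabel and RDKit agree
fixtureMolecules <- function() {
  c(toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    chlorophenol = "Oc1ccc(Cl)cc1",
    anisole = "COc1ccccc1",
    pyridine = "c1ccncc1",
    picoline = "Cc1ccccn1",
    dimethylaniline = "CN(C)c1ccccc1",
    benzamide = "NC(=O)c1ccccc1",
    cyclohexane = "C1CCCCC1",
    ethylacetate = "CCOC(C)=O")
}

fixturePatterns <- function() {
  c(benzene = "c1ccccc1",
    phenolParaH = "Oc1ccc([H])cc1",
    secondaryAmine = "CNC",
    esterAcid = "CC(=O)O",
    pyridineRing = "c1ccncc1")
}

writeTempCsv <- function(df, sep = ",", ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

smallCompoundCsv <- function() {
  writeTempCsv(data.frame(
    id = c("C1", "C2", "C3"),
    smiles = c("Cc1ccccc1", "CCO", "c1ccncc1"),
    class = c("arene", "alcohol", "azine")))
}
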