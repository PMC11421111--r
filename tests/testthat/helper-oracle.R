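# Independent substructure-matching oracle backed by RDKit (a different
# toolkit and code path from the OpenBabel-based implementation). Explicit
# [H] atoms in a pattern are merged into hydrogen-count query constraints
# on their heavy atom, mirroring the defined-hydrogen semantics.
oracleOccurrence <- function(targets, patterns) {
  script <- c(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "data = json.load(sys.stdin)",
    "ps = Chem.SmilesParserParams(); ps.removeHs = False",
    "qs = [Chem.MergeQueryHs(Chem.MolFromSmiles(p, ps)) for p in data['patterns']]",
    "res = []",
    "for t in data['targets']:",
    "    mol = Chem.MolFromSmiles(t)",
    "    res.append([bool(mol.HasSubstructMatch(q)) for q in qs])",
    "print(json.dumps(res))"
  )
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  inp <- as.character(jsonlite::toJSON(list(targets = targets,
                                            patterns = patterns)))
  out <- system2("python", f, input = inp, stdout = TRUE)
  m <- jsonlite::fromJSON(paste(out, collapse = ""))
  matrix(as.logical(m), nrow = length(targets),
         dimnames = list(targets, patterns))
}
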