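## Pattern engine: defined-hydrogen substructure queries, matching,
## occurrence matrices, and basic-scaffold detection.
##
## Semantics (applied identically to every pattern and scaffold):
##   * catalog SMILES are interpreted as substructure queries directly:
##     aromatic lowercase atoms match aromatic atoms, aliphatic uppercase
##     match aliphatic atoms; both sides go through OpenBabel's aromaticity
##     perception (patterns are canonicalised first, so kekule input is
##     aromatised exactly as targets are);
##   * every hydrogen written as [H] becomes a minimum-hydrogen-count
##     constraint on its heavy atom - the position is not substitutable -
##     while unwritten hydrogens may be replaced by any substituent;
##   * stereo marks are stripped (patterns are 2D), charges and isotopes
##     must match exactly as written;
##   * multiple embeddings of a pattern in one molecule count once.
##
## During canonicalisation defined hydrogens are protected as [3H] isotope
## markers (OpenBabel would otherwise fold them into implicit hydrogens); a
## genuine tritium atom in a catalog SMILES would therefore be misread as a
## defined hydrogen.

.stripStereo <- function(smiles) gsub("@|/|\\\\", "", smiles)

#' Compile one substructure record into a pattern query
#'
#' Turns a catalog SMILES (possibly containing defined hydrogens written as
#' `[H]`) into a SMARTS query plus the hydrogen/heavy-atom accounting that
#' feeds the average flexibility: the pattern read as a molecule (implicit
#' hydrogens filled by standard valence) has `n_H_total` hydrogens, of which
#' the `n_H_defined` written ones are unsubstitutable; the remaining
#' `n_H_variable` are substitutable, and
#' `flexibility = n_H_variable / n_heavy`.
#'
#' @param smiles a single SMILES string.
#' @param substructure_id identifier used in error messages and output.
#' @param name optional trivial name.
#' @return a one-row [PatternSet-class].
#' @export
#' @examples
#' pq <- compilePattern("Oc1ccc([H])cc1", "S1", "phenol (para-H)")
#' as.data.frame(pq)[, c("n_heavy", "n_H_total", "n_H_defined", "flexibility")]
compilePattern <- function(smiles, substructure_id = "pattern",
                           name = NA_character_) {
  stopifnot(length(smiles) == 1L)
  s <- .stripStereo(smiles)
  nDefined <- length(gregexpr("[H]", s, fixed = TRUE)[[1]])
  if (gregexpr("[H]", s, fixed = TRUE)[[1]][1] == -1L) nDefined <- 0L
  protected <- gsub("[H]", "[3H]", s, fixed = TRUE)
  can <- canonicalSmiles(protected)
  if (is.na(can))
    stop("cannot compile substructure '", substructure_id,
         "': SMILES does not parse: ", smiles)
  nMarkers <- length(gregexpr("[3H]", can, fixed = TRUE)[[1]])
  if (gregexpr("[3H]", can, fixed = TRUE)[[1]][1] == -1L) nMarkers <- 0L
  if (nMarkers != nDefined)
    stop("defined hydrogens lost for substructure '", substructure_id, "'")
  smarts <- .definedHSmarts(can)
  acc <- .hydrogenAccounting(s)
  nVar <- acc$n_H_total - nDefined
  if (nVar < 0)
    stop("more defined than total hydrogens in substructure '",
         substructure_id, "'")
  df <- data.frame(
    substructure_id = substructure_id,
    name = name,
    smiles = smiles,
    canonical_smiles = gsub("[3H]", "[H]", can, fixed = TRUE),
    smarts = smarts,
    n_heavy = acc$n_heavy,
    n_H_total = acc$n_H_total,
    n_H_defined = as.integer(nDefined),
    n_H_variable = as.integer(nVar),
    flexibility = nVar / acc$n_heavy,
    stringsAsFactors = FALSE
  )
  new("PatternSet", patternData = df,
      rejections = .emptyPatternRejections(), metadata = list())
}

.emptyPatternRejections <- function() {
  data.frame(row = integer(0), substructure_id = character(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Compile a whole substructure catalog
#'
#' @param substructure_id,smiles,name parallel vectors describing the
#'   catalog rows.
#' @param strict error on the first uncompilable SMILES instead of rejecting.
#' @param metadata list of provenance information.
#' @return a [PatternSet-class]; uncompilable rows are reported via
#'   [rejections()].
#' @export
compileCatalog <- function(substructure_id, smiles, name = NA_character_,
                           strict = FALSE, metadata = list()) {
  n <- length(smiles)
  substructure_id <- as.character(substructure_id)
  name <- rep_len(as.character(name), n)
  dup <- unique(substructure_id[duplicated(substructure_id)])
  if (length(dup))
    stop("duplicated substructure_id: ", paste(dup, collapse = ", "))
  rows <- vector("list", n)
  rej <- .emptyPatternRejections()
  for (i in seq_len(n)) {
    res <- tryCatch(compilePattern(smiles[i], substructure_id[i], name[i]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(conditionMessage(res))
      rej <- rbind(rej, data.frame(row = i,
                                   substructure_id = substructure_id[i],
                                   reason = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      rows[[i]] <- res@patternData
    }
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) df <- compilePattern("C")@patternData[0, , drop = FALSE]
  rownames(df) <- NULL
  new("PatternSet", patternData = df, rejections = rej, metadata = metadata)
}

#' Match a pattern against molecules
#'
#' Pure presence/absence predicate: `TRUE` iff an embedding of the query
#' into the molecule exists honouring element, aromaticity, bond order,
#' charge and defined-hydrogen constraints.
#'
#' @param pattern a one-row [PatternSet-class] (or larger; only the first
#'   query is used) or a single SMARTS string.
#' @param molecules a [CompoundSet-class] or character vector of SMILES.
#' @return logical vector, one element per molecule.
#' @export
#' @examples
#' matchesPattern(compilePattern("c1ccccc1"), c("Cc1ccccc1", "C1CCCCC1"))
matchesPattern <- function(pattern, molecules) {
  smarts <- if (is(pattern, "PatternSet")) pattern@patternData$smarts[1]
            else as.character(pattern)
  mols <- if (is(molecules, "CompoundSet")) .molsOf(molecules)
          else .obMols(canonicalSmiles(molecules))
  .smartsCount(mols, smarts) > 0
}

#' Compute the compounds x substructures occurrence matrix
#'
#' `presence[i, j]` is `TRUE` iff substructure `j` matches compound `i`;
#' multiplicity of embeddings is ignored. Values are deterministic and
#' independent of input order.
#'
#' @param compounds a [CompoundSet-class].
#' @param patterns a [PatternSet-class].
#' @return an [OccurrenceMatrix-class].
#' @export
occurrenceMatrix <- function(compounds, patterns) {
  stopifnot(is(compounds, "CompoundSet"), is(patterns, "PatternSet"))
  mols <- .molsOf(compounds)
  pid <- patternIds(patterns)
  m <- matrix(FALSE, nrow = nCompounds(compounds), ncol = length(pid),
              dimnames = list(compoundIds(compounds), pid))
  for (j in seq_along(pid))
    m[, j] <- .smartsCount(mols, patterns@patternData$smarts[j]) > 0
  new("OccurrenceMatrix", presence = m)
}

#' Built-in basic scaffold definitions
#'
#' The five ring-system cores used as library pre-filters: chromone,
#' xanthone, phenothiazine, purine and 9-deazapurine.
#'
#' @return a [PatternSet-class] of compiled scaffold queries whose
#'   `substructure_id` is the scaffold name.
#' @export
defaultScaffolds <- function() {
  path <- system.file("extdata", "scaffolds.csv", package = "PatternSig")
  readScaffoldFile(path)
}

#' Detect basic scaffolds in molecules
#'
#' Plain substructure containment of each named core (no ring-system
#' pruning): a molecule may carry several scaffolds, and a scaffold whose
#' core is embedded in a larger listed core (chromone within xanthone) is
#' reported as well.
#'
#' @param molecules a [CompoundSet-class] or character vector of SMILES.
#' @param scaffolds a [PatternSet-class] of scaffold queries, by default
#'   [defaultScaffolds()].
#' @return a list (one element per molecule) of character vectors of
#'   scaffold names; for a single molecule the bare character vector.
#' @export
#' @examples
#' detectScaffolds("O=c1cc(-c2ccccc2)oc2ccccc12")  # flavone -> chromone
detectScaffolds <- function(molecules, scaffolds = defaultScaffolds()) {
  single <- is.character(molecules) && length(molecules) == 1L
  cs <- if (is(molecules, "CompoundSet")) molecules
        else CompoundSet(paste0("mol", seq_along(molecules)), molecules)
  occ <- occurrenceMatrix(cs, scaffolds)
  res <- apply(presence(occ), 1L, function(r) colnames(presence(occ))[r],
               simplify = FALSE)
  names(res) <- compoundIds(cs)
  if (single) res[[1]] else res
}
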