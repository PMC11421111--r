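#' CompoundSet: a validated collection of molecules
#'
#' Container for a compound table: one row per molecule with a unique
#' identifier, the OpenBabel-canonical SMILES (matching always uses the
#' parsed molecule, the canonical string is for storage and round-trips),
#' an optional name, chemical-class label, bioactivity span in micromolar,
#' and any passthrough columns (database identifiers etc.). Rows whose
#' SMILES do not parse are kept in the rejection report, never in the set.
#'
#' @slot compoundData data.frame with columns `compound_id`, `smiles`
#'   (canonical), `input_smiles`, `name`, `chem_class`, `activity_low_uM`,
#'   `activity_high_uM`, plus passthrough columns.
#' @slot rejections data.frame with columns `row`, `compound_id`, `reason`.
#' @slot metadata list of provenance information (source path, column map).
#' @slot cache environment holding lazily built OpenBabel molecule handles.
#'
#' @aliases compoundIds compoundSmiles chemClasses nCompounds rejections
#' @export
setClass("CompoundSet",
  representation(
    compoundData = "data.frame",
    rejections   = "data.frame",
    metadata     = "list",
    cache        = "environment"
  )
)

setValidity("CompoundSet", function(object) {
  df <- object@compoundData
  required <- c("compound_id", "smiles")
  if (!all(required %in% names(df)))
    return(paste("compoundData must contain columns:",
                 paste(required, collapse = ", ")))
  if (nrow(df) > 0) {
    if (anyNA(df$compound_id) || any(!nzchar(df$compound_id)))
      return("compound_id must be non-empty")
    dup <- df$compound_id[duplicated(df$compound_id)]
    if (length(dup))
      return(paste("duplicated compound_id:", paste(unique(dup), collapse = ", ")))
    if (anyNA(df$smiles))
      return("all stored SMILES must be valid (canonical)")
  }
  TRUE
})

#' Construct a CompoundSet from vectors or a data.frame
#'
#' SMILES are validated and canonicalised through OpenBabel; records whose
#' SMILES do not parse are moved to the rejection report (or raise an error
#' when `strict = TRUE`). Duplicated identifiers are always an error.
#'
#' @param compound_id character vector of unique identifiers.
#' @param smiles character vector of SMILES strings.
#' @param name,chem_class optional character vectors.
#' @param activity_low_uM,activity_high_uM optional numeric bioactivity span.
#' @param extra optional data.frame of passthrough columns.
#' @param strict error on the first invalid SMILES instead of rejecting.
#' @param metadata list of provenance information.
#' @return a [CompoundSet-class] object.
#' @export
#' @examples
#' cs <- CompoundSet(c("a", "b"), c("CCO", "c1ccccc1"))
#' compoundIds(cs)
CompoundSet <- function(compound_id, smiles, name = NA_character_,
                        chem_class = NA_character_,
                        activity_low_uM = NA_real_, activity_high_uM = NA_real_,
                        extra = NULL, strict = FALSE, metadata = list()) {
  n <- length(compound_id)
  df <- data.frame(
    compound_id = as.character(compound_id),
    input_smiles = as.character(smiles),
    name = rep_len(as.character(name), n),
    chem_class = rep_len(as.character(chem_class), n),
    activity_low_uM = rep_len(as.numeric(activity_low_uM), n),
    activity_high_uM = rep_len(as.numeric(activity_high_uM), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == n)
    df <- cbind(df, extra)
  }
  dup <- unique(df$compound_id[duplicated(df$compound_id)])
  if (length(dup))
    stop("duplicated compound_id: ", paste(dup, collapse = ", "))
  can <- canonicalSmiles(df$input_smiles)
  bad <- which(is.na(can))
  if (length(bad) && strict)
    stop("invalid SMILES for compound(s): ",
         paste(df$compound_id[bad], collapse = ", "))
  rej <- data.frame(row = bad,
                    compound_id = df$compound_id[bad],
                    reason = rep("SMILES does not parse", length(bad)),
                    stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(n), bad)
  df <- df[keep, , drop = FALSE]
  df$smiles <- can[keep]
  df <- df[, c("compound_id", "smiles",
               setdiff(names(df), c("compound_id", "smiles"))), drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L && n > 0L)
    stop("empty dataset: no valid compound records")
  new("CompoundSet", compoundData = df, rejections = rej,
      metadata = metadata, cache = new.env(parent = emptyenv()))
}

## lazily built, session-local OpenBabel molecule handles
.molsOf <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  if (is.null(x@cache$mols))
    x@cache$mols <- .obMols(x@compoundData$smiles)
  x@cache$mols
}

#' @rdname CompoundSet-class
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@compoundData$compound_id)

#' @rdname CompoundSet-class
#' @export
setMethod("compoundSmiles", "CompoundSet", function(x) {
  stats::setNames(x@compoundData$smiles, x@compoundData$compound_id)
})

#' @rdname CompoundSet-class
#' @export
setMethod("chemClasses", "CompoundSet", function(x) {
  stats::setNames(x@compoundData$chem_class, x@compoundData$compound_id)
})

#' @rdname CompoundSet-class
#' @export
setMethod("nCompounds", "CompoundSet", function(x) nrow(x@compoundData))

#' @rdname CompoundSet-class
#' @export
setMethod("rejections", "CompoundSet", function(x) x@rejections)

#' @rdname CompoundSet-class
#' @param object a `CompoundSet`.
#' @export
setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with", nrow(object@compoundData), "compounds",
      sprintf("(%d rejected)\n", nrow(object@rejections)))
  cl <- object@compoundData$chem_class
  if (any(!is.na(cl)))
    cat("  chemical classes:", length(unique(cl[!is.na(cl)])), "\n")
  if (nrow(object@compoundData)) {
    head <- utils::head(object@compoundData$compound_id, 4)
    cat("  ids:", paste(head, collapse = ", "),
        if (nrow(object@compoundData) > 4) "..." else "", "\n")
  }
})

#' @rdname CompoundSet-class
#' @param i index, logical vector, or compound identifiers.
#' @param j,drop,... ignored (matrix-style subsetting is row-only).
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@compoundData$compound_id)
  df <- x@compoundData[i, , drop = FALSE]
  rownames(df) <- NULL
  new("CompoundSet", compoundData = df,
      rejections = x@rejections[0, , drop = FALSE],
      metadata = x@metadata, cache = new.env(parent = emptyenv()))
})

#' @rdname CompoundSet-class
#' @export
setMethod("as.data.frame", "CompoundSet", function(x) x@compoundData)

#' PatternSet: compiled substructure queries with hydrogen accounting
#'
#' Each row of a substructure catalog compiles into a SMARTS query in which
#' hydrogens explicitly written as `[H]` in the catalog SMILES become
#' minimum-hydrogen-count constraints on their heavy atom (the position is
#' not substitutable), while all unwritten hydrogens remain substitutable.
#' The hydrogen accounting treats the pattern as a molecule with implicit
#' hydrogens filled by standard valence: `n_H_variable = n_H_total -
#' n_H_defined`, and the average flexibility is `n_H_variable / n_heavy`.
#'
#' @slot patternData data.frame with columns `substructure_id`, `name`,
#'   `smiles`, `canonical_smiles`, `smarts`, `n_heavy`, `n_H_total`,
#'   `n_H_defined`, `n_H_variable`, `flexibility`.
#' @slot rejections data.frame with columns `row`, `substructure_id`, `reason`.
#' @slot metadata list of provenance information.
#'
#' @aliases patternIds patternSmarts flexibility
#' @export
setClass("PatternSet",
  representation(
    patternData = "data.frame",
    rejections  = "data.frame",
    metadata    = "list"
  )
)

setValidity("PatternSet", function(object) {
  df <- object@patternData
  required <- c("substructure_id", "smiles", "smarts", "n_heavy",
                "n_H_total", "n_H_defined", "n_H_variable", "flexibility")
  if (!all(required %in% names(df)))
    return(paste("patternData must contain columns:",
                 paste(required, collapse = ", ")))
  if (nrow(df) > 0) {
    dup <- df$substructure_id[duplicated(df$substructure_id)]
    if (length(dup))
      return(paste("duplicated substructure_id:",
                   paste(unique(dup), collapse = ", ")))
    if (any(df$n_H_defined > df$n_H_total))
      return("n_H_defined must not exceed n_H_total")
    if (any(df$n_H_variable < 0) || any(df$n_heavy < 1))
      return("n_H_variable must be >= 0 and n_heavy >= 1")
    if (any(abs(df$flexibility - df$n_H_variable / df$n_heavy) > 1e-12))
      return("flexibility must equal n_H_variable / n_heavy")
  }
  TRUE
})

#' @rdname PatternSet-class
#' @export
setMethod("patternIds", "PatternSet", function(x) x@patternData$substructure_id)

#' @rdname PatternSet-class
#' @export
setMethod("patternSmarts", "PatternSet", function(x) {
  stats::setNames(x@patternData$smarts, x@patternData$substructure_id)
})

#' @rdname PatternSet-class
#' @export
setMethod("flexibility", "PatternSet", function(x) {
  stats::setNames(x@patternData$flexibility, x@patternData$substructure_id)
})

#' @rdname PatternSet-class
#' @export
setMethod("rejections", "PatternSet", function(x) x@rejections)

#' @rdname PatternSet-class
#' @param object a `PatternSet`.
#' @export
setMethod("show", "PatternSet", function(object) {
  cat("PatternSet with", nrow(object@patternData), "compiled substructures",
      sprintf("(%d rejected)\n", nrow(object@rejections)))
  if (nrow(object@patternData)) {
    cat("  defined-H patterns:",
        sum(object@patternData$n_H_defined > 0), "\n")
    cat("  flexibility range:",
        paste(signif(range(object@patternData$flexibility), 3),
              collapse = " - "), "\n")
  }
})

#' @rdname PatternSet-class
#' @param x,i a `PatternSet` and an index or substructure identifiers.
#' @export
setMethod("[", "PatternSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@patternData$substructure_id)
  df <- x@patternData[i, , drop = FALSE]
  rownames(df) <- NULL
  new("PatternSet", patternData = df,
      rejections = x@rejections[0, , drop = FALSE], metadata = x@metadata)
})

#' @rdname PatternSet-class
#' @export
setMethod("as.data.frame", "PatternSet", function(x) x@patternData)

#' OccurrenceMatrix: compounds x substructures presence
#'
#' Boolean presence/absence matrix; a substructure matching a compound
#' several times still counts once. Rows are compounds, columns are
#' substructures.
#'
#' @slot presence logical matrix with compound ids as rownames and
#'   substructure ids as colnames.
#'
#' @aliases presence
#' @export
setClass("OccurrenceMatrix", representation(presence = "matrix"))

setValidity("OccurrenceMatrix", function(object) {
  m <- object@presence
  if (!is.logical(m)) return("presence must be a logical matrix")
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("presence must carry compound ids (rows) and substructure ids (cols)")
  if (anyNA(m)) return("presence must not contain NA")
  TRUE
})

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("presence", "OccurrenceMatrix", function(x) x@presence)

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("compoundIds", "OccurrenceMatrix", function(x) {
  rn <- rownames(x@presence)
  if (is.null(rn)) character(0) else rn
})

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("patternIds", "OccurrenceMatrix", function(x) {
  cn <- colnames(x@presence)
  if (is.null(cn)) character(0) else cn
})

#' @rdname OccurrenceMatrix-class
#' @param object an `OccurrenceMatrix`.
#' @export
setMethod("show", "OccurrenceMatrix", function(object) {
  m <- object@presence
  cat("OccurrenceMatrix:", nrow(m), "compounds x", ncol(m), "substructures\n")
  if (length(m))
    cat("  overall presence:", sprintf("%.1f%%", 100 * mean(m)), "\n")
})

#' @rdname OccurrenceMatrix-class
#' @param x an `OccurrenceMatrix`.
#' @param ... ignored.
#' @export
setMethod("dim", "OccurrenceMatrix", function(x) dim(x@presence))

#' ScreeningResult: scaffold-filtered, signature-scored library
#'
#' Result of screening a compound library: per-compound scaffold membership
#' and signature scores, per-scaffold hit counts from the filtering step,
#' and the deterministic ranked lists per (scaffold x tier-selection).
#'
#' @slot hits data.frame of scored screening hits (one row per compound that
#'   carries at least one basic scaffold).
#' @slot scaffoldCounts named integer vector of per-scaffold hit counts.
#' @slot nMultiScaffold number of compounds carrying two or more scaffolds.
#' @slot rankedLists named list of ranked data.frames
#'   (`<scaffold>.<selection>`).
#' @slot manifest list recording configuration and counts of the run.
#'
#' @aliases scaffoldCounts rankedLists screeningHits
#' @export
setClass("ScreeningResult",
  representation(
    hits           = "data.frame",
    scaffoldCounts = "integer",
    nMultiScaffold = "integer",
    rankedLists    = "list",
    manifest       = "list"
  )
)

#' @rdname ScreeningResult-class
#' @export
setMethod("screeningHits", "ScreeningResult", function(x) x@hits)

#' @rdname ScreeningResult-class
#' @export
setMethod("scaffoldCounts", "ScreeningResult", function(x) x@scaffoldCounts)

#' @rdname ScreeningResult-class
#' @export
setMethod("rankedLists", "ScreeningResult", function(x) x@rankedLists)

#' @rdname ScreeningResult-class
#' @param object a `ScreeningResult`.
#' @export
setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult:", nrow(object@hits), "scaffold-bearing hits\n")
  cat("  per-scaffold counts:",
      paste(names(object@scaffoldCounts), object@scaffoldCounts,
            sep = "=", collapse = ", "), "\n")
  cat("  multi-scaffold compounds:", object@nMultiScaffold, "\n")
  cat("  ranked lists:", length(object@rankedLists), "\n")
})
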