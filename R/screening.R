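## Virtual screening: scaffold-based library filtering, signature scoring
## (primary / secondary / combined tiers), deterministic ranked lists per
## scaffold, and a property-balanced shortlist helper standing in for the
## human selection step.

#' Filter a screening library by basic scaffolds
#'
#' Retains compounds matching at least one scaffold core and reports
#' per-scaffold hit counts plus the number of multi-scaffold compounds (a
#' molecule may carry two or more cores, and then appears in each of its
#' scaffolds' lists downstream).
#'
#' @param library a [CompoundSet-class].
#' @param scaffolds a [PatternSet-class] of scaffold queries, by default
#'   [defaultScaffolds()].
#' @return list with elements `hits` (data.frame: `compound_id`, `smiles`,
#'   `scaffolds` as `;`-separated names), `counts` (named integer per
#'   scaffold) and `n_multi` (compounds with two or more scaffolds).
#' @export
filterByScaffolds <- function(library, scaffolds = defaultScaffolds()) {
  stopifnot(is(library, "CompoundSet"))
  occ <- presence(occurrenceMatrix(library, scaffolds))
  counts <- stats::setNames(as.integer(colSums(occ)), colnames(occ))
  keep <- rowSums(occ) > 0
  hits <- data.frame(
    compound_id = compoundIds(library)[keep],
    smiles = unname(compoundSmiles(library))[keep],
    scaffolds = vapply(which(keep), function(i)
      paste(colnames(occ)[occ[i, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  list(hits = hits, counts = counts,
       n_multi = sum(rowSums(occ) > 1L))
}

## signature totals per substructure for a tier selection
.tierTotals <- function(signature, selection) {
  sel <- switch(selection,
                primary = signature$tier == "primary",
                secondary = signature$tier == "secondary",
                combined = rep(TRUE, nrow(signature)),
                stop("unknown selection: ", selection))
  stats::setNames(signature$total[sel], signature$substructure_id[sel])
}

#' Score molecules against a signature
#'
#' The score of a molecule is the sum of the signature totals of the
#' distinct substructures it contains within the selected tier(s);
#' multiplicity of embeddings is ignored.
#'
#' @param molecules a [CompoundSet-class] or character vector of SMILES.
#' @param patterns the [PatternSet-class] the signature was built from.
#' @param signature data.frame from [buildSignature()].
#' @param selection `"primary"`, `"secondary"` or `"combined"`.
#' @return data.frame with columns `compound_id`, `score`, `n_matched`,
#'   and `matched` (`;`-separated substructure ids).
#' @export
scoreCompounds <- function(molecules, patterns, signature,
                           selection = c("combined", "primary", "secondary")) {
  selection <- match.arg(selection)
  cs <- if (is(molecules, "CompoundSet")) molecules
        else CompoundSet(paste0("mol", seq_along(molecules)), molecules)
  occ <- presence(occurrenceMatrix(cs, patterns))
  totals <- .tierTotals(signature, selection)
  ids <- intersect(colnames(occ), names(totals))
  sub <- occ[, ids, drop = FALSE]
  data.frame(
    compound_id = rownames(sub),
    score = as.integer(sub %*% totals[ids]),
    n_matched = as.integer(rowSums(sub)),
    matched = apply(sub, 1L, function(r) paste(ids[r], collapse = ";")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Screen a library end to end
#'
#' Scaffold-filters the library, matches the surviving compounds against
#' the substructure catalog, scores them against the signature for each
#' requested tier selection, and produces deterministic ranked lists per
#' (scaffold x selection). Ties are broken by the number of distinct
#' matched primary substructures (more first), then molecular weight
#' (lower first), then compound id, so fixed inputs give byte-identical
#' lists regardless of input order.
#'
#' @param library a [CompoundSet-class].
#' @param patterns the substructure catalog as a [PatternSet-class].
#' @param signature data.frame from [buildSignature()].
#' @param scaffolds scaffold [PatternSet-class], default
#'   [defaultScaffolds()].
#' @param selections subset of `c("primary", "secondary", "combined")`.
#' @param topK optional truncation of each ranked list.
#' @return a [ScreeningResult-class].
#' @export
screenLibrary <- function(library, patterns, signature,
                          scaffolds = defaultScaffolds(),
                          selections = c("primary", "secondary", "combined"),
                          topK = NULL) {
  stopifnot(all(selections %in% c("primary", "secondary", "combined")))
  flt <- filterByScaffolds(library, scaffolds)
  if (nrow(flt$hits) == 0L) {
    warning("no compounds carry any of the basic scaffolds")
    return(new("ScreeningResult", hits = flt$hits[0, , drop = FALSE],
               scaffoldCounts = flt$counts, nMultiScaffold = 0L,
               rankedLists = list(),
               manifest = list(selections = selections,
                               n_library = nCompounds(library),
                               n_hits = 0L)))
  }
  hitSet <- library[flt$hits$compound_id]
  occ <- presence(occurrenceMatrix(hitSet, patterns))
  props <- computeProperties(hitSet)
  primTotals <- .tierTotals(signature, "primary")
  secTotals <- .tierTotals(signature, "secondary")
  inOcc <- function(tot) tot[intersect(colnames(occ), names(tot))]
  pT <- inOcc(primTotals); sT <- inOcc(secTotals)
  matchedIn <- function(r, ids) ids[r[ids]]
  hits <- flt$hits
  hits$matched_primary <- apply(occ, 1L, function(r)
    paste(matchedIn(r, names(pT)), collapse = ";"))
  hits$matched_secondary <- apply(occ, 1L, function(r)
    paste(matchedIn(r, names(sT)), collapse = ";"))
  hits$n_matched_primary <- as.integer(rowSums(occ[, names(pT), drop = FALSE]))
  hits$n_matched_secondary <- as.integer(rowSums(occ[, names(sT), drop = FALSE]))
  hits$score_primary <- as.integer(occ[, names(pT), drop = FALSE] %*% pT)
  hits$score_secondary <- as.integer(occ[, names(sT), drop = FALSE] %*% sT)
  hits$score_combined <- hits$score_primary + hits$score_secondary
  hits$mw <- props$mw[match(hits$compound_id, props$compound_id)]
  hits$clogp <- props$clogp[match(hits$compound_id, props$compound_id)]
  rownames(hits) <- NULL
  lists <- generateRankedLists(hits, selections = selections, topK = topK)
  new("ScreeningResult",
      hits = hits,
      scaffoldCounts = flt$counts,
      nMultiScaffold = as.integer(flt$n_multi),
      rankedLists = lists,
      manifest = list(
        selections = selections,
        n_library = nCompounds(library),
        n_hits = nrow(hits),
        scaffold_counts = as.list(flt$counts),
        n_multi_scaffold = as.integer(flt$n_multi),
        descriptor_provider = attr(props, "descriptor_provider"),
        topK = topK
      ))
}

#' Generate deterministic ranked lists per scaffold and tier selection
#'
#' @param hits scored hit data.frame as produced inside [screenLibrary()].
#' @param selections tier selections to rank by.
#' @param perScaffold split lists by scaffold (a multi-scaffold compound
#'   appears in each of its scaffolds' lists); `FALSE` gives one global
#'   list per selection.
#' @param topK optional truncation (the top-k list is always a prefix of
#'   the full list).
#' @return named list of data.frames (`<scaffold>.<selection>` or
#'   `all.<selection>`), each carrying a `score` column for the selected
#'   tier and ordered by the screening tie-breaks.
#' @export
generateRankedLists <- function(hits,
                                selections = c("primary", "secondary",
                                               "combined"),
                                perScaffold = TRUE, topK = NULL) {
  scaffoldsOf <- strsplit(hits$scaffolds, ";", fixed = TRUE)
  groups <- if (perScaffold) sort(unique(unlist(scaffoldsOf))) else "all"
  lists <- list()
  for (g in groups) {
    inG <- if (identical(g, "all")) rep(TRUE, nrow(hits))
           else vapply(scaffoldsOf, function(s) g %in% s, logical(1))
    for (sel in selections) {
      df <- hits[inG, , drop = FALSE]
      df$score <- df[[paste0("score_", sel)]]
      ord <- order(-df$score, -df$n_matched_primary, df$mw, df$compound_id)
      df <- df[ord, , drop = FALSE]
      if (!is.null(topK)) df <- utils::head(df, topK)
      rownames(df) <- NULL
      lists[[paste(g, sel, sep = ".")]] <- df
    }
  }
  lists
}

#' Property-balanced shortlist
#'
#' Greedy round-robin over the 2D (CLogP bin x MW bin) grid: cells are
#' visited in a fixed order and the highest-scoring unused candidate of
#' each occupied cell is taken until `k` compounds are selected - a
#' deterministic stand-in for shortlisting "balanced" candidates by
#' lipophilicity and molecular weight.
#'
#' @param candidates data.frame with columns `compound_id`, `score`,
#'   `clogp`, `mw` (e.g. a ranked list from [rankedLists()]).
#' @param k number of compounds to select; if `k` is at least the number
#'   of candidates, all are returned.
#' @param clogp_bins,mw_bins numeric break vectors defining the grid
#'   (values outside the range fall into the outermost bins).
#' @return data.frame of the selected rows, in selection order, with a
#'   `cell` column naming the grid cell.
#' @export
shortlistBalanced <- function(candidates, k,
                              clogp_bins = seq(-2, 8, by = 2),
                              mw_bins = seq(100, 700, by = 100)) {
  if (nrow(candidates) == 0L || k <= 0L)
    return(cbind(candidates[0, , drop = FALSE],
                 data.frame(cell = character(0))))
  binOf <- function(v, breaks) {
    pmin(pmax(findInterval(v, breaks), 1L), length(breaks) - 1L)
  }
  cb <- binOf(candidates$clogp, clogp_bins)
  mb <- binOf(candidates$mw, mw_bins)
  cell <- sprintf("clogp%02d.mw%02d", cb, mb)
  used <- rep(FALSE, nrow(candidates))
  cells <- sort(unique(cell))
  picked <- integer(0)
  while (length(picked) < min(k, nrow(candidates))) {
    took <- FALSE
    for (cl in cells) {
      if (length(picked) >= k) break
      avail <- which(!used & cell == cl)
      if (length(avail) == 0L) next
      best <- avail[order(-candidates$score[avail],
                          candidates$compound_id[avail])][1L]
      used[best] <- TRUE
      picked <- c(picked, best)
      took <- TRUE
    }
    if (!took) break
  }
  out <- candidates[picked, , drop = FALSE]
  out$cell <- cell[picked]
  rownames(out) <- NULL
  out
}
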