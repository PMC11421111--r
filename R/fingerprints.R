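## The four fingerprint value tables derived from the occurrence matrix,
## the chemical-class labels, and the pattern flexibility:
##   I  (f1): fraction of compounds containing the substructure;
##   II (f2): fraction of chemical classes containing it (a class contains
##            a substructure iff at least one member matches);
##   III(q3): f1 / flexibility;
##   IV (q4): f2 / flexibility.
## Fractions are stored on the 0-1 scale throughout; formatting to percent
## happens only at I/O. Dividing by the average flexibility rewards
## structurally specific patterns (many defined hydrogens, low flexibility)
## over permissive ones.

#' Fraction of compounds containing each substructure (fingerprint I)
#'
#' @param occurrence an [OccurrenceMatrix-class] with at least one compound.
#' @return named numeric vector `f1` in `[0, 1]` per substructure.
#' @export
fractionOccurrence <- function(occurrence) {
  m <- presence(occurrence)
  if (nrow(m) == 0L) stop("occurrence matrix has no compounds")
  colSums(m) / nrow(m)
}

#' Fraction of chemical classes containing each substructure (fingerprint II)
#'
#' A substructure occurs in a class iff at least one member of the class
#' matches it; `f2` is the number of such classes over the total number of
#' classes. The denominators of `f1` and `f2` are independent, so neither
#' bounds the other.
#'
#' @param occurrence an [OccurrenceMatrix-class].
#' @param classes named character vector mapping compound ids to class
#'   labels (e.g. [chemClasses()]); every compound in the matrix must be
#'   labelled.
#' @return named numeric vector `f2` in `[0, 1]` per substructure.
#' @export
classOccurrence <- function(occurrence, classes) {
  m <- presence(occurrence)
  ids <- rownames(m)
  lab <- classes[ids]
  if (anyNA(lab) || any(!nzchar(lab)))
    stop("missing class label for compound(s): ",
         paste(ids[is.na(lab) | !nzchar(lab)], collapse = ", "))
  classList <- unique(lab)
  if (length(classList) == 0L) stop("at least one class is required")
  hitClasses <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(lab[m[, j]]))
  }, integer(1))
  stats::setNames(hitClasses / length(classList), colnames(m))
}

#' Flexibility quotients (fingerprints III and IV)
#'
#' Divides a fraction value by the pattern's average flexibility
#' (substitutable hydrogens per heavy atom). A flexibility of zero (all
#' hydrogens defined) yields `NA` - the quotient is undefined, and the
#' signature falls back to the thresholded fraction scores for such
#' patterns.
#'
#' @param fraction numeric vector (`f1` or `f2`).
#' @param flexibility numeric vector of average flexibilities, recycled.
#' @return numeric vector of quotients, `NA` where flexibility is zero.
#' @export
#' @examples
#' flexibilityQuotients(0.402, 0.714)  # ~0.563
flexibilityQuotients <- function(fraction, flexibility) {
  stopifnot(all(fraction >= 0, na.rm = TRUE),
            all(flexibility >= 0, na.rm = TRUE))
  ifelse(flexibility > 0, fraction / flexibility, NA_real_)
}

#' Build the full fingerprint table
#'
#' One row per substructure with hit counts, the four fingerprint values
#' and the hydrogen accounting, mirroring the layout of a substructure
#' catalog's analysis sheet.
#'
#' @param occurrence an [OccurrenceMatrix-class] (compounds x patterns).
#' @param patterns the [PatternSet-class] the matrix was computed from.
#' @param classes named character vector of class labels per compound id;
#'   required for fingerprints II/IV (pass `NULL` to skip them).
#' @return data.frame with columns `substructure_id`, `name`, `smiles`,
#'   `n_hits`, `f1`, `n_class_hits`, `f2`, `n_H_total`, `n_H_defined`,
#'   `n_H_variable`, `n_heavy`, `flexibility`, `q3`, `q4`.
#' @export
fingerprintTable <- function(occurrence, patterns, classes = NULL) {
  stopifnot(is(occurrence, "OccurrenceMatrix"), is(patterns, "PatternSet"))
  pd <- patterns@patternData
  if (!identical(colnames(presence(occurrence)), pd$substructure_id))
    stop("occurrence matrix and pattern set disagree on substructures")
  m <- presence(occurrence)
  f1 <- fractionOccurrence(occurrence)
  if (!is.null(classes)) {
    f2 <- classOccurrence(occurrence, classes)
    lab <- classes[rownames(m)]
    nClassHits <- vapply(seq_len(ncol(m)), function(j)
      length(unique(lab[m[, j]])), integer(1))
  } else {
    f2 <- rep(NA_real_, ncol(m))
    nClassHits <- rep(NA_integer_, ncol(m))
  }
  data.frame(
    substructure_id = pd$substructure_id,
    name = pd$name,
    smiles = pd$smiles,
    n_hits = as.integer(colSums(m)),
    f1 = as.numeric(f1),
    n_class_hits = as.integer(nClassHits),
    f2 = as.numeric(f2),
    n_H_total = pd$n_H_total,
    n_H_defined = pd$n_H_defined,
    n_H_variable = pd$n_H_variable,
    n_heavy = pd$n_heavy,
    flexibility = pd$flexibility,
    q3 = flexibilityQuotients(as.numeric(f1), pd$flexibility),
    q4 = ifelse(rep(is.null(classes), nrow(pd)), NA_real_,
                flexibilityQuotients(as.numeric(f2), pd$flexibility)),
    stringsAsFactors = FALSE
  )
}
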