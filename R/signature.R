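## Signature scoring: fingerprint values are binned into 10-0 scores, the
## fraction fingerprints (I/II) are subjected to a 20%-presence threshold
## with a gap-filling exception driven by the quotient fingerprints
## (III/IV), the four scores are summed to a total (0-40), and each
## substructure is classified as a primary or secondary positive
## substructure.

#' Default score bin edges
#'
#' Lower edges of the score bins 1..10: values at or above 0.90 score 10,
#' `[0.80, 0.90)` scores 9, ..., `[0.01, 0.10)` scores 1 and anything below
#' 0.01 scores 0. Bins are inclusive at the lower edge and open at the top
#' (the largest quotient observed in a catalog is not a cap), tiling
#' `[0, Inf)` without gaps.
#'
#' @return increasing numeric vector of length 10.
#' @export
defaultBinEdges <- function() {
  c(0.01, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90)
}

#' Bin a fingerprint value into a 0-10 score
#'
#' Piecewise-constant, monotone non-decreasing mapping from non-negative
#' fingerprint values (fractions or flexibility quotients) to integer
#' scores: the score is the number of bin edges at or below the value.
#'
#' @param value numeric vector of non-negative fingerprint values.
#' @param edges increasing numeric vector of lower bin edges, by default
#'   [defaultBinEdges()].
#' @return integer vector of scores in `0:length(edges)`.
#' @export
#' @examples
#' binScore(c(0.95, 0.55, 0.005, 0.20))  # 10, 6, 0, 3
binScore <- function(value, edges = defaultBinEdges()) {
  stopifnot(!is.unsorted(edges, strictly = TRUE))
  if (any(value < 0, na.rm = TRUE))
    stop("fingerprint values must be non-negative")
  as.integer(findInterval(value, edges))
}

#' Apply the presence threshold and the gap-filling rule
#'
#' The fraction scores s1/s2 count only when the substructure is present in
#' at least `presence` (20%) of the compounds/classes; below that the score
#' is zeroed. However, when the paired quotient fingerprint scores above 2
#' (s3 >= 3 for s1, s4 >= 3 for s2) and the zeroed raw score was 1 or 2,
#' that raw score is restored ("gap filling"), promoting structurally
#' specific alternative substructures. Quotient scores are never
#' thresholded.
#'
#' @param s1_raw,s2_raw integer raw bin scores of f1 and f2.
#' @param s3,s4 integer bin scores of the quotient fingerprints.
#' @param f1,f2 the underlying fraction values.
#' @param presence inclusive presence threshold (default 0.20).
#' @return list with integer vectors `s1` and `s2`.
#' @export
thresholdAndFill <- function(s1_raw, s2_raw, s3, s4, f1, f2,
                             presence = 0.20) {
  fill <- function(raw, frac, quot) {
    out <- ifelse(!is.na(frac) & frac >= presence, raw, 0L)
    gap <- !is.na(frac) & frac < presence & raw >= 1L & raw <= 2L &
      !is.na(quot) & quot >= 3L
    out[gap] <- raw[gap]
    as.integer(out)
  }
  list(s1 = fill(s1_raw, f1, s3), s2 = fill(s2_raw, f2, s4))
}

#' Classify a substructure into the primary or secondary positive tier
#'
#' Primary positive substructures fulfil either criterion: (i) occurrence
#' in fingerprint I and/or II of at least 20%; or (ii) a flexibility
#' quotient (fingerprint III and/or IV) of at least 0.2 together with an
#' occurrence in fingerprint I and/or II of at least 10%. Everything else
#' is a secondary positive substructure. Undefined quotients (flexibility
#' zero) fail criterion (ii).
#'
#' @param f1,f2 fraction values (0-1); `f2` may be `NA`.
#' @param q3,q4 flexibility quotients; `NA` where undefined.
#' @param presence criterion (i) threshold on the fractions (default 0.20).
#' @param quotient criterion (ii) threshold on the quotients (default 0.2).
#' @param occurrence criterion (ii) threshold on the fractions (default 0.10).
#' @return character vector, `"primary"` or `"secondary"`.
#' @export
#' @examples
#' classifyTier(f1 = 0.12, f2 = 0, q3 = 0.30, q4 = 0)  # "primary"
classifyTier <- function(f1, f2, q3, q4, presence = 0.20, quotient = 0.2,
                         occurrence = 0.10) {
  n <- max(length(f1), length(f2), length(q3), length(q4))
  f1 <- rep_len(as.numeric(f1), n); f2 <- rep_len(as.numeric(f2), n)
  q3 <- rep_len(as.numeric(q3), n); q4 <- rep_len(as.numeric(q4), n)
  maxNA <- function(a, b) pmax(ifelse(is.na(a), -Inf, a),
                               ifelse(is.na(b), -Inf, b))
  fMax <- maxNA(f1, f2)
  qMax <- maxNA(q3, q4)
  ifelse(fMax >= presence | (qMax >= quotient & fMax >= occurrence),
         "primary", "secondary")
}

#' Build the signature table from a fingerprint table
#'
#' Scores every substructure on the four fingerprints (with thresholding
#' and gap filling), sums them to the total score (0-40), classifies the
#' tier, and orders the result by total score descending with deterministic
#' tie-breaks (higher s1, then higher s3, then substructure id). Patterns
#' with flexibility zero have undefined quotients; their s3/s4 fall back to
#' the thresholded s1/s2.
#'
#' @param fingerprints data.frame from [fingerprintTable()].
#' @param edges score bin edges, by default [defaultBinEdges()].
#' @param presence,quotient,occurrence tier/threshold parameters, see
#'   [classifyTier()] and [thresholdAndFill()].
#' @return data.frame with columns `substructure_id`, `name`, `smiles`,
#'   `f1`, `f2`, `flexibility`, `q3`, `q4`, `s1`..`s4`, `total`, `tier`.
#' @export
buildSignature <- function(fingerprints, edges = defaultBinEdges(),
                           presence = 0.20, quotient = 0.2,
                           occurrence = 0.10) {
  fp <- fingerprints
  if (nrow(fp) == 0L) stop("empty fingerprint table")
  f2 <- if (all(is.na(fp$f2))) rep(0, nrow(fp)) else fp$f2
  s1raw <- binScore(fp$f1, edges)
  s2raw <- binScore(f2, edges)
  s1thr <- ifelse(fp$f1 >= presence, s1raw, 0L)
  s2thr <- ifelse(f2 >= presence, s2raw, 0L)
  s3 <- ifelse(is.na(fp$q3), s1thr, binScore(ifelse(is.na(fp$q3), 0, fp$q3),
                                             edges))
  s4 <- ifelse(is.na(fp$q4), s2thr, binScore(ifelse(is.na(fp$q4), 0, fp$q4),
                                             edges))
  ss <- thresholdAndFill(s1raw, s2raw, s3, s4, fp$f1, f2, presence)
  out <- data.frame(
    substructure_id = fp$substructure_id,
    name = fp$name,
    smiles = fp$smiles,
    f1 = fp$f1,
    f2 = fp$f2,
    flexibility = fp$flexibility,
    q3 = fp$q3,
    q4 = fp$q4,
    s1 = as.integer(ss$s1),
    s2 = as.integer(ss$s2),
    s3 = as.integer(s3),
    s4 = as.integer(s4),
    stringsAsFactors = FALSE
  )
  out$total <- out$s1 + out$s2 + out$s3 + out$s4
  out$tier <- classifyTier(fp$f1, fp$f2, fp$q3, fp$q4,
                           presence, quotient, occurrence)
  ord <- order(-out$total, -out$s1, -out$s3, out$substructure_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
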