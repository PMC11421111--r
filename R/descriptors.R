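## Physicochemical / molecular-structural descriptors and dataset-level
## validation summaries. Descriptor provider is OpenBabel throughout;
## molecular weight and the simple counts are implementation-independent,
## logP / molar refractivity / H-bond acceptor definitions are provider
## specific and every output carries a descriptor_provider tag.

## standard rotatable-bond definition: non-ring single bond between two
## non-terminal atoms not involved in a triple bond; SMARTS matches each
## bond twice (once per direction)
.ROTOR_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"

#' Compute physicochemical properties per compound
#'
#' Computes CLogP, molecular weight (g/mol), molar refractivity, TPSA
#' (A^2), H-bond donor/acceptor counts, rotatable bonds and heavy-atom
#' counts from the parsed molecules. Calculated solubility (CLogS) is not
#' offered by the OpenBabel provider and is reported as `NA`. Molecules are
#' used exactly as given (no charge normalisation), so e.g. a zwitterion
#' and its neutral form give different CLogP.
#'
#' @param x a [CompoundSet-class] or character vector of SMILES.
#' @return data.frame with one row per compound and columns `compound_id`,
#'   `clogp`, `clogs`, `mw`, `mr`, `tpsa`, `n_hbd`, `n_hba`, `n_rotb`,
#'   `n_heavy`, plus a `descriptor_provider` attribute.
#' @export
#' @examples
#' computeProperties("c1ccccc1")[, c("mw", "n_rotb", "n_hbd")]
computeProperties <- function(x) {
  cs <- if (is(x, "CompoundSet")) x
        else CompoundSet(if (is.null(names(x))) paste0("mol", seq_along(x))
                         else names(x), x)
  mols <- .molsOf(cs)
  if (length(mols) == 0L) {
    out <- data.frame(compound_id = character(0), clogp = numeric(0),
                      clogs = numeric(0), mw = numeric(0), mr = numeric(0),
                      tpsa = numeric(0), n_hbd = integer(0),
                      n_hba = integer(0), n_rotb = integer(0),
                      n_heavy = integer(0))
    attr(out, "descriptor_provider") <- "openbabel"
    return(out)
  }
  pr <- ChemmineOB::prop_OB(mols)
  nHeavy <- vapply(pr$formula, function(f) {
    counts <- .parseFormula(f)
    as.integer(sum(counts[names(counts) != "H"]))
  }, integer(1), USE.NAMES = FALSE)
  nRot <- .smartsCount(mols, .ROTOR_SMARTS, uniqueMatches = FALSE) %/% 2L
  out <- data.frame(
    compound_id = compoundIds(cs),
    clogp = pr$logP,
    clogs = NA_real_,
    mw = pr$MW,
    mr = pr$MR,
    tpsa = pr$TPSA,
    n_hbd = as.integer(pr$HBD),
    n_hba = as.integer(pr$HBA2),
    n_rotb = as.integer(nRot),
    n_heavy = nHeavy,
    stringsAsFactors = FALSE
  )
  attr(out, "descriptor_provider") <- "openbabel"
  out
}

#' Summarise a dataset's property distributions
#'
#' Median and arithmetic mean per property over the accepted records, plus
#' histograms (bin edges and counts). The median convention defaults to the
#' mean-of-middle-two for even n; `median = "lower"` selects the
#' lower-middle value instead.
#'
#' @param properties data.frame from [computeProperties()] (or any
#'   data.frame of numeric property columns).
#' @param median `"midmean"` (mean of the two middle values) or `"lower"`.
#' @param breaks histogram bin specification passed to [graphics::hist()].
#' @return list with elements `summary` (data.frame: property, median,
#'   mean, n), `histograms` (named list of `breaks`/`counts`), `n`, and
#'   `descriptor_provider`.
#' @export
summarizeDataset <- function(properties, median = c("midmean", "lower"),
                             breaks = 10) {
  median <- match.arg(median)
  num <- properties[, vapply(properties, is.numeric, logical(1)), drop = FALSE]
  num <- num[, colSums(!is.na(num)) > 0, drop = FALSE]
  med <- function(v) {
    v <- sort(v[!is.na(v)])
    n <- length(v)
    if (n == 0L) return(NA_real_)
    if (median == "midmean") stats::median(v)
    else v[ceiling(n / 2)]
  }
  summary <- data.frame(
    property = names(num),
    median = vapply(num, med, numeric(1), USE.NAMES = FALSE),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1),
                  USE.NAMES = FALSE),
    n = vapply(num, function(v) sum(!is.na(v)), integer(1),
               USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  histograms <- lapply(num, function(v) {
    h <- graphics::hist(v[!is.na(v)], breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  })
  list(summary = summary, histograms = histograms, n = nrow(properties),
       descriptor_provider = attr(properties, "descriptor_provider"))
}

#' Chemical-class composition of a compound set
#'
#' Per-class compound counts and percentages, the standard sanity check on
#' the class balance of a curated bioactivity dataset.
#'
#' @param x a [CompoundSet-class] or a character vector of class labels.
#' @return data.frame with columns `chem_class`, `n`, `fraction`,
#'   `percent`, sorted by decreasing size.
#' @export
classComposition <- function(x) {
  classes <- if (is(x, "CompoundSet")) chemClasses(x) else as.character(x)
  if (anyNA(classes))
    stop("missing class label for compound(s): ",
         paste(names(classes)[is.na(classes)], collapse = ", "))
  tab <- sort(table(classes), decreasing = TRUE)
  data.frame(
    chem_class = names(tab),
    n = as.integer(tab),
    fraction = as.numeric(tab) / sum(tab),
    percent = 100 * as.numeric(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
}
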