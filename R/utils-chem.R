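## Low-level molecule utilities shared across modules.
##
## All SMILES parsing, canonicalisation and SMARTS matching go through
## OpenBabel (via ChemmineOB), so patterns and targets see one and the same
## aromaticity perception model.

#' Canonicalise SMILES strings
#'
#' Round-trips each SMILES through OpenBabel's canonical SMILES writer.
#' Invalid strings yield `NA_character_` rather than an error, which the
#' readers use as their validity probe.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparseable.
#' @export
#' @examples
#' canonicalSmiles(c("C1=CC=CC=C1", "not-a-smiles"))
canonicalSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- sub("[ \t\r\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

## Persistent OpenBabel molecule references for a SMILES vector.
## One conversion, reusable across many SMARTS queries (orders of magnitude
## faster than re-converting an SDFset per query).
.obMols <- function(smiles) {
  smiles <- as.character(smiles)
  if (length(smiles) == 0L) return(list())
  stopifnot(!anyNA(smiles))
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

## Count of matches of one SMARTS against a list of OBMol refs.
.smartsCount <- function(mols, smarts, uniqueMatches = TRUE) {
  if (length(mols) == 0L) return(integer(0))
  as.integer(ChemmineOB::smartsSearch_OB(mols, smarts,
                                         uniqueMatches = uniqueMatches))
}

## Parse a Hill-style molecular formula ("C6H6O", "C2H3O2-") into element
## counts. Charge suffixes are dropped.
.parseFormula <- function(formula) {
  f <- gsub("[+-]+[0-9]*", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  stats::setNames(counts, elems)
}

## Hydrogen / heavy-atom accounting for a molecule SMILES (explicit [H]
## included in the hydrogen total via the molecular formula).
.hydrogenAccounting <- function(smiles) {
  mol <- .obMols(smiles)
  pr <- ChemmineOB::prop_OB(mol)
  counts <- .parseFormula(pr$formula[1])
  nH <- if ("H" %in% names(counts)) sum(counts[names(counts) == "H"]) else 0L
  nHeavy <- sum(counts[names(counts) != "H"])
  list(n_H_total = as.integer(nH), n_heavy = as.integer(nHeavy))
}

## Valence sanity probes: OpenBabel accepts some hypervalent neutral atoms
## ("unusual valence") when parsing assembled SMILES; the synthetic
## generator rejects such candidates. Neutral O must be v1/v2, neutral N
## v3, neutral C v4 (aromatic atoms report their total bond-order valence).
.VALENCE_PROBES <- c("[#8;!v1;!v2;+0]", "[#7;!v3;+0]", "[#6;!v4;+0]")

.validValences <- function(smiles) {
  mols <- .obMols(smiles)
  ok <- rep(TRUE, length(smiles))
  for (p in .VALENCE_PROBES)
    ok <- ok & (.smartsCount(mols, p) == 0L)
  ok
}

## ---------------------------------------------------------------------------
## SMILES tokenizer and defined-hydrogen SMARTS rewrite
## ---------------------------------------------------------------------------

## Token types: atom (bracket or organic subset), bond, ring, open, close, dot.
.tokenizeSmiles <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  tokens <- character(0)
  types <- character(0)
  i <- 1L
  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I",
                "b", "c", "n", "o", "p", "s", "*")
  bondch <- c("-", "=", "#", "$", ":", "/", "\\", "~")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", s)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      types <- c(types, "atom")
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% organic2) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L])); types <- c(types, "atom")
      i <- i + 2L
    } else if (ch %in% organic1) {
      tokens <- c(tokens, ch); types <- c(types, "atom")
      i <- i + 1L
    } else if (ch == "%") {
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      types <- c(types, "ring")
      i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      tokens <- c(tokens, ch); types <- c(types, "ring")
      i <- i + 1L
    } else if (ch %in% bondch) {
      tokens <- c(tokens, ch); types <- c(types, "bond")
      i <- i + 1L
    } else if (ch == "(") {
      tokens <- c(tokens, ch); types <- c(types, "open"); i <- i + 1L
    } else if (ch == ")") {
      tokens <- c(tokens, ch); types <- c(types, "close"); i <- i + 1L
    } else if (ch == ".") {
      tokens <- c(tokens, ch); types <- c(types, "dot"); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  data.frame(token = tokens, type = types, stringsAsFactors = FALSE)
}

## Rewrite a canonical SMILES in which defined hydrogens are protected as
## [3H] markers into a SMARTS: each marker becomes a minimum-hydrogen-count
## constraint (!H0, !H0;!H1, ...) on the heavy atom it is bonded to, and the
## marker atom itself is removed. All other atoms pass through unchanged, so
## aromatic/aliphatic case, charges and isotopes match exactly as written.
.definedHSmarts <- function(canonical) {
  tk <- .tokenizeSmiles(canonical)
  nt <- nrow(tk)
  atomIdx <- which(tk$type == "atom")
  isH <- tk$token[atomIdx] == "[3H]"

  ## attachment walk: attachedTo[k] = atom index (into atomIdx) the k-th atom
  ## was bonded to when first written, NA for chain/component starts.
  attachedTo <- rep(NA_integer_, length(atomIdx))
  prev <- NA_integer_
  stack <- integer(0)
  acount <- 0L
  for (i in seq_len(nt)) {
    ty <- tk$type[i]
    if (ty == "atom") {
      acount <- acount + 1L
      attachedTo[acount] <- prev
      prev <- acount
    } else if (ty == "open") {
      stack <- c(stack, prev)
    } else if (ty == "close") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ty == "dot") {
      prev <- NA_integer_
    }
  }

  ## resolve the heavy partner of every [3H]
  minH <- integer(length(atomIdx))
  for (k in which(isH)) {
    partner <- attachedTo[k]
    if (is.na(partner)) {
      nxt <- which(attachedTo == k)       # leading [3H]: bonded to next atom
      if (length(nxt) != 1L)
        stop("cannot resolve attachment of defined hydrogen in: ", canonical)
      partner <- nxt
    }
    if (isH[partner])
      stop("defined hydrogen bonded to another hydrogen in: ", canonical)
    minH[partner] <- minH[partner] + 1L
  }

  ## rewrite heavy atoms carrying constraints
  keep <- rep(TRUE, nt)
  for (k in seq_along(atomIdx)) {
    if (isH[k] || minH[k] == 0L) next
    constraint <- paste0("!H", seq_len(minH[k]) - 1L, collapse = ";")
    tok <- tk$token[atomIdx[k]]
    tk$token[atomIdx[k]] <- if (startsWith(tok, "[")) {
      sub("\\]$", paste0(";", constraint, "]"), tok)
    } else {
      paste0("[", tok, ";", constraint, "]")
    }
  }

  ## drop the [3H] atoms (plus enclosing empty branch / adjacent bond token)
  for (k in which(isH)) {
    i <- atomIdx[k]
    keep[i] <- FALSE
    lead <- is.na(attachedTo[k])
    if (lead) {
      if (i < nt && tk$type[i + 1L] == "bond") keep[i + 1L] <- FALSE
      next
    }
    if (i > 1L && tk$type[i - 1L] == "bond") keep[i - 1L] <- FALSE
    j <- i - 1L
    if (j >= 1L && !keep[j]) j <- j - 1L    # skip removed bond token
    if (j >= 1L && i < nt && tk$type[j] == "open" && tk$type[i + 1L] == "close") {
      keep[j] <- FALSE
      keep[i + 1L] <- FALSE
    }
  }
  paste(tk$token[keep], collapse = "")
}
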