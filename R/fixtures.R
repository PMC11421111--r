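## Synthetic data with known ground truth: compound sets with substructures
## planted at controlled frequencies and class structure, and screening
## libraries with a known scaffold mix plus scaffold-free decoys. The
## generator is the test bed for every downstream stage - molecules are
## valence-valid but make no attempt at drug-likeness; hosts and decoy
## decorations are purely aliphatic so that planted (aromatic or
## heteroatom-bearing) patterns cannot arise by accident, and every set is
## verified against the matcher before it is returned.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Class-size profile of the curated activation dataset
#'
#' The published ABCC1 activation-focused dataset comprises 174 compounds
#' in 18 chemical classes: 70 flavonoids, 31 verapamil analogs, 18 GSH
#' analogs, 18 xanthones, 12 phenothiazines, 6 pyrrolopyrimidines, 4
#' purines, and 15 further compounds spread over 11 minor classes. The
#' synthetic generator uses this profile as its default study shape.
#'
#' @return named integer vector of class sizes summing to 174.
#' @export
defaultClassProfile <- function() {
  c(flavonoid = 70L, verapamil_analog = 31L, gsh_analog = 18L,
    xanthone = 18L, phenothiazine = 12L, pyrrolopyrimidine = 6L,
    purine = 4L,
    minor01 = 2L, minor02 = 2L, minor03 = 2L, minor04 = 2L,
    minor05 = 1L, minor06 = 1L, minor07 = 1L, minor08 = 1L,
    minor09 = 1L, minor10 = 1L, minor11 = 1L)
}

#' Specify a synthetic compound set
#'
#' @param n_compounds total number of molecules.
#' @param classes named integer vector of class sizes; must sum to
#'   `n_compounds`.
#' @param planted list of planting instructions, each a list with elements
#'   `smiles` (the substructure to plant), `frequency` (target fraction in
#'   `[0, 1]`; the pattern ends up in exactly `round(frequency *
#'   n_compounds)` molecules) and optional `classes` (restrict carriers to
#'   these classes).
#' @param scaffold_mix optional named integer vector passed through to
#'   [generateLibrary()] workflows.
#' @param seed integer; fully determines the generated set.
#' @return a validated `fixture_spec` list.
#' @export
fixtureSpec <- function(n_compounds, classes, planted = list(),
                        scaffold_mix = NULL, seed = 1L) {
  stopifnot(is.numeric(n_compounds), n_compounds >= 0)
  if (sum(classes) != n_compounds)
    stop("class sizes must sum to n_compounds (", sum(classes), " != ",
         n_compounds, ")")
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("classes must be a named vector")
  for (p in planted) {
    if (is.null(p$smiles) || is.null(p$frequency))
      stop("each planted entry needs 'smiles' and 'frequency'")
    if (p$frequency < 0 || p$frequency > 1)
      stop("planted frequencies must lie in [0, 1]")
    if (!is.null(p$classes) && !all(p$classes %in% names(classes)))
      stop("planted class restriction names unknown class")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 classes = classes, planted = planted,
                 scaffold_mix = scaffold_mix, seed = as.integer(seed)),
            class = "fixture_spec")
}

## aliphatic-only building blocks: cannot contain aromatic rings or
## heteroatoms, hence cannot collide with typical planted patterns
.HOST_LENGTHS <- 3:6
.DECOY_BRANCHES <- c("C", "CC", "C(C)C", "CCC")

## attach a fragment SMILES to a host chain; returns NA if no valence-valid
## attachment exists
.attachForms <- function(fragment, nBranchSlots = 1L) {
  list(
    branch = function(host, pos) {
      ## insert "(fragment)" after the pos-th chain carbon
      paste0(substr(host, 1, pos), "(", fragment, ")",
             substr(host, pos + 1L, nchar(host)))
    },
    tail = function(host, pos) paste0(fragment, host),
    alone = function(host, pos) fragment
  )
}

#' Generate a synthetic compound set with planted ground truth
#'
#' Builds `n_compounds` molecules from aliphatic host chains, planting each
#' requested substructure into exactly `round(frequency * n_compounds)`
#' molecules (optionally restricted to classes). Before generation, every
#' planted pattern is checked against the bare hosts and against the other
#' patterns' carrier fragments; a pattern that would arise where it was not
#' planted makes the fixture infeasible and is an error. After assembly the
#' whole set is verified with the matcher: planted occurrences must be
#' found, and accidental extra matches are counted and reported (zero by
#' construction for feasible specs).
#'
#' @param spec a [fixtureSpec()].
#' @return list with elements `compounds` (a [CompoundSet-class] whose
#'   `chem_class` column follows the requested profile), `patterns` (the compiled
#'   planted patterns), `truth` (logical ground-truth occurrence matrix),
#'   `occurrence` (the matcher's [OccurrenceMatrix-class]) and
#'   `n_accidental` (extra matches beyond the ground truth).
#' @export
generateCompoundSet <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_compounds
  classes <- rep(names(spec$classes), spec$classes)
  ids <- sprintf("SYN_%04d", seq_len(n))
  k <- length(spec$planted)
  pat <- if (k) compileCatalog(paste0("P", seq_len(k)),
                               vapply(spec$planted, `[[`, character(1),
                                      "smiles"),
                               strict = TRUE)
         else NULL

  ## feasibility: no pattern may match a bare aliphatic host ...
  hosts <- vapply(.HOST_LENGTHS, function(L)
    paste(rep("C", L), collapse = ""), character(1))
  if (k) {
    for (j in seq_len(k)) {
      if (any(matchesPattern(pat[j], hosts)))
        stop("infeasible spec: planted pattern ", patternIds(pat)[j],
             " matches an undecorated host molecule")
    }
    ## ... and no pattern may be implied by another pattern's fragment
    for (j in seq_len(k)) {
      carrier <- paste0("CC(", spec$planted[[j]]$smiles, ")C")
      if (is.na(canonicalSmiles(carrier)))
        carrier <- paste0(spec$planted[[j]]$smiles, "CC")
      if (is.na(canonicalSmiles(carrier)))
        carrier <- spec$planted[[j]]$smiles
      other <- setdiff(seq_len(k), j)
      clash <- other[vapply(other, function(o)
        matchesPattern(pat[o], carrier), logical(1))]
      if (length(clash))
        stop("infeasible spec: planting conflict, pattern ",
             patternIds(pat)[clash[1]], " occurs in the carrier fragment of ",
             patternIds(pat)[j])
    }
  }

  .withSeed(spec$seed, {
    ## carrier assignment: exactly round(freq * n) per pattern
    truth <- matrix(FALSE, nrow = n, ncol = k,
                    dimnames = list(ids, if (k) patternIds(pat) else NULL))
    for (j in seq_len(k)) {
      p <- spec$planted[[j]]
      eligible <- if (is.null(p$classes)) seq_len(n)
                  else which(classes %in% p$classes)
      nCarry <- round(p$frequency * n)
      if (nCarry > length(eligible))
        stop("infeasible spec: pattern ", patternIds(pat)[j], " needs ",
             nCarry, " carriers but only ", length(eligible),
             " compounds are eligible")
      truth[sample(eligible, nCarry), j] <- TRUE
    }

    ## assembly
    smiles <- character(n)
    for (i in seq_len(n)) {
      host <- hosts[sample.int(length(hosts), 1L)]
      frags <- which(truth[i, ])
      mol <- host
      ok <- TRUE
      for (j in frags) {
        forms <- .attachForms(spec$planted[[j]]$smiles)
        placed <- NA_character_
        for (f in c("branch", "tail", "alone")) {
          cand <- forms[[f]](mol, pos = 2L)
          if (!is.na(canonicalSmiles(cand)) && .validValences(cand) &&
              matchesPattern(pat[j], cand)) { placed <- cand; break }
        }
        if (is.na(placed)) { ok <- FALSE; break }
        mol <- placed
      }
      if (!ok)
        stop("infeasible spec: cannot plant patterns ",
             paste(colnames(truth)[frags], collapse = "+"),
             " into one molecule")
      ## aliphatic decoy decorations for variety; a decoration must leave a
      ## valence-valid molecule and every planted pattern still matching
      nDec <- sample(0:2, 1L)
      for (d in seq_len(nDec)) {
        cand <- paste0(mol, "(",
                       .DECOY_BRANCHES[sample.int(length(.DECOY_BRANCHES), 1L)],
                       ")")
        if (is.na(canonicalSmiles(cand)) || !.validValences(cand)) next
        stillThere <- all(vapply(frags, function(j)
          matchesPattern(pat[j], cand), logical(1)))
        if (stillThere) mol <- cand
      }
      smiles[i] <- mol
    }

    compounds <- CompoundSet(ids, smiles, chem_class = classes,
                             strict = TRUE,
                             metadata = list(generator = "generateCompoundSet",
                                             seed = spec$seed))
    occ <- if (k) occurrenceMatrix(compounds, pat)
           else new("OccurrenceMatrix",
                    presence = matrix(logical(0), nrow = n, ncol = 0,
                                      dimnames = list(ids, character(0))))
    if (k && any(presence(occ) < truth))
      stop("internal error: planted pattern not recovered by the matcher")
    list(compounds = compounds, patterns = pat, truth = truth,
         occurrence = occ,
         n_accidental = sum(presence(occ) & !truth))
  })
}

## decorated, verified variants of a scaffold core
.scaffoldVariants <- function(core, scaffoldQuery) {
  cands <- c(core, paste0(core, "C"), paste0(core, "CC"),
             paste0("C", core), paste0("CC", core), paste0(core, "CCC"))
  cands <- cands[!is.na(canonicalSmiles(cands))]
  cands <- cands[.validValences(cands)]
  cands[matchesPattern(scaffoldQuery, cands)]
}

#' Generate a synthetic screening library
#'
#' Emits the requested number of molecules per scaffold (the core plus
#' small aliphatic decorations, each verified to still contain its core)
#' and `n_decoys` scaffold-free aliphatic decoys, deterministically per
#' seed.
#'
#' @param scaffold_mix named integer vector, e.g.
#'   `c(chromone = 10, purine = 5)`; names must exist in `scaffolds`.
#' @param n_decoys number of scaffold-free molecules to add.
#' @param seed integer seed.
#' @param scaffolds scaffold [PatternSet-class], default
#'   [defaultScaffolds()].
#' @param path optional output path; when given, a one-SMILES-per-line
#'   file (`smiles id`) is written and the path returned invisibly.
#' @return a [CompoundSet-class] (or the path when `path` is given).
#' @export
generateLibrary <- function(scaffold_mix = integer(0), n_decoys = 0L,
                            seed = 1L, scaffolds = defaultScaffolds(),
                            path = NULL) {
  stopifnot(all(names(scaffold_mix) %in% patternIds(scaffolds)))
  decoys <- c("CCCCCC", "CC(C)CCC", "C1CCCCC1", "CCCCCCC", "CC(C)(C)CC",
              "C1CCCC1CC")
  .withSeed(seed, {
    smiles <- character(0)
    for (nm in names(scaffold_mix)) {
      cnt <- scaffold_mix[[nm]]
      if (cnt <= 0L) next
      core <- scaffolds@patternData$smiles[match(nm, patternIds(scaffolds))]
      variants <- .scaffoldVariants(core, scaffolds[nm])
      if (length(variants) == 0L)
        stop("cannot decorate scaffold ", nm, " into valid molecules")
      smiles <- c(smiles, sample(variants, cnt, replace = TRUE))
    }
    if (n_decoys > 0L)
      smiles <- c(smiles, sample(decoys, n_decoys, replace = TRUE))
    ids <- sprintf("LIB_%04d", seq_along(smiles))
    lib <- if (length(smiles))
      CompoundSet(ids, smiles, strict = TRUE,
                  metadata = list(generator = "generateLibrary", seed = seed))
    else CompoundSet(character(0), character(0),
                     metadata = list(generator = "generateLibrary",
                                     seed = seed))
    if (!is.null(path)) {
      writeLines(if (length(smiles))
        paste(unname(compoundSmiles(lib)), compoundIds(lib)) else character(0),
        path)
      return(invisible(path))
    }
    lib
  })
}
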