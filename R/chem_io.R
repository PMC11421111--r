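## Readers and writers for the tabular formats the workflow touches:
## compound tables, substructure catalogs, scaffold definitions, screening
## libraries (CSV/TSV, one-SMILES-per-line, SDF) and ranked output lists.
## All text I/O is UTF-8 CSV/TSV; invalid rows are skipped-with-report by
## default and fail fast under strict = TRUE.

.detectSep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
}

.resolveColumns <- function(df, column_map, required, context) {
  for (key in required) {
    col <- column_map[[key]]
    if (is.null(col) || !col %in% names(df))
      stop("configuration error: required column '", key, "' (mapped to '",
           if (is.null(col)) "?" else col, "') not found in ", context)
  }
  column_map
}

#' Read a compound table (CSV/TSV)
#'
#' Reads a per-compound table with SMILES, unique identifier and optional
#' name/class/bioactivity columns; every other column is carried along as a
#' passthrough column. Rows whose SMILES do not parse are skipped and listed
#' in the rejection report (use `strict = TRUE` to fail instead); duplicated
#' identifiers are always an error.
#'
#' @param path file path; delimiter auto-detected (CSV or TSV) unless `sep`
#'   is given.
#' @param column_map named list/vector mapping the roles `id`, `smiles`,
#'   `name`, `class`, `activity_low`, `activity_high` to column names.
#' @param sep field separator, `NULL` for auto-detection.
#' @param strict fail on the first invalid row.
#' @return a [CompoundSet-class]; see [rejections()] for skipped rows.
#' @export
readCompoundTable <- function(path,
                              column_map = list(id = "id", smiles = "smiles",
                                                name = "name", class = "class",
                                                activity_low = "activity_low_uM",
                                                activity_high = "activity_high_uM"),
                              sep = NULL, strict = FALSE) {
  df <- .readTable(path, sep)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  column_map <- .resolveColumns(df, column_map, c("id", "smiles"), path)
  pick <- function(role) {
    col <- column_map[[role]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else NA_character_
  }
  used <- unlist(column_map[vapply(column_map, function(c)
    !is.null(c) && c %in% names(df), logical(1))])
  extra <- df[, setdiff(names(df), used), drop = FALSE]
  CompoundSet(
    compound_id = pick("id"),
    smiles = pick("smiles"),
    name = pick("name"),
    chem_class = pick("class"),
    activity_low_uM = suppressWarnings(as.numeric(pick("activity_low"))),
    activity_high_uM = suppressWarnings(as.numeric(pick("activity_high"))),
    extra = if (ncol(extra)) extra else NULL,
    strict = strict,
    metadata = list(source = path, column_map = as.list(column_map))
  )
}

#' Read and compile a substructure catalog (CSV/TSV)
#'
#' Expects columns `substructure_id`, `name`, `smiles` (configurable via
#' `column_map`). Each SMILES is compiled into a pattern query; defined
#' hydrogens written as `[H]` survive parsing and become unsubstitutable
#' positions. Rows that do not compile are rejected with a reason.
#'
#' @inheritParams readCompoundTable
#' @return a [PatternSet-class].
#' @export
readSubstructureCatalog <- function(path,
                                    column_map = list(id = "substructure_id",
                                                      name = "name",
                                                      smiles = "smiles"),
                                    sep = NULL, strict = FALSE) {
  df <- .readTable(path, sep)
  if (nrow(df) == 0L) stop("empty catalog: ", path)
  column_map <- .resolveColumns(df, column_map, c("id", "smiles"), path)
  nm <- if (!is.null(column_map$name) && column_map$name %in% names(df))
    df[[column_map$name]] else NA_character_
  compileCatalog(df[[column_map$id]], df[[column_map$smiles]], nm,
                 strict = strict,
                 metadata = list(source = path,
                                 column_map = as.list(column_map)))
}

#' Read a scaffold definition file
#'
#' Two-column CSV (`scaffold_name`, `smiles`); scaffold cores are compiled
#' with the same machinery as substructure patterns.
#'
#' @inheritParams readCompoundTable
#' @return a [PatternSet-class] whose ids are the scaffold names.
#' @export
readScaffoldFile <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  if (!all(c("scaffold_name", "smiles") %in% names(df)))
    stop("configuration error: scaffold file needs columns ",
         "'scaffold_name' and 'smiles': ", path)
  compileCatalog(df$scaffold_name, df$smiles, df$scaffold_name,
                 strict = TRUE, metadata = list(source = path))
}

#' Read a screening library
#'
#' Accepts one-SMILES-per-line files (`.smi`/`.smiles`, optional second
#' token used as identifier), CSV/TSV tables (via [readCompoundTable()]),
#' or SDF files whose title line provides the identifier.
#'
#' @param path library file.
#' @param format `"auto"` (by extension), `"smiles"`, `"csv"` or `"sdf"`.
#' @param column_map column mapping for tabular input.
#' @param strict fail on the first invalid record.
#' @return a [CompoundSet-class].
#' @export
readLibrary <- function(path, format = c("auto", "smiles", "csv", "sdf"),
                        column_map = list(id = "id", smiles = "smiles"),
                        strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     smi = , smiles = , txt = "smiles",
                     csv = , tsv = "csv",
                     sdf = , sd = "sdf",
                     stop("cannot infer library format from extension: ", path))
  }
  if (format == "csv")
    return(readCompoundTable(path, column_map = column_map, strict = strict))
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- as.character(ChemmineR::sdfid(sdf))
    ids[is.na(ids) | !nzchar(ids)] <-
      paste0("mol", which(is.na(ids) | !nzchar(ids)))
    txt <- ChemmineOB::convertFormat("SDF", "SMI",
                                     paste(readLines(path, warn = FALSE),
                                           collapse = "\n"))
    lines <- strsplit(txt, "\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    smi <- vapply(strsplit(lines, "[ \t]"), `[`, character(1), 1L)
    if (length(smi) != length(ids))
      ids <- paste0("mol", seq_along(smi))
    return(CompoundSet(ids, smi, strict = strict,
                       metadata = list(source = path, format = "sdf")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(CompoundSet(character(0), character(0),
                       metadata = list(source = path, format = "smiles")))
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("mol%04d", i)
  }, character(1))
  CompoundSet(ids, smi, strict = strict,
              metadata = list(source = path, format = "smiles"))
}

#' Write a ranked screening list
#'
#' CSV with columns `compound_id`, `smiles`, `scaffolds`, `score`,
#' `n_matched_primary`, `n_matched_secondary`, `rank` (1-based, in the
#' deterministic order produced by the screening tie-breaks). An empty hit
#' list yields a header-only file.
#'
#' @param hits ordered data.frame of screening hits (a ranked list from
#'   [rankedLists()] or [generateRankedLists()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRankedList <- function(hits, path) {
  cols <- c("compound_id", "smiles", "scaffolds", "score",
            "n_matched_primary", "n_matched_secondary")
  missing <- setdiff(cols, names(hits))
  if (length(missing))
    stop("ranked list lacks columns: ", paste(missing, collapse = ", "))
  out <- hits[, cols, drop = FALSE]
  out$rank <- seq_len(nrow(out))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a ranked screening list
#'
#' @param path CSV written by [writeRankedList()].
#' @return data.frame with scores as numeric (bit-exact round trip).
#' @export
readRankedList <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df
}

#' Write a fingerprint or signature table as CSV
#'
#' @param table data.frame produced by [fingerprintTable()] or
#'   [buildSignature()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
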