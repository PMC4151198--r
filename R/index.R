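# Building, querying, and persisting the peptide database: peptide ->
# occurrences (protein, coordinates, missed cleavages) with protein-level
# annotation features remapped to the peptide level.

#' @importFrom data.table data.table setkeyv rbindlist setDT as.data.table
#'   fread uniqueN :=
#' @importFrom IRanges IRanges overlapsAny
NULL

# data.table NSE columns
utils::globalVariables(c("pepkey", "accession", "mass", "total_occurrences",
                         "distinct_proteins", "sequence", "nonstandard",
                         ".N", "."))

pepKey <- function(sequence, collapseIL) {
  if (collapseIL) chartr("I", "L", sequence) else sequence
}

#' Remap protein features to one peptide occurrence
#'
#' Computes the annotation flags of a peptide occurrence from its parent
#' protein's feature list: a flag is true iff at least one feature of the
#' corresponding kind overlaps the occurrence interval (1-based inclusive
#' interval intersection). `nonstandard` depends only on the peptide
#' sequence (presence of B, Z, X, U or O).
#'
#' @param start,end 1-based inclusive coordinates on the parent protein.
#' @param sequence the peptide sequence.
#' @param features feature table of the parent protein (columns `kind`,
#'   `start`, `end`); may have zero rows.
#' @return named logical vector with elements `has_ptm`, `has_variant`,
#'   `has_conflict`, `in_signal`, `isoform_variable`, `nonstandard`.
#' @examples
#' ft <- data.frame(kind = "ptm", start = 5L, end = 5L)
#' annotateOccurrence(1L, 7L, "AAAAASK", ft)["has_ptm"]
#' @export
annotateOccurrence <- function(start, end, sequence, features) {
  stopifnot(start >= 1L, end >= start)
  flags <- stats::setNames(rep(FALSE, length(FLAG_COLUMNS)), FLAG_COLUMNS)
  flags["nonstandard"] <- grepl("[BZXUO]", sequence)
  if (!is.null(features) && nrow(features)) {
    hit <- features$start <= end & features$end >= start
    kinds <- unique(features$kind[hit])
    flags[unique(stats::na.omit(KIND_TO_FLAG[kinds]))] <- TRUE
  }
  flags
}

# Vectorised flag computation for all occurrences of one protein.
occurrenceFlags <- function(occ, features) {
  flags <- data.table(has_ptm = FALSE, has_variant = FALSE,
                      has_conflict = FALSE, in_signal = FALSE,
                      isoform_variable = FALSE,
                      nonstandard = occ$nonstandard)
  if (nrow(occ) == 0L || is.null(features) || nrow(features) == 0L)
    return(flags[seq_len(nrow(occ))])
  pepRanges <- IRanges::IRanges(occ$start, occ$end)
  for (flag in setdiff(FLAG_COLUMNS, "nonstandard")) {
    kinds <- names(KIND_TO_FLAG)[KIND_TO_FLAG == flag]
    sel <- features$kind %in% kinds
    if (!any(sel)) next
    ftRanges <- IRanges::IRanges(features$start[sel], features$end[sel])
    flags[[flag]] <- IRanges::overlapsAny(pepRanges, ftRanges)
  }
  flags
}

#' Build a peptide index from parsed protein records
#'
#' Digests every protein with the given parameters and assembles the peptide
#' database: a distinct-peptide table with aggregate counts
#' (`total_occurrences`, `distinct_proteins`) and an occurrence table with
#' per-occurrence coordinates, missed-cleavage counts and annotation flags.
#' Peptide masses are monoisotopic; peptides containing nonstandard residues
#' get `NA` mass and a `nonstandard` flag.
#'
#' @param records a [ProteinSet-class]; accessions must be unique.
#' @param params a [DigestionParams-class].
#' @param label proteome label stored in the metadata (e.g. `"human"`).
#' @param collapseIL collapse I and L to a single symbol for peptide
#'   matching (they are isobaric in MS); the flag is recorded in the
#'   metadata and must agree between indexes compared in a dual-proteome
#'   query.
#' @param sourceFile optional name of the file the records came from,
#'   recorded in the metadata.
#' @return A [PeptideIndex-class].
#' @examples
#' ps <- proteinSet("P1", "toy", "synthetic", "AAAKGGGR")
#' buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "toy")
#' @export
buildPeptideIndex <- function(records, params = digestionParams(),
                              label = "", collapseIL = FALSE,
                              sourceFile = NA_character_) {
  stopifnot(is(records, "ProteinSet"), is(params, "DigestionParams"))
  validObject(params)
  if (length(records) == 0L)
    stop("cannot build an index from an empty record set")

  prot <- records@proteins
  seqs <- as.character(records@sequences)
  featsByAcc <- split(records@features, records@features$accession)

  occList <- vector("list", nrow(prot))
  for (i in seq_len(nrow(prot))) {
    digest <- digestSequence(seqs[[i]], params)
    if (nrow(digest) == 0L) next
    setDT(digest)
    flags <- occurrenceFlags(digest, featsByAcc[[prot$accession[[i]]]])
    occList[[i]] <- cbind(
      data.table(sequence = digest$sequence,
                 accession = prot$accession[[i]],
                 start = digest$start, end = digest$end,
                 missed_cleavages = digest$missed_cleavages),
      flags)
  }
  occurrences <- rbindlist(occList)
  if (nrow(occurrences) == 0L)
    stop("digestion produced no peptides; lower minPeptideLength?")
  occurrences[, pepkey := pepKey(sequence, collapseIL)]

  peptides <- occurrences[, .(sequence = sequence[[1L]],
                              length = nchar(sequence[[1L]]),
                              total_occurrences = .N,
                              distinct_proteins = uniqueN(accession),
                              nonstandard = any(nonstandard)),
                          by = pepkey]
  peptides[, mass := NA_real_]
  std <- !peptides$nonstandard
  peptides$mass[std] <- round(peptideMass(peptides$sequence[std]), 6L)

  setkeyv(occurrences, "pepkey")
  setkeyv(peptides, "pepkey")

  proteins <- data.frame(accession = prot$accession, name = prot$name,
                         organism = prot$organism,
                         length = nchar(seqs), sequence = seqs,
                         stringsAsFactors = FALSE)

  metadata <- list(label = label,
                   source = sourceFile,
                   dialect = records@source,
                   params = params,
                   collapseIL = collapseIL,
                   built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   format_version = INDEX_FORMAT_VERSION)
  new("PeptideIndex", metadata = metadata, proteins = proteins,
      peptides = peptides, occurrences = occurrences)
}

setMethod("countHits", "PeptideIndex", function(index, sequence) {
  sequence <- toupper(as.character(sequence))
  keys <- pepKey(sequence, isTRUE(index@metadata$collapseIL))
  hit <- index@peptides[data.table(pepkey = keys), on = "pepkey"]
  data.frame(sequence = sequence,
             total_occurrences = ifelse(is.na(hit$total_occurrences), 0L,
                                        hit$total_occurrences),
             distinct_proteins = ifelse(is.na(hit$distinct_proteins), 0L,
                                        hit$distinct_proteins),
             stringsAsFactors = FALSE)
})

# ---- persistence ----------------------------------------------------------
# Single-file plain-text container: a header line, a JSON metadata line, and
# one tab-separated section per table, each preceded by a section marker
# carrying its row count. Reloading reproduces identical query answers.

sectionMarker <- "#%%SECTION"

#' Persist a peptide index to a single file
#'
#' Writes the index as a single self-contained text file (JSON metadata plus
#' tab-separated table sections). [loadPeptideIndex()] restores it with
#' identical query answers, including the peptide-sequence key used for
#' exact-match lookup.
#'
#' @param index a [PeptideIndex-class].
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
savePeptideIndex <- function(index, file) {
  stopifnot(is(index, "PeptideIndex"))
  md <- index@metadata
  p <- md$params
  mdJson <- jsonlite::toJSON(
    list(label = md$label, source = md$source, dialect = md$dialect,
         enzyme = p@enzyme, max_missed_cleavages = p@maxMissedCleavages,
         min_peptide_length = p@minPeptideLength,
         proline_rule = p@prolineRule, collapse_il = md$collapseIL,
         built = md$built, format_version = md$format_version),
    auto_unbox = TRUE)

  writeSection <- function(con, name, dt) {
    writeLines(sprintf("%s %s %d", sectionMarker, name, nrow(dt)), con)
    tab <- vapply(as.data.frame(dt), function(col) {
      if (is.logical(col)) ifelse(col, "1", "0")
      else if (is.double(col)) ifelse(is.na(col), "NA", sprintf("%.6f", col))
      else as.character(col)
    }, character(nrow(dt)))
    if (nrow(dt) == 1L) tab <- matrix(tab, nrow = 1L)
    writeLines(paste(names(dt), collapse = "\t"), con)
    if (nrow(dt)) writeLines(apply(tab, 1L, paste, collapse = "\t"), con)
  }

  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#%%PeptideIndex v%d", INDEX_FORMAT_VERSION), con)
  writeLines(as.character(mdJson), con)
  writeSection(con, "proteins", index@proteins)
  writeSection(con, "peptides", index@peptides)
  writeSection(con, "occurrences", index@occurrences)
  invisible(file)
}

#' Load a peptide index written by [savePeptideIndex()]
#'
#' @param file path to an index file.
#' @return A [PeptideIndex-class].
#' @export
loadPeptideIndex <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines) || !startsWith(lines[[1L]], "#%PeptideIndex"))
    stop(sprintf("'%s' is not a peptide index file", file))
  md <- jsonlite::fromJSON(lines[[2L]])
  params <- digestionParams(enzyme = md$enzyme,
                            maxMissedCleavages = md$max_missed_cleavages,
                            minPeptideLength = md$min_peptide_length,
                            prolineRule = md$proline_rule)
  marks <- which(startsWith(lines, sectionMarker))
  sections <- list()
  for (i in seq_along(marks)) {
    hdr <- strsplit(lines[[marks[[i]]]], " ", fixed = TRUE)[[1L]]
    from <- marks[[i]] + 1L
    to <- if (i < length(marks)) marks[[i + 1L]] - 1L else length(lines)
    sections[[hdr[[2L]]]] <- fread(text = paste(lines[from:to],
                                                collapse = "\n"),
                                   sep = "\t", header = TRUE,
                                   na.strings = "NA", colClasses = NULL)
  }
  proteins <- as.data.frame(sections$proteins)
  peptides <- sections$peptides
  occurrences <- sections$occurrences
  for (col in intersect(FLAG_COLUMNS, names(occurrences)))
    occurrences[[col]] <- as.logical(occurrences[[col]])
  peptides$nonstandard <- as.logical(peptides$nonstandard)
  if (!"mass" %in% names(peptides)) peptides$mass <- NA_real_
  peptides$mass <- as.numeric(peptides$mass)
  for (col in c("start", "end", "missed_cleavages"))
    occurrences[[col]] <- as.integer(occurrences[[col]])
  for (col in c("length", "total_occurrences", "distinct_proteins"))
    peptides[[col]] <- as.integer(peptides[[col]])
  setkeyv(occurrences, "pepkey")
  setkeyv(peptides, "pepkey")
  metadata <- list(label = md$label, source = md$source, dialect = md$dialect,
                   params = params, collapseIL = isTRUE(md$collapse_il),
                   built = md$built, format_version = md$format_version)
  new("PeptideIndex", metadata = metadata, proteins = proteins,
      peptides = peptides, occurrences = occurrences)
}

# Digestion settings that must agree between indexes compared in a
# dual-proteome query. minPeptideLength may differ (it only affects which
# short peptides were stored, which the caller controls); enzyme, missed
# cleavages, proline rule and I/L collapse change matching semantics.
checkComparableIndexes <- function(fg, bg) {
  pf <- fg@metadata$params; pb <- bg@metadata$params
  problems <- character()
  if (pf@enzyme != pb@enzyme)
    problems <- c(problems, sprintf("enzyme (%s vs %s)", pf@enzyme, pb@enzyme))
  if (pf@maxMissedCleavages != pb@maxMissedCleavages)
    problems <- c(problems, sprintf("maxMissedCleavages (%d vs %d)",
                                    pf@maxMissedCleavages,
                                    pb@maxMissedCleavages))
  if (pf@prolineRule != pb@prolineRule)
    problems <- c(problems, "prolineRule")
  if (isTRUE(fg@metadata$collapseIL) != isTRUE(bg@metadata$collapseIL))
    problems <- c(problems, "collapseIL")
  if (length(problems))
    stop(sprintf("digestion parameter mismatch between indexes: %s",
                 paste(problems, collapse = ", ")))
  invisible(TRUE)
}
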