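# Query engine and surrogate-peptide selection: accession / name / sequence
# queries over a peptide index, the candidate filter set, the dual-proteome
# (foreground vs host/background) selection, and CSV export.

SELECTION_COLUMNS <- c("protein_accession", "protein_name",
                       "peptide_sequence", "start", "end", "length",
                       "missed_cleavages", "mass",
                       "fg_total_occurrences", "fg_distinct_proteins",
                       "bg_total_occurrences",
                       FLAG_COLUMNS, "passed_filters", "rejection_reasons")

FLAG_REJECTION_REASONS <- c(
  has_ptm = "modified residue (PTM)",
  has_variant = "sequence variant (SNP)",
  has_conflict = "sequence conflict",
  in_signal = "signal peptide",
  isoform_variable = "isoform-variable region",
  nonstandard = "nonstandard residue")

# Unfiltered candidate rows for a set of accessions known to be in the index.
rowsForAccessions <- function(index, accs) {
  occ <- index@occurrences[index@occurrences$accession %in% accs, ]
  counts <- index@peptides[occ$pepkey,
                           c("total_occurrences", "distinct_proteins",
                             "mass")]
  nameOf <- stats::setNames(index@proteins$name, index@proteins$accession)
  df <- data.frame(protein_accession = occ$accession,
                   protein_name = unname(nameOf[occ$accession]),
                   peptide_sequence = occ$sequence,
                   start = occ$start, end = occ$end,
                   length = nchar(occ$sequence),
                   missed_cleavages = occ$missed_cleavages,
                   mass = counts$mass,
                   fg_total_occurrences = counts$total_occurrences,
                   fg_distinct_proteins = counts$distinct_proteins,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(occ)[, FLAG_COLUMNS])
}

orderRows <- function(rows) {
  rows <- rows[order(rows$protein_accession, rows$start,
                     rows$missed_cleavages, rows$peptide_sequence,
                     na.last = TRUE, method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

finishRows <- function(rows, filters, keepRejected) {
  rows <- applyFilters(rows, filters)
  rows <- orderRows(rows)
  if (!keepRejected) {
    rows <- rows[rows$passed_filters, , drop = FALSE]
    rownames(rows) <- NULL
  }
  rows
}

#' Apply selection filters to candidate rows
#'
#' Evaluates every filter in [filterConfig()] against each row and populates
#' `rejection_reasons` (reasons joined by `"; "`, in the fixed order: length,
#' excluded residues, missed cleavages, annotation flags, foreground
#' uniqueness, background presence, m/z window) and `passed_filters`
#' (true iff no reason). The function recomputes both columns from scratch,
#' so it is idempotent, and it never drops rows.
#'
#' @param rows selection rows as produced by the query functions.
#' @param filters a [FilterConfig-class].
#' @return `rows` with `passed_filters` and `rejection_reasons` columns.
#' @export
applyFilters <- function(rows, filters = filterConfig()) {
  stopifnot(is(filters, "FilterConfig"))
  validObject(filters)
  n <- nrow(rows)
  reasons <- vector("list", n)
  if (n == 0L) {
    rows$passed_filters <- logical(0L)
    rows$rejection_reasons <- character(0L)
    return(rows)
  }
  add <- function(reasons, hit, text) {
    hit <- !is.na(hit) & hit
    for (i in which(hit)) reasons[[i]] <- c(reasons[[i]], text)
    reasons
  }

  reasons <- add(reasons, rows$length < filters@minLength,
                 sprintf("length < %g", filters@minLength))
  reasons <- add(reasons, rows$length > filters@maxLength,
                 sprintf("length > %g", filters@maxLength))
  for (res in filters@excludedResidues)
    reasons <- add(reasons, grepl(res, rows$peptide_sequence, fixed = TRUE),
                   sprintf("excluded residue %s", res))
  if (is.finite(filters@maxMissedCleavages))
    reasons <- add(reasons,
                   rows$missed_cleavages > filters@maxMissedCleavages,
                   sprintf("missed cleavages > %g",
                           filters@maxMissedCleavages))
  for (flag in intersect(FLAG_COLUMNS, filters@excludeFlags))
    reasons <- add(reasons, rows[[flag]], FLAG_REJECTION_REASONS[[flag]])
  if (filters@requireUniqueFg) {
    fgTotal <- rows$fg_total_occurrences
    reasons <- add(reasons, fgTotal == 0L, "no hit in foreground")
    notUnique <- if (filters@uniqueBy == "proteins")
      rows$fg_distinct_proteins > 1L else fgTotal > 1L
    reasons <- add(reasons, notUnique, "not unique in foreground")
  }
  if ("bg_total_occurrences" %in% names(rows))
    reasons <- add(reasons,
                   rows$bg_total_occurrences > filters@maxBgOccurrences,
                   "present in background")
  if (length(filters@mzWindow)) {
    w <- filters@mzWindow
    inWindow <- rep(NA, n)
    ok <- !is.na(rows$mass)
    if (any(ok)) {
      hits <- rep(FALSE, sum(ok))
      for (z in w$charges) {
        mzv <- peptideMz(rows$mass[ok], z)
        hits <- hits | (mzv >= w$low & mzv <= w$high)
      }
      inWindow[ok] <- hits
    }
    reasons <- add(reasons, !inWindow, "m/z outside window")
  }

  rows$rejection_reasons <- vapply(reasons, function(r)
    paste(r, collapse = "; "), character(1L))
  rows$passed_filters <- !nzchar(rows$rejection_reasons)
  rows
}

#' Query a peptide index by protein accession
#'
#' Returns every digest peptide of the queried proteins as a selection row
#' carrying foreground hit counts and annotation flags, with the filters
#' applied. In batch mode (more than one accession) an unknown accession
#' raises a warning and is skipped; with a single accession it is an error.
#'
#' @param index a [PeptideIndex-class].
#' @param accessions character vector of protein accessions.
#' @param filters a [FilterConfig-class].
#' @param keepRejected keep rows failing the filters (with their
#'   `rejection_reasons` populated) instead of dropping them.
#' @return data.frame of selection rows sorted by (accession, start,
#'   missed cleavages).
#' @examples
#' ps <- proteinSet("P1", "toy", "synthetic", "AAAKGGGR")
#' idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "toy")
#' queryAccession(idx, "P1", uniquenessFilter())
#' @export
queryAccession <- function(index, accessions, filters = filterConfig(),
                           keepRejected = FALSE) {
  stopifnot(is(index, "PeptideIndex"), length(accessions) >= 1L)
  known <- accessions %in% index@proteins$accession
  if (!all(known)) {
    missing <- accessions[!known]
    if (length(accessions) == 1L)
      stop(sprintf("accession not in index: %s", missing))
    for (m in missing)
      warning(sprintf("accession not in index, skipped: %s", m),
              call. = FALSE)
  }
  rows <- rowsForAccessions(index, accessions[known])
  finishRows(rows, filters, keepRejected)
}

#' Query a peptide index by protein name
#'
#' Case-insensitive substring match over the protein names; all matching
#' proteins are expanded to their peptide rows as in [queryAccession()].
#' No match yields an empty result, not an error.
#'
#' @inheritParams queryAccession
#' @param name substring to look for in protein names.
#' @return data.frame of selection rows (zero rows when nothing matches).
#' @export
queryName <- function(index, name, filters = filterConfig(),
                      keepRejected = FALSE) {
  stopifnot(is(index, "PeptideIndex"), nzchar(name))
  hit <- grepl(tolower(name), tolower(index@proteins$name), fixed = TRUE)
  rows <- rowsForAccessions(index, index@proteins$accession[hit])
  finishRows(rows, filters, keepRejected)
}

#' Query a peptide index by peptide sequences
#'
#' One row per (sequence, occurrence) for sequences present in the digest;
#' sequences absent from the index yield a single row with zero hits and no
#' protein fields. Intended to check the uniqueness of experimentally
#' observed peptides and confirm the proteins they identify.
#'
#' @inheritParams queryAccession
#' @param sequences character vector of peptide sequences (upper-cased
#'   internally).
#' @return data.frame of selection rows.
#' @export
querySequences <- function(index, sequences, filters = filterConfig(),
                           keepRejected = FALSE) {
  stopifnot(is(index, "PeptideIndex"), length(sequences) >= 1L)
  sequences <- toupper(sequences)
  collapse <- isTRUE(index@metadata$collapseIL)
  keys <- pepKey(sequences, collapse)
  nameOf <- stats::setNames(index@proteins$name, index@proteins$accession)
  pieces <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    occ <- index@occurrences[.(keys[[i]]), nomatch = NULL]
    if (nrow(occ)) {
      counts <- index@peptides[.(keys[[i]])]
      df <- data.frame(protein_accession = occ$accession,
                       protein_name = unname(nameOf[occ$accession]),
                       peptide_sequence = occ$sequence,
                       start = occ$start, end = occ$end,
                       length = nchar(occ$sequence),
                       missed_cleavages = occ$missed_cleavages,
                       mass = counts$mass,
                       fg_total_occurrences = counts$total_occurrences,
                       fg_distinct_proteins = counts$distinct_proteins,
                       stringsAsFactors = FALSE)
      pieces[[i]] <- cbind(df, as.data.frame(occ)[, FLAG_COLUMNS])
    } else {
      mass <- tryCatch(round(peptideMass(sequences[[i]]), 6L),
                       error = function(e) NA_real_)
      df <- data.frame(protein_accession = NA_character_,
                       protein_name = NA_character_,
                       peptide_sequence = sequences[[i]],
                       start = NA_integer_, end = NA_integer_,
                       length = nchar(sequences[[i]]),
                       missed_cleavages = NA_integer_,
                       mass = mass,
                       fg_total_occurrences = 0L,
                       fg_distinct_proteins = 0L,
                       stringsAsFactors = FALSE)
      flags <- as.data.frame(as.list(stats::setNames(
        rep(FALSE, length(FLAG_COLUMNS)), FLAG_COLUMNS)))
      flags$nonstandard <- grepl("[BZXUO]", sequences[[i]])
      pieces[[i]] <- cbind(df, flags)
    }
  }
  rows <- do.call(rbind, pieces)
  finishRows(rows, filters, keepRejected)
}

#' Select surrogate peptides against a host/background proteome
#'
#' The dual-proteome (xenograft) query: all digest peptides of the queried
#' proteins in the foreground proteome are looked up in the background
#' proteome's peptide database, and only peptides that are unique within the
#' foreground proteome and absent from the background (at the default
#' `maxBgOccurrences = 0`) pass, together with all other configured filters.
#' The two indexes must have been built with the same enzyme, missed-cleavage
#' setting, proline rule and I/L-collapse flag; otherwise an error is raised
#' before any query runs.
#'
#' @param fgIndex [PeptideIndex-class] of the proteome of interest.
#' @param bgIndex [PeptideIndex-class] of the host/background proteome.
#' @inheritParams queryAccession
#' @return data.frame of selection rows with an additional
#'   `bg_total_occurrences` column.
#' @export
selectSurrogates <- function(fgIndex, bgIndex, accessions,
                             filters = filterConfig(),
                             keepRejected = FALSE) {
  stopifnot(is(fgIndex, "PeptideIndex"), is(bgIndex, "PeptideIndex"))
  checkComparableIndexes(fgIndex, bgIndex)
  known <- accessions %in% fgIndex@proteins$accession
  if (!all(known)) {
    missing <- accessions[!known]
    if (length(accessions) == 1L)
      stop(sprintf("accession not in foreground index: %s", missing))
    for (m in missing)
      warning(sprintf("accession not in foreground index, skipped: %s", m),
              call. = FALSE)
  }
  rows <- rowsForAccessions(fgIndex, accessions[known])
  bg <- countHits(bgIndex, rows$peptide_sequence)
  rows$bg_total_occurrences <- bg$total_occurrences
  # keep the column order stable: bg count right after the fg counts
  rows <- rows[, intersect(SELECTION_COLUMNS, names(rows))]
  finishRows(rows, filters, keepRejected)
}

#' Export selection rows as CSV
#'
#' Writes RFC 4180 CSV (UTF-8, quoted text fields, header row) with the
#' fixed column order of the selection rows; logical columns are written as
#' `true`/`false`. [readSelectionCsv()] reproduces the rows.
#'
#' @param rows selection rows.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
exportSelectionCsv <- function(rows, file) {
  out <- rows
  for (col in names(out))
    if (is.logical(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "true", "false"))
  utils::write.csv(out, file, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\r\n")
  invisible(file)
}

#' Read back a CSV written by [exportSelectionCsv()]
#'
#' @param file path to the CSV.
#' @return data.frame of selection rows with the original column types.
#' @export
readSelectionCsv <- function(file) {
  rows <- utils::read.csv(file, stringsAsFactors = FALSE, na.strings = "",
                          fileEncoding = "UTF-8")
  for (col in intersect(c(FLAG_COLUMNS, "passed_filters"), names(rows)))
    rows[[col]] <- rows[[col]] == "true"
  for (col in intersect(c("start", "end", "length", "missed_cleavages",
                          "fg_total_occurrences", "fg_distinct_proteins",
                          "bg_total_occurrences"), names(rows)))
    rows[[col]] <- as.integer(rows[[col]])
  if ("rejection_reasons" %in% names(rows)) {
    rows$rejection_reasons[is.na(rows$rejection_reasons)] <- ""
    rows$rejection_reasons <- as.character(rows$rejection_reasons)
  }
  if ("mass" %in% names(rows)) rows$mass <- as.numeric(rows$mass)
  for (col in c("protein_accession", "protein_name", "peptide_sequence"))
    if (col %in% names(rows)) rows[[col]] <- as.character(rows[[col]])
  rows
}

#' Read a batch query file
#'
#' Plain-text batch input: one accession or peptide sequence per line;
#' blank lines and `#` comments are ignored.
#'
#' @param file path to the batch file.
#' @return character vector of items.
#' @export
readBatchFile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
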