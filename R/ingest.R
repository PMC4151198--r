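# Parsers for the supported proteome database dialects: UniProt flat text
# (.dat/.txt), RefSeq GenPept (.gpff) and FASTA. Each returns a ProteinSet.
# Parsing is tolerant per entry (malformed entries are skipped and reported)
# but strict per file for structural corruption such as an unterminated
# final entry.

# Accept either a file path or raw text (a character vector of lines, or a
# single string with embedded newlines).
asLines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

newParseReport <- function() list(parsed = 0L, skipped = 0L,
                                  messages = character())

#' Write a parse report as plain text
#'
#' @param x a [ProteinSet-class] returned by one of the parsers.
#' @param file destination path or connection.
#' @return `file`, invisibly.
#' @export
writeParseReport <- function(x, file) {
  stopifnot(is(x, "ProteinSet"))
  rep <- x@parseReport
  lines <- c(sprintf("source: %s", x@source),
             sprintf("entries parsed: %d", rep$parsed),
             sprintf("entries skipped: %d", rep$skipped),
             if (length(rep$messages)) c("messages:",
                                         paste0("  ", rep$messages)))
  writeLines(lines, file)
  invisible(file)
}

# Parse a UniProt feature-table location token: "5", "3..4"; positional
# ranges with unknown/outside endpoints ("<1", "?23") are not usable at the
# peptide level and return NULL.
parseFtLocation <- function(loc) {
  loc <- trimws(loc)
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    return(c(p, p))
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
  if (length(m) == 3L) return(as.integer(m[2:3]))
  # legacy two-column "FROM TO" layout
  m <- regmatches(loc, regexec("^(\\d+)\\s+(\\d+)", loc))[[1L]]
  if (length(m) == 3L) return(as.integer(m[2:3]))
  NULL
}

#' Parse UniProt flat-text entries
#'
#' Reads zero or more UniProt flat-text entries (SwissProt/TrEMBL `.dat` /
#' `.txt` format, entries terminated by `//`). The primary accession is the
#' first accession on the first `AC` line. Feature-table keys are mapped to
#' peptide-level feature kinds through a fixed table (`MOD_RES`, `LIPID`,
#' `CROSSLNK` to `ptm`; `CARBOHYD` to `glyco`; `VARIANT` to `variant_snp`;
#' `CONFLICT` to `conflict`; `SIGNAL` to `signal_peptide`; `VAR_SEQ` to
#' `isoform_variable`; anything else to `other`, retained). Entries missing
#' an accession or with an unparseable sequence block are skipped and
#' recorded in the parse report; a duplicate primary accession or an
#' unterminated final entry is an error.
#'
#' @param file path to a flat file, or its text.
#' @return A [ProteinSet-class]; the parse report is available in the
#'   `parseReport` slot and can be written with [writeParseReport()].
#' @export
readUniProt <- function(file) {
  lines <- asLines(file)
  report <- newParseReport()
  nonblank <- which(nzchar(trimws(lines)))
  term <- which(trimws(lines) == "//")
  if (length(nonblank) && (length(term) == 0L || max(nonblank) > max(term)))
    stop("structurally corrupt UniProt flat file: unterminated final entry")

  entries <- list()
  start <- 1L
  for (t in term) {
    entries[[length(entries) + 1L]] <- lines[start:(t - 1L)]
    start <- t + 1L
  }

  acc <- name <- org <- seqs <- character()
  taxid <- integer(); reviewed <- logical()
  featList <- list()

  entryStart <- c(1L, utils::head(term, -1L) + 1L)
  for (i in seq_along(entries)) {
    e <- tryCatch(parseUniProtEntry(entries[[i]]),
                  error = function(err) conditionMessage(err))
    if (is.character(e)) {
      report$skipped <- report$skipped + 1L
      report$messages <- c(report$messages,
                           sprintf("entry %d (line %d): %s", i,
                                   entryStart[i], e))
      next
    }
    report$parsed <- report$parsed + 1L
    acc <- c(acc, e$accession); name <- c(name, e$name)
    org <- c(org, e$organism); seqs <- c(seqs, e$sequence)
    taxid <- c(taxid, e$taxon_id); reviewed <- c(reviewed, e$reviewed)
    if (nrow(e$features)) featList[[length(featList) + 1L]] <- e$features
  }
  if (anyDuplicated(acc))
    stop(sprintf("duplicate primary accession(s) in file: %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  features <- if (length(featList)) do.call(rbind, featList)
              else emptyFeatureTable()
  proteinSet(accession = acc, name = name, organism = org, sequence = seqs,
             taxon_id = taxid, reviewed = reviewed, features = features,
             source = "uniprot_dat", parseReport = report)
}

parseUniProtEntry <- function(lines) {
  tag <- substr(lines, 1L, 2L)
  body <- trimws(substr(lines, 6L, nchar(lines)))

  acLines <- body[tag == "AC"]
  if (!length(acLines)) stop("missing accession (AC line)")
  accession <- sub(";.*$", "", acLines[[1L]])
  accession <- trimws(accession)
  if (!nzchar(accession)) stop("missing accession (empty AC line)")

  deLines <- body[tag == "DE"]
  name <- NA_character_
  if (length(deLines)) {
    rec <- grep("RecName: Full=", deLines, fixed = TRUE, value = TRUE)
    name <- if (length(rec)) sub(".*RecName: Full=([^;{]*).*", "\\1", rec[[1L]])
            else deLines[[1L]]
    name <- trimws(sub("[;.]\\s*$", "", name))
  }
  if (is.na(name) || !nzchar(name)) name <- accession

  osLines <- body[tag == "OS"]
  organism <- if (length(osLines))
    sub("\\.$", "", paste(osLines, collapse = " ")) else NA_character_

  oxLines <- body[tag == "OX"]
  taxon_id <- NA_integer_
  if (length(oxLines)) {
    m <- regmatches(oxLines[[1L]],
                    regexec("NCBI_TaxID=(\\d+)", oxLines[[1L]]))[[1L]]
    if (length(m) == 2L) taxon_id <- as.integer(m[[2L]])
  }

  idLine <- body[tag == "ID"]
  reviewed <- if (length(idLine)) grepl("\\bReviewed\\b", idLine[[1L]]) else NA

  # Sequence block: SQ header then continuation lines (tag is spaces).
  sqAt <- which(tag == "SQ")
  if (!length(sqAt)) stop("missing sequence block (SQ line)")
  seqLines <- lines[seq(sqAt[[1L]] + 1L, length(lines))]
  seqLines <- seqLines[substr(seqLines, 1L, 2L) == "  "]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence block")
  if (grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence))
    stop("unparseable sequence block: letters outside the allowed alphabet")

  # Feature table: a key line starts with a non-blank key in the FT body;
  # qualifier/continuation lines are indented past the key column.
  ftIdx <- which(tag == "FT")
  feats <- list()
  cur <- NULL
  flush <- function(cur, feats) {
    if (is.null(cur)) return(feats)
    pos <- parseFtLocation(cur$loc)
    if (is.null(pos)) return(feats)
    feats[[length(feats) + 1L]] <- data.frame(
      accession = accession,
      kind = mapFeatureKind(cur$key, "uniprot"),
      start = pos[[1L]], end = pos[[2L]],
      description = cur$desc, source_key = cur$key,
      stringsAsFactors = FALSE)
    feats
  }
  for (j in ftIdx) {
    raw <- substr(lines[[j]], 6L, nchar(lines[[j]]))
    if (grepl("^\\S", raw)) {                     # new feature key line
      feats <- flush(cur, feats)
      key <- sub("\\s.*$", "", raw)
      loc <- trimws(sub("^\\S+", "", raw))
      cur <- list(key = key, loc = loc, desc = "")
    } else if (!is.null(cur)) {
      q <- trimws(raw)
      m <- regmatches(q, regexec("^/note=\"(.*)\"?$", q))[[1L]]
      if (length(m) == 2L) {
        cur$desc <- sub("\"$", "", m[[2L]])
      } else if (!startsWith(q, "/") && !nzchar(cur$desc) && nzchar(q)) {
        # legacy layout carries the description on continuation lines
        cur$desc <- sub("\\.$", "", q)
      }
    }
  }
  feats <- flush(cur, feats)
  features <- if (length(feats)) do.call(rbind, feats) else emptyFeatureTable()
  if (nrow(features) && any(features$end > nchar(sequence)))
    stop("feature interval extends beyond the sequence")

  list(accession = accession, name = name, organism = organism,
       taxon_id = taxon_id, reviewed = reviewed, sequence = sequence,
       features = features)
}

#' Parse RefSeq GenPept entries
#'
#' Reads GenPept flat-format (`.gpff`) entries (LOCUS ... ORIGIN ... `//`).
#' The accession is taken from the VERSION line (falling back to ACCESSION).
#' Feature keys are mapped through a fixed table: `Site` features are `ptm`
#' (or `glyco` when the qualifiers mention glycosylation), `sig_peptide` is
#' `signal_peptide`, `variation` is `variant_snp`, `misc_difference` is
#' `conflict`, `Region` and anything else is `other`. Error handling matches
#' [readUniProt()].
#'
#' @inheritParams readUniProt
#' @return A [ProteinSet-class].
#' @export
readGenPept <- function(file) {
  lines <- asLines(file)
  report <- newParseReport()
  nonblank <- which(nzchar(trimws(lines)))
  term <- which(trimws(lines) == "//")
  if (length(nonblank) && (length(term) == 0L || max(nonblank) > max(term)))
    stop("structurally corrupt GenPept file: unterminated final entry")

  entries <- list()
  start <- 1L
  for (t in term) {
    entries[[length(entries) + 1L]] <- lines[start:(t - 1L)]
    start <- t + 1L
  }

  acc <- name <- org <- seqs <- character()
  taxid <- integer()
  featList <- list()
  entryStart <- c(1L, utils::head(term, -1L) + 1L)
  for (i in seq_along(entries)) {
    e <- tryCatch(parseGenPeptEntry(entries[[i]]),
                  error = function(err) conditionMessage(err))
    if (is.character(e)) {
      report$skipped <- report$skipped + 1L
      report$messages <- c(report$messages,
                           sprintf("entry %d (line %d): %s", i,
                                   entryStart[i], e))
      next
    }
    report$parsed <- report$parsed + 1L
    acc <- c(acc, e$accession); name <- c(name, e$name)
    org <- c(org, e$organism); seqs <- c(seqs, e$sequence)
    taxid <- c(taxid, e$taxon_id)
    if (nrow(e$features)) featList[[length(featList) + 1L]] <- e$features
  }
  if (anyDuplicated(acc))
    stop(sprintf("duplicate accession(s) in file: %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  features <- if (length(featList)) do.call(rbind, featList)
              else emptyFeatureTable()
  proteinSet(accession = acc, name = name, organism = org, sequence = seqs,
             taxon_id = taxid, reviewed = NA, features = features,
             source = "genpept_gpff", parseReport = report)
}

parseGenPeptEntry <- function(lines) {
  key <- sub("\\s.*$", "", substr(lines, 1L, 12L))

  getMultiline <- function(kw) {
    at <- which(startsWith(lines, kw))
    if (!length(at)) return(NA_character_)
    out <- trimws(sub(kw, "", lines[[at[[1L]]]], fixed = TRUE))
    j <- at[[1L]] + 1L
    while (j <= length(lines) && grepl("^\\s{10,}\\S", lines[[j]]) &&
           !startsWith(lines[[j]], "FEATURES")) {
      out <- paste(out, trimws(lines[[j]]))
      j <- j + 1L
    }
    out
  }

  versionLine <- grep("^VERSION", lines, value = TRUE)
  accessionLine <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(versionLine))
    strsplit(trimws(sub("^VERSION", "", versionLine[[1L]])), "\\s+")[[1L]][1L]
  else if (length(accessionLine))
    strsplit(trimws(sub("^ACCESSION", "", accessionLine[[1L]])), "\\s+")[[1L]][1L]
  else NA_character_
  if (is.na(accession) || !nzchar(accession))
    stop("missing accession (VERSION/ACCESSION line)")

  name <- getMultiline("DEFINITION")
  if (is.na(name)) name <- accession
  name <- sub("\\.$", "", name)
  # RefSeq definitions end with the bracketed organism; keep it out of name
  name <- trimws(sub("\\s*\\[[^]]*\\]$", "", name))

  orgLine <- grep("^\\s+ORGANISM", lines, value = TRUE)
  organism <- if (length(orgLine))
    trimws(sub("^\\s+ORGANISM", "", orgLine[[1L]])) else NA_character_

  taxon_id <- NA_integer_
  m <- regmatches(lines, regexec("/db_xref=\"taxon:(\\d+)\"", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) taxon_id <- as.integer(m[[hit[[1L]]]][[2L]])

  originAt <- grep("^ORIGIN", lines)
  if (!length(originAt)) stop("missing sequence block (ORIGIN line)")
  seqLines <- lines[seq(originAt[[1L]] + 1L, length(lines))]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence block")
  if (grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence))
    stop("unparseable sequence block: letters outside the allowed alphabet")

  # FEATURES table: key lines are indented 5 columns, qualifiers 21.
  featAt <- grep("^FEATURES", lines)
  feats <- list()
  if (length(featAt)) {
    j <- featAt[[1L]] + 1L
    cur <- NULL
    flush <- function(cur, feats) {
      if (is.null(cur) || cur$key == "source") return(feats)
      pos <- parseFtLocation(cur$loc)
      if (is.null(pos)) return(feats)
      kind <- mapFeatureKind(cur$key, "genpept")
      quals <- tolower(paste(cur$quals, collapse = " "))
      if (cur$key == "Site" && grepl("glycosyl", quals)) kind <- "glyco"
      desc <- if (length(cur$quals)) cur$quals[[1L]] else ""
      feats[[length(feats) + 1L]] <- data.frame(
        accession = accession, kind = kind,
        start = pos[[1L]], end = pos[[2L]],
        description = desc, source_key = cur$key,
        stringsAsFactors = FALSE)
      feats
    }
    while (j <= length(lines) && !grepl("^\\S", lines[[j]])) {
      ln <- lines[[j]]
      if (grepl("^\\s{1,10}\\S", ln)) {          # feature key line
        feats <- flush(cur, feats)
        parts <- strsplit(trimws(ln), "\\s+")[[1L]]
        cur <- list(key = parts[[1L]],
                    loc = if (length(parts) > 1L) parts[[2L]] else "",
                    quals = character())
      } else if (!is.null(cur)) {
        q <- trimws(ln)
        m <- regmatches(q, regexec("^/(?:site_type|note|name)=\"(.*)\"$", q))[[1L]]
        if (length(m) == 2L) cur$quals <- c(cur$quals, m[[2L]])
        else if (startsWith(q, "/")) cur$quals <- c(cur$quals, sub("^/", "", q))
      }
      j <- j + 1L
    }
    feats <- flush(cur, feats)
  }
  features <- if (length(feats)) do.call(rbind, feats) else emptyFeatureTable()
  if (nrow(features) && any(features$end > nchar(sequence)))
    stop("feature interval extends beyond the sequence")

  list(accession = accession, name = name, organism = organism,
       taxon_id = taxon_id, sequence = sequence, features = features)
}

#' Parse a protein FASTA file
#'
#' Reads protein FASTA with the header interpreted per dialect: `"uniprot"`
#' (`db|ACCESSION|ENTRY description`), `"refseq"` (accession-first, optional
#' trailing `[organism]`), or `"generic"` (first whitespace-delimited token
#' is the accession). FASTA carries no feature table, so the feature list is
#' always empty. Sequences are upper-cased and `*` terminators stripped; any
#' remaining letter outside the allowed alphabet is an error naming the
#' record.
#'
#' @inheritParams readUniProt
#' @param dialect `"uniprot"`, `"refseq"` or `"generic"`.
#' @return A [ProteinSet-class].
#' @examples
#' readProteinFasta(">sp|P99999|TEST Synthetic\nACDEFGHIK", "uniprot")
#' @export
readProteinFasta <- function(file, dialect = c("generic", "uniprot", "refseq")) {
  dialect <- match.arg(dialect)
  lines <- asLines(file)
  if (!any(nzchar(trimws(lines))))
    return(proteinSet(accession = character(), sequence = character(),
                      source = "fasta",
                      parseReport = newParseReport()))
  # Records are split on the raw text so that disallowed letters are caught
  # and reported (Biostrings drops invalid codes silently on read).
  hdrAt <- which(startsWith(lines, ">"))
  if (!length(hdrAt)) stop("not a FASTA file: no '>' header line")
  headers <- sub("^>", "", lines[hdrAt])
  bounds <- c(hdrAt, length(lines) + 1L)
  sequence <- vapply(seq_along(hdrAt), function(i) {
    if (bounds[[i]] + 1L > bounds[[i + 1L]] - 1L) return("")
    block <- lines[seq(bounds[[i]] + 1L, bounds[[i + 1L]] - 1L)]
    gsub("\\s", "", paste(block, collapse = ""))
  }, character(1L))
  sequence <- gsub("\\*", "", toupper(sequence))

  accession <- name <- organism <- character(length(headers))
  taxid <- rep(NA_integer_, length(headers))
  reviewed <- rep(NA, length(headers))
  for (i in seq_along(headers)) {
    h <- headers[[i]]
    first <- sub("\\s.*$", "", h)
    desc <- trimws(sub("^\\S+\\s*", "", h))
    if (dialect == "uniprot" && grepl("^[a-z]+\\|[^|]+\\|", first)) {
      parts <- strsplit(first, "|", fixed = TRUE)[[1L]]
      accession[[i]] <- parts[[2L]]
      reviewed[[i]] <- parts[[1L]] == "sp"
      # strip UniProt OS=/OX=/GN= blocks from the description
      m <- regmatches(desc, regexec("OS=([^=]+?)\\s+[A-Z]{2}=", desc))[[1L]]
      organism[[i]] <- if (length(m) == 2L) trimws(m[[2L]]) else NA_character_
      mox <- regmatches(desc, regexec("OX=(\\d+)", desc))[[1L]]
      if (length(mox) == 2L) taxid[[i]] <- as.integer(mox[[2L]])
      desc <- trimws(sub("\\s+[A-Z]{2}=.*$", "", desc))
      name[[i]] <- if (nzchar(desc)) desc else parts[[3L]]
    } else if (dialect == "refseq") {
      accession[[i]] <- first
      m <- regmatches(desc, regexec("\\[([^]]*)\\]\\s*$", desc))[[1L]]
      organism[[i]] <- if (length(m) == 2L) m[[2L]] else NA_character_
      desc <- trimws(sub("\\s*\\[[^]]*\\]\\s*$", "", desc))
      name[[i]] <- if (nzchar(desc)) desc else first
    } else {
      accession[[i]] <- first
      organism[[i]] <- NA_character_
      name[[i]] <- if (nzchar(desc)) desc else first
    }
    bad <- gsub(sprintf("[%s]", paste(AA_ALLOWED, collapse = "")), "",
                sequence[[i]])
    if (nzchar(bad))
      stop(sprintf("record '%s': sequence contains disallowed letter(s) %s",
                   accession[[i]],
                   paste(unique(strsplit(bad, "")[[1L]]), collapse = ", ")))
  }
  report <- newParseReport()
  report$parsed <- length(accession)
  proteinSet(accession = accession, name = name, organism = organism,
             sequence = sequence, taxon_id = taxid, reviewed = reviewed,
             source = "fasta", parseReport = report)
}

#' Dispatch a proteome file to the right parser
#'
#' @inheritParams readUniProt
#' @param format `"uniprot"`, `"genpept"`, `"fasta"`, `"fasta-uniprot"` or
#'   `"fasta-refseq"`.
#' @return A [ProteinSet-class].
#' @export
readProteome <- function(file, format = c("uniprot", "genpept", "fasta",
                                          "fasta-uniprot", "fasta-refseq")) {
  format <- match.arg(format)
  switch(format,
         uniprot = readUniProt(file),
         genpept = readGenPept(file),
         fasta = readProteinFasta(file, "generic"),
         `fasta-uniprot` = readProteinFasta(file, "uniprot"),
         `fasta-refseq` = readProteinFasta(file, "refseq"))
}
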