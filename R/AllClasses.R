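#' @import methods
#' @importFrom Biostrings AAStringSet width
#' @importClassesFrom Biostrings AAStringSet
NULL

setOldClass("data.table")

#' Digestion parameters
#'
#' Parameters controlling in-silico proteolytic digestion: the enzyme, the
#' number of allowed missed cleavages, the minimal peptide length retained at
#' database build time, and whether the proline rule (no cleavage C-terminal
#' to K/R when the next residue is proline) is applied.
#'
#' @slot enzyme one of `"trypsin"`, `"lysc"`, `"argc"`, `"lysn"`.
#' @slot maxMissedCleavages integer, 0--2.
#' @slot minPeptideLength integer >= 1. Database builds conventionally use
#'   3--5 to limit database size; 1 disables the length cut.
#' @slot prolineRule logical; applies to trypsin/Lys-C/Arg-C only (Lys-N
#'   cleaves N-terminally to lysine and has no proline suppression).
#'
#' @examples
#' digestionParams(enzyme = "trypsin", maxMissedCleavages = 2L)
#' @export
setClass("DigestionParams",
         representation(enzyme = "character",
                        maxMissedCleavages = "integer",
                        minPeptideLength = "integer",
                        prolineRule = "logical"))

setValidity("DigestionParams", function(object) {
  msg <- character()
  if (length(object@enzyme) != 1L || !object@enzyme %in% ENZYMES)
    msg <- c(msg, sprintf("enzyme must be one of: %s",
                          paste(ENZYMES, collapse = ", ")))
  if (length(object@maxMissedCleavages) != 1L ||
      is.na(object@maxMissedCleavages) ||
      object@maxMissedCleavages < 0L || object@maxMissedCleavages > 2L)
    msg <- c(msg, "maxMissedCleavages must be in [0, 2]")
  if (length(object@minPeptideLength) != 1L ||
      is.na(object@minPeptideLength) || object@minPeptideLength < 1L)
    msg <- c(msg, "minPeptideLength must be >= 1")
  if (length(object@prolineRule) != 1L || is.na(object@prolineRule))
    msg <- c(msg, "prolineRule must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @param enzyme,maxMissedCleavages,minPeptideLength,prolineRule see slots.
#' @rdname DigestionParams-class
#' @export
digestionParams <- function(enzyme = "trypsin",
                            maxMissedCleavages = 0L,
                            minPeptideLength = 3L,
                            prolineRule = TRUE) {
  new("DigestionParams",
      enzyme = enzyme,
      maxMissedCleavages = as.integer(maxMissedCleavages),
      minPeptideLength = as.integer(minPeptideLength),
      prolineRule = prolineRule)
}

setMethod("show", "DigestionParams", function(object) {
  cat(sprintf(
    "DigestionParams: enzyme=%s, maxMissedCleavages=%d, minPeptideLength=%d, prolineRule=%s\n",
    object@enzyme, object@maxMissedCleavages, object@minPeptideLength,
    object@prolineRule))
})

#' Set of protein records parsed from a proteome database file
#'
#' Container for protein entries: per-protein metadata, amino-acid
#' sequences as an [Biostrings::AAStringSet], and a feature table holding the
#' sequence annotations (PTM sites, variants, conflicts, signal peptides,
#' isoform-variable regions) lifted from the source database.
#'
#' @slot proteins data.frame with columns `accession`, `name`, `organism`,
#'   `taxon_id`, `reviewed`.
#' @slot sequences [Biostrings::AAStringSet] named by accession, parallel to
#'   `proteins`.
#' @slot features data.frame with columns `accession`, `kind`, `start`,
#'   `end`, `description`, `source_key`; coordinates are 1-based inclusive.
#' @slot source character, the dialect the records were parsed from
#'   (`"uniprot_dat"`, `"genpept_gpff"`, `"fasta"`, or `"memory"`).
#' @slot parseReport list with elements `parsed`, `skipped`, `messages`.
#'
#' @export
setClass("ProteinSet",
         representation(proteins = "data.frame",
                        sequences = "AAStringSet",
                        features = "data.frame",
                        source = "character",
                        parseReport = "list"))

setValidity("ProteinSet", function(object) {
  msg <- character()
  p <- object@proteins
  need <- c("accession", "name", "organism", "taxon_id", "reviewed")
  if (!all(need %in% names(p)))
    return(sprintf("proteins table must have columns: %s",
                   paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(p))
    msg <- c(msg, "sequences and proteins table differ in length")
  if (nrow(p)) {
    if (anyNA(p$accession) || any(!nzchar(p$accession)))
      msg <- c(msg, "accessions must be non-empty")
    dup <- p$accession[duplicated(p$accession)]
    if (length(dup))
      msg <- c(msg, sprintf("duplicate accession(s): %s",
                            paste(unique(dup), collapse = ", ")))
    if (!identical(names(object@sequences), p$accession))
      msg <- c(msg, "sequence names must equal the accession column")
    seqs <- as.character(object@sequences)
    if (any(!nzchar(seqs)))
      msg <- c(msg, "sequences must be non-empty")
    bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
    if (any(bad))
      msg <- c(msg, sprintf("sequence of %s contains letters outside the allowed alphabet",
                            paste(p$accession[bad], collapse = ", ")))
  }
  ft <- object@features
  needf <- c("accession", "kind", "start", "end", "description", "source_key")
  if (!all(needf %in% names(ft)))
    return(sprintf("features table must have columns: %s",
                   paste(needf, collapse = ", ")))
  if (nrow(ft)) {
    if (any(!ft$kind %in% FEATURE_KINDS))
      msg <- c(msg, "unknown feature kind")
    if (any(ft$start < 1L) || any(ft$end < ft$start))
      msg <- c(msg, "feature intervals must satisfy 1 <= start <= end")
    if (any(!ft$accession %in% p$accession))
      msg <- c(msg, "feature accession not present in proteins table")
    len <- setNames(Biostrings::width(object@sequences), p$accession)
    if (any(ft$end > len[ft$accession]))
      msg <- c(msg, "feature interval extends beyond its protein sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSet from vectors
#'
#' @param accession,name,organism character vectors, recycled to the same
#'   length; `accession` must be unique.
#' @param sequence character vector of amino-acid sequences (upper-cased on
#'   input).
#' @param taxon_id optional integer vector.
#' @param reviewed optional logical vector (SwissProt vs TrEMBL status).
#' @param features feature table (see the class slot), or NULL for none.
#' @param source source dialect label.
#' @param parseReport parse report list.
#' @return A [ProteinSet-class] object.
#' @examples
#' proteinSet("P00001", "Toy protein", "Homo sapiens", "AAAKGGGR")
#' @export
proteinSet <- function(accession, name = accession, organism = NA_character_,
                       sequence, taxon_id = NA_integer_, reviewed = NA,
                       features = NULL, source = "memory",
                       parseReport = list(parsed = length(accession),
                                          skipped = 0L,
                                          messages = character())) {
  n <- length(accession)
  proteins <- data.frame(accession = as.character(accession),
                         name = rep_len(as.character(name), n),
                         organism = rep_len(as.character(organism), n),
                         taxon_id = rep_len(as.integer(taxon_id), n),
                         reviewed = rep_len(as.logical(reviewed), n),
                         stringsAsFactors = FALSE)
  sequence <- toupper(as.character(sequence))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence)
  if (any(bad))
    stop(sprintf("sequence of %s contains letters outside the allowed alphabet",
                 paste(proteins$accession[bad], collapse = ", ")))
  seqs <- Biostrings::AAStringSet(sequence)
  names(seqs) <- proteins$accession
  if (is.null(features)) features <- emptyFeatureTable()
  new("ProteinSet", proteins = proteins, sequences = seqs,
      features = features, source = source, parseReport = parseReport)
}

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet of %d protein(s) [source: %s]\n",
              nrow(object@proteins), object@source))
  if (nrow(object@proteins)) {
    head_n <- utils::head(object@proteins$accession, 5L)
    cat(sprintf("  accessions: %s%s\n", paste(head_n, collapse = ", "),
                if (nrow(object@proteins) > 5L) ", ..." else ""))
  }
  cat(sprintf("  features: %d\n", nrow(object@features)))
})

setMethod("length", "ProteinSet", function(x) nrow(x@proteins))

#' Peptide database (index) over one digested proteome
#'
#' Holds the digest of a whole proteome: the proteins table, the distinct
#' peptide table with aggregate hit counts, and the occurrence table mapping
#' each peptide to every (protein, start, end) where it occurs, with
#' annotation flags remapped from the protein features to the peptide level.
#' Built with [buildPeptideIndex()] and persisted with [savePeptideIndex()].
#'
#' @slot metadata list: `label`, `source`, `dialect`, `params`
#'   (the [DigestionParams-class] used), `collapseIL`, `built` (timestamp),
#'   `format_version`.
#' @slot proteins data.frame: `accession`, `name`, `organism`, `length`,
#'   `sequence`.
#' @slot peptides data.table keyed by `pepkey`: `sequence`, `length`, `mass`
#'   (NA for peptides with nonstandard residues), `total_occurrences`,
#'   `distinct_proteins`.
#' @slot occurrences data.table keyed by `pepkey`: `sequence`, `accession`,
#'   `start`, `end`, `missed_cleavages` and the six annotation flags.
#'
#' @export
setClass("PeptideIndex",
         representation(metadata = "list",
                        proteins = "data.frame",
                        peptides = "data.table",
                        occurrences = "data.table"))

setMethod("show", "PeptideIndex", function(object) {
  md <- object@metadata
  cat(sprintf("PeptideIndex '%s' (%d proteins, %d distinct peptides, %d occurrences)\n",
              md$label, nrow(object@proteins), nrow(object@peptides),
              nrow(object@occurrences)))
  show(md$params)
  cat(sprintf("  I/L collapsed for matching: %s\n", isTRUE(md$collapseIL)))
})

#' Peptide selection filters
#'
#' The filter set applied to candidate surrogate peptides. Defaults follow
#' the advised values for targeted (SRM) assay design: length 5--22 residues,
#' no methionine or cysteine, no missed cleavages, no overlap with PTM /
#' variant / conflict / signal-peptide annotations and no nonstandard
#' residues, exactly one hit in the foreground proteome, and zero hits in the
#' background proteome when one is queried.
#'
#' @slot minLength,maxLength numeric length window in residues.
#' @slot excludedResidues character vector of forbidden amino-acid letters.
#' @slot maxMissedCleavages numeric, maximum missed cleavages accepted.
#' @slot requireUniqueFg logical; require uniqueness in the foreground.
#' @slot uniqueBy `"occurrences"` (default: exactly one hit, so a peptide
#'   repeated inside one protein fails) or `"proteins"` (one distinct
#'   protein suffices).
#' @slot maxBgOccurrences numeric, maximum allowed background hits.
#' @slot excludeFlags character vector of annotation flags that reject a
#'   peptide (subset of `has_ptm`, `has_variant`, `has_conflict`,
#'   `in_signal`, `isoform_variable`, `nonstandard`).
#' @slot mzWindow empty list (off) or `list(low=, high=, charges=)`; a
#'   peptide passes when any charge in `charges` puts its m/z inside
#'   `[low, high]`.
#'
#' @examples
#' filterConfig()                       # advised defaults
#' uniquenessFilter()                   # uniqueness constraints only
#' @export
setClass("FilterConfig",
         representation(minLength = "numeric",
                        maxLength = "numeric",
                        excludedResidues = "character",
                        maxMissedCleavages = "numeric",
                        requireUniqueFg = "logical",
                        uniqueBy = "character",
                        maxBgOccurrences = "numeric",
                        excludeFlags = "character",
                        mzWindow = "list"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@minLength < 1 || object@minLength > object@maxLength)
    msg <- c(msg, "need 1 <= minLength <= maxLength")
  if (object@maxBgOccurrences < 0)
    msg <- c(msg, "maxBgOccurrences must be >= 0")
  if (!object@uniqueBy %in% c("occurrences", "proteins"))
    msg <- c(msg, "uniqueBy must be 'occurrences' or 'proteins'")
  if (length(object@excludeFlags) &&
      !all(object@excludeFlags %in% FLAG_COLUMNS))
    msg <- c(msg, "unknown flag name in excludeFlags")
  if (length(object@mzWindow) &&
      !all(c("low", "high", "charges") %in% names(object@mzWindow)))
    msg <- c(msg, "mzWindow must be empty or have low, high, charges")
  if (length(msg)) msg else TRUE
})

#' @param minLength,maxLength,excludedResidues,maxMissedCleavages see slots.
#' @param requireUniqueFg,uniqueBy,maxBgOccurrences,excludeFlags,mzWindow
#'   see slots.
#' @rdname FilterConfig-class
#' @export
filterConfig <- function(minLength = 5,
                         maxLength = 22,
                         excludedResidues = c("M", "C"),
                         maxMissedCleavages = 0,
                         requireUniqueFg = TRUE,
                         uniqueBy = "occurrences",
                         maxBgOccurrences = 0,
                         excludeFlags = c("has_ptm", "has_variant",
                                          "has_conflict", "in_signal",
                                          "nonstandard"),
                         mzWindow = list()) {
  new("FilterConfig", minLength = minLength, maxLength = maxLength,
      excludedResidues = excludedResidues,
      maxMissedCleavages = maxMissedCleavages,
      requireUniqueFg = requireUniqueFg, uniqueBy = uniqueBy,
      maxBgOccurrences = maxBgOccurrences, excludeFlags = excludeFlags,
      mzWindow = mzWindow)
}

#' @rdname FilterConfig-class
#' @export
uniquenessFilter <- function() {
  filterConfig(minLength = 1, maxLength = Inf, excludedResidues = character(),
               maxMissedCleavages = Inf, requireUniqueFg = TRUE,
               maxBgOccurrences = 0, excludeFlags = character())
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf("FilterConfig: length %s-%s", object@minLength,
              object@maxLength))
  cat(sprintf(", exclude {%s}", paste(object@excludedResidues, collapse = ",")))
  cat(sprintf(", missed <= %s", object@maxMissedCleavages))
  if (object@requireUniqueFg)
    cat(sprintf(", unique fg by %s", object@uniqueBy))
  cat(sprintf(", bg <= %s", object@maxBgOccurrences))
  if (length(object@excludeFlags))
    cat(sprintf(", flags: %s", paste(object@excludeFlags, collapse = ",")))
  if (length(object@mzWindow))
    cat(sprintf(", m/z %g-%g z{%s}", object@mzWindow$low, object@mzWindow$high,
                paste(object@mzWindow$charges, collapse = ",")))
  cat("\n")
})
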