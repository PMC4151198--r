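#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `accessions()`
#' returns the protein accessions, `proteinInfo()` the per-protein metadata
#' table, `proteinFeatures()` the feature table, `proteinSequences()` the
#' sequences, `digestionParams()` used as an accessor returns the parameters
#' an index was built with, and `indexMetadata()` the full metadata list.
#'
#' @param x a [ProteinSet-class] or [PeptideIndex-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname accessors
#' @export
setGeneric("proteinInfo", function(x) standardGeneric("proteinInfo"))

#' @rdname accessors
#' @export
setGeneric("proteinFeatures", function(x) standardGeneric("proteinFeatures"))

#' @rdname accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname accessors
#' @export
setGeneric("indexMetadata", function(x) standardGeneric("indexMetadata"))

#' @rdname accessors
#' @export
setGeneric("indexParams", function(x) standardGeneric("indexParams"))

#' Count hits of peptide sequences in a peptide index
#'
#' Exact-match lookup of peptide sequences against the stored digest peptide
#' set (not a substring search of the protein sequences). Returns, for every
#' query sequence, the total number of occurrences (protein x position) and
#' the number of distinct proteins carrying it; both are zero when the
#' peptide is absent from the digest.
#'
#' @param index a [PeptideIndex-class].
#' @param sequence character vector of peptide sequences (upper-cased
#'   internally). If the index was built with `collapseIL = TRUE`, queries
#'   are matched with I and L collapsed as well.
#' @return data.frame with columns `sequence`, `total_occurrences`,
#'   `distinct_proteins`, one row per query in input order.
#' @examples
#' ps <- proteinSet("P1", "toy", "synthetic", "AAAKGGGR")
#' idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "toy")
#' countHits(idx, c("AAAK", "MISSING"))
#' @export
setGeneric("countHits", function(index, sequence) standardGeneric("countHits"))

setMethod("accessions", "ProteinSet", function(x) x@proteins$accession)
setMethod("accessions", "PeptideIndex", function(x) x@proteins$accession)
setMethod("proteinInfo", "ProteinSet", function(x) x@proteins)
setMethod("proteinInfo", "PeptideIndex", function(x) x@proteins)
setMethod("proteinFeatures", "ProteinSet", function(x) x@features)
setMethod("proteinSequences", "ProteinSet", function(x) x@sequences)
setMethod("indexMetadata", "PeptideIndex", function(x) x@metadata)
setMethod("indexParams", "PeptideIndex", function(x) x@metadata$params)
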