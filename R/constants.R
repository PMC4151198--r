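# Amino-acid alphabets, monoisotopic masses, and the feature-key mapping
# tables shared across the parsing, digestion and indexing code.

#' Amino-acid alphabets
#'
#' `AA_STANDARD` holds the 20 standard amino-acid one-letter codes.
#' `AA_NONSTANDARD` holds the additional letters accepted in database
#' sequences: B (Asx), Z (Glx), X (unknown), U (selenocysteine),
#' O (pyrrolysine). Peptides containing any of the latter are flagged
#' `nonstandard`: they are never cleavage sites and have no defined
#' monoisotopic mass.
#'
#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_STANDARD
#' @keywords internal
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O")

AA_ALLOWED <- c(AA_STANDARD, AA_NONSTANDARD)

# Monoisotopic residue masses in Da (residue = amino acid minus water).
AA_MONO_MASS <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048508, H = 137.05891185,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294
)

MASS_WATER  <- 18.01056468
MASS_PROTON <- 1.007276

# Feature kinds recognised at the peptide level.
FEATURE_KINDS <- c("ptm", "glyco", "variant_snp", "conflict",
                   "signal_peptide", "isoform_variable", "other")

# Fixed, versioned mapping from UniProt feature-table keys to feature kinds.
# Unknown keys map to "other" and are retained, never dropped.
UNIPROT_FEATURE_KEY_MAP <- c(
  MOD_RES  = "ptm",
  CARBOHYD = "glyco",
  LIPID    = "ptm",
  CROSSLNK = "ptm",
  VARIANT  = "variant_snp",
  CONFLICT = "conflict",
  SIGNAL   = "signal_peptide",
  VAR_SEQ  = "isoform_variable"
)

# GenPept feature keys routed through the same kind vocabulary. "Site"
# features are refined by their qualifiers (see parse code): glycosylation
# sites become "glyco", all other annotated sites "ptm".
GENPEPT_FEATURE_KEY_MAP <- c(
  Site            = "ptm",
  sig_peptide     = "signal_peptide",
  variation       = "variant_snp",
  misc_difference = "conflict",
  Region          = "other"
)

# Preferred rendering key for each feature kind (used when writing UniProt
# flat text from records whose source key is unknown).
KIND_TO_UNIPROT_KEY <- c(
  ptm              = "MOD_RES",
  glyco            = "CARBOHYD",
  variant_snp      = "VARIANT",
  conflict         = "CONFLICT",
  signal_peptide   = "SIGNAL",
  isoform_variable = "VAR_SEQ",
  other            = "SITE"
)

# Which occurrence-level flag each feature kind raises when it overlaps a
# peptide. "other" features are stored with the protein but raise no flag.
KIND_TO_FLAG <- c(
  ptm              = "has_ptm",
  glyco            = "has_ptm",
  variant_snp      = "has_variant",
  conflict         = "has_conflict",
  signal_peptide   = "in_signal",
  isoform_variable = "isoform_variable"
)

FLAG_COLUMNS <- c("has_ptm", "has_variant", "has_conflict", "in_signal",
                  "isoform_variable", "nonstandard")

ENZYMES <- c("trypsin", "lysc", "argc", "lysn")

INDEX_FORMAT_VERSION <- 1L

mapFeatureKind <- function(source_key, dialect = c("uniprot", "genpept")) {
  dialect <- match.arg(dialect)
  map <- switch(dialect,
                uniprot = UNIPROT_FEATURE_KEY_MAP,
                genpept = GENPEPT_FEATURE_KEY_MAP)
  kind <- unname(map[source_key])
  kind[is.na(kind)] <- "other"
  kind
}

emptyFeatureTable <- function() {
  data.frame(accession = character(), kind = character(),
             start = integer(), end = integer(),
             description = character(), source_key = character(),
             stringsAsFactors = FALSE)
}
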