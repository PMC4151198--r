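Package: SurrogatePeptides
Title: Peptide Database Construction and Surrogate Peptide Selection for
    Targeted Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds searchable peptide databases from whole-proteome protein
    databases (UniProt flat text, RefSeq GenPept, FASTA) by in-silico
    proteolytic digestion (trypsin, Lys-C, Arg-C, Lys-N) with missed-cleavage
    enumeration, remaps protein-level sequence annotations (PTM sites,
    variants, conflicts, signal peptides, isoform-variable regions) to the
    peptide level, and answers uniqueness queries that select surrogate
    peptides unique within a proteome of interest and absent from a
    host/background proteome, as needed for targeted-proteomics (SRM) assay
    design on mixed-species samples such as xenografts. Includes a synthetic
    two-species proteome generator with planted ground truth, CSV export of
    selection results, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
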