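test_that("UniProt flat entries parse with mapped features", {
  ps <- readUniProt(miniUniProtEntry(ftLines = c(
    "FT   MOD_RES         5",
    "FT                   /note=\"Phosphoserine\"")))
  expect_identical(length(ps), 1L)
  info <- proteinInfo(ps)
  expect_identical(info$accession, "P00001")
  expect_identical(info$name, "Toy protein")
  expect_identical(info$organism, "Synthetica prima")
  expect_identical(info$taxon_id, 900001L)
  expect_true(info$reviewed)
  ft <- proteinFeatures(ps)
  expect_identical(ft$kind, "ptm")
  expect_identical(ft$start, 5L)
  expect_identical(ft$end, 5L)
  expect_identical(ft$description, "Phosphoserine")

  ps <- readUniProt(miniUniProtEntry(ftLines = "FT   CONFLICT        3..4"))
  ft <- proteinFeatures(ps)
  expect_identical(ft[, c("kind", "start", "end")],
                   data.frame(kind = "conflict", start = 3L, end = 4L))
})

test_that("the feature-key map covers the documented keys and keeps unknown ones", {
  keys <- c("MOD_RES", "CARBOHYD", "LIPID", "CROSSLNK", "VARIANT",
            "CONFLICT", "SIGNAL", "VAR_SEQ", "HELIX")
  ftLines <- as.vector(rbind(sprintf("FT   %-15s 2..3", keys)))
  ps <- readUniProt(miniUniProtEntry(ftLines = ftLines))
  ft <- proteinFeatures(ps)
  expect_identical(ft$kind[match(keys, ft$source_key)],
                   c("ptm", "glyco", "ptm", "ptm", "variant_snp", "conflict",
                     "signal_peptide", "isoform_variable", "other"))
  expect_identical(nrow(ft), length(keys))   # unknown keys retained
})

test_that("multi-entry files parse in order; duplicates and corruption are errors", {
  n <- 7L
  entries <- unlist(lapply(seq_len(n), function(i)
    miniUniProtEntry(acc = sprintf("P%05d", i))))
  ps <- readUniProt(entries)
  expect_identical(length(ps), n)
  expect_identical(accessions(ps), sprintf("P%05d", seq_len(n)))

  dup <- c(miniUniProtEntry("P11111"), miniUniProtEntry("P11111"))
  expect_error(readUniProt(dup), "duplicate")

  unterminated <- miniUniProtEntry("P22222")
  unterminated <- unterminated[-length(unterminated)]
  expect_error(readUniProt(unterminated), "unterminated")

  expect_identical(length(readUniProt(character())), 0L)
})

test_that("malformed entries are skipped and reported, not fatal", {
  bad <- miniUniProtEntry("P33333")
  bad <- bad[!startsWith(bad, "SQ") & !startsWith(bad, "     ")]
  text <- c(miniUniProtEntry("P44444"), bad)
  ps <- readUniProt(text)
  expect_identical(accessions(ps), "P44444")
  expect_identical(ps@parseReport$parsed, 1L)
  expect_identical(ps@parseReport$skipped, 1L)
  expect_match(ps@parseReport$messages, "sequence")
  rf <- tempfile()
  writeParseReport(ps, rf)
  expect_match(paste(readLines(rf), collapse = "\n"), "skipped: 1")
})

test_that("GenPept entries parse with Site features mapped to ptm", {
  gp <- function(acc, seq, feats = character()) c(
    sprintf("LOCUS       %s  %d aa  linear", acc, nchar(seq)),
    sprintf("DEFINITION  toy protein %s [Mus musculus].", acc),
    sprintf("ACCESSION   %s", acc),
    sprintf("VERSION     %s.1", acc),
    "SOURCE      Mus musculus",
    "  ORGANISM  Mus musculus",
    "FEATURES             Location/Qualifiers",
    "     source          1..10",
    "                     /db_xref=\"taxon:10090\"",
    feats,
    "ORIGIN",
    paste0("        1 ", tolower(seq)),
    "//")

  ps <- readGenPept(gp("NP_000010", "MAAAKGGGRK"))
  expect_identical(length(ps), 1L)
  expect_identical(accessions(ps), "NP_000010.1")
  expect_identical(seqsOf(ps), "MAAAKGGGRK")
  expect_identical(proteinInfo(ps)$taxon_id, 10090L)
  expect_identical(nrow(proteinFeatures(ps)), 0L)

  ps <- readGenPept(gp("NP_000011", "MAAAKGGGRK", c(
    "     Site            7",
    "                     /site_type=\"phosphorylation\"")))
  ft <- proteinFeatures(ps)
  expect_identical(ft[, c("kind", "start", "end")],
                   data.frame(kind = "ptm", start = 7L, end = 7L))

  two <- c(gp("NP_000012", "MAAAKGGGRK"), gp("NP_000013", "MTTTKGGGRK"))
  ps <- readGenPept(two)
  expect_identical(accessions(ps), c("NP_000012.1", "NP_000013.1"))
})

test_that("FASTA dialects parse headers correctly and validate the alphabet", {
  ps <- readProteinFasta(">sp|P99999|TEST Synthetic\nACDEFGHIK", "uniprot")
  expect_identical(accessions(ps), "P99999")
  expect_identical(seqsOf(ps), "ACDEFGHIK")
  expect_identical(nrow(proteinFeatures(ps)), 0L)
  expect_true(proteinInfo(ps)$reviewed)

  ps <- readProteinFasta(">acc1 some description\nacdef", "generic")
  expect_identical(accessions(ps), "acc1")
  expect_identical(seqsOf(ps), "ACDEF")

  ps <- readProteinFasta(">NP_01.1 keratin [Mus musculus]\nMKTR*", "refseq")
  expect_identical(accessions(ps), "NP_01.1")
  expect_identical(proteinInfo(ps)$organism, "Mus musculus")
  expect_identical(seqsOf(ps), "MKTR")

  expect_identical(length(readProteinFasta("", "generic")), 0L)
  expect_error(readProteinFasta(">acc1\nAC1DEF", "generic"), "acc1")
})

test_that("FASTA rendering of a flat file matches the flat-file parse", {
  set.seed(31)
  out <- generateProteomePair(fixtureSpec(nProteinsFg = 5L, nProteinsBg = 3L,
                                          meanProteinLength = 80L,
                                          nPlantedUnique = 3L, seed = 31L),
                              withr::local_tempdir())
  flat <- readUniProt(out$files$fg_dat)
  fasta <- readProteinFasta(out$files$fg_fasta, "generic")
  expect_identical(accessions(fasta), accessions(flat))
  expect_identical(seqsOf(fasta),
                   seqsOf(flat))
  expect_identical(nrow(proteinFeatures(fasta)), 0L)
})

test_that("record validity enforces alphabet, uniqueness and feature bounds", {
  expect_error(proteinSet("P1", sequence = "AC1DEF"), "alphabet")
  expect_error(proteinSet(c("P1", "P1"), sequence = c("ACDEF", "ACDEF")),
               "duplicate")
  ft <- data.frame(accession = "P1", kind = "ptm", start = 4L, end = 99L,
                   description = "", source_key = "MOD_RES")
  expect_error(proteinSet("P1", sequence = "ACDEF", features = ft),
               "beyond")
})
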