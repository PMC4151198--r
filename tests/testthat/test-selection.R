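relaxed <- function(...) {
  f <- filterConfig(minLength = 1, maxLength = Inf,
                    excludedResidues = character(),
                    maxMissedCleavages = Inf, requireUniqueFg = TRUE,
                    maxBgOccurrences = 0, excludeFlags = character())
  overrides <- list(...)
  for (nm in names(overrides)) slot(f, nm) <- overrides[[nm]]
  validObject(f)
  f
}

pairIndexes <- function(seed = 11L, shared = 0.4, planted = 6L,
                        params = digestionParams(minPeptideLength = 1L)) {
  out <- generateProteomePair(
    fixtureSpec(nProteinsFg = 8L, nProteinsBg = 8L, meanProteinLength = 100L,
                sharedFragmentFraction = shared, nPlantedUnique = planted,
                seed = seed),
    withr::local_tempdir(.local_envir = parent.frame()))
  list(fg = buildPeptideIndex(out$fg, params, "fg"),
       bg = buildPeptideIndex(out$bg, params, "bg"),
       truth = out$truth, records = out)
}

test_that("accession queries return peptide rows with hit counts", {
  ps <- proteinSet("P1", "toy", "syn", "AAAKGGGR")
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  rows <- queryAccession(idx, "P1", relaxed())
  expect_identical(rows$peptide_sequence, c("AAAK", "GGGR"))
  expect_identical(rows$fg_total_occurrences, c(1L, 1L))
  expect_true(all(rows$passed_filters))
  expect_error(queryAccession(idx, "NOPE"), "NOPE")
})

test_that("methionine-containing peptides are rejected under the defaults", {
  ps <- proteinSet("P1", "toy", "syn", "MAAKGGGGGR")
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  rows <- queryAccession(idx, "P1", filterConfig(), keepRejected = TRUE)
  maak <- rows[rows$peptide_sequence == "MAAK", ]
  expect_false(maak$passed_filters)
  expect_match(maak$rejection_reasons, "excluded residue M")
  expect_match(maak$rejection_reasons, "length < 5")
})

test_that("batch queries warn on unknown accessions and keep the rest", {
  ps <- proteinSet(c("P1", "P2"), c("alpha", "beta"), "syn",
                   c("AAAKGGGR", "TTTKGGGR"))
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  expect_warning(rows <- queryAccession(idx, c("P1", "NOPE"), relaxed()),
                 "NOPE")
  expect_identical(unique(rows$protein_accession), "P1")
})

test_that("name queries are case-insensitive substring matches", {
  ps <- proteinSet(c("P1", "P2", "P3"),
                   c("Keratin-like protein", "Other protein",
                     "keratin, type II"),
                   "syn", c("AAAKGGGR", "TTTKGGGR", "WWWKGGGR"))
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  rows <- queryName(idx, "KERAT", relaxed(requireUniqueFg = FALSE))
  expect_setequal(unique(rows$protein_accession), c("P1", "P3"))
  expect_identical(nrow(queryName(idx, "ZZZ", relaxed())), 0L)
})

test_that("sequence queries report occurrences and zero-hit rows", {
  ps <- proteinSet(c("P1", "P2"), c("alpha", "beta"), "syn",
                   c("AAAKGGGR", "TTTKGGGR"))
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  rows <- querySequences(idx, "AAAK", relaxed())
  expect_identical(nrow(rows), 1L)
  expect_identical(rows$fg_total_occurrences, 1L)

  rows <- querySequences(idx, "GGGR", relaxed(requireUniqueFg = FALSE))
  expect_identical(nrow(rows), 2L)
  expect_identical(rows$fg_total_occurrences, c(2L, 2L))
  expect_identical(rows$fg_distinct_proteins, c(2L, 2L))

  rows <- querySequences(idx, "WWWWW", relaxed(requireUniqueFg = FALSE))
  expect_identical(nrow(rows), 1L)
  expect_identical(rows$fg_total_occurrences, 0L)
  expect_true(is.na(rows$protein_accession))
  # lower-case input is upper-cased
  expect_identical(querySequences(idx, "aaak", relaxed())$fg_total_occurrences,
                   1L)
})

test_that("surrogate selection recovers planted-unique peptides exactly", {
  p <- pairIndexes(seed = 23L)
  rows <- selectSurrogates(p$fg, p$bg, accessions(p$records$fg),
                           uniquenessFilter())
  expect_identical(sort(unique(rows$peptide_sequence)),
                   p$truth$planted_unique)
  expect_true(all(rows$fg_total_occurrences == 1L))
  expect_true(all(rows$bg_total_occurrences == 0L))

  all_rows <- selectSurrogates(p$fg, p$bg, accessions(p$records$fg),
                               uniquenessFilter(), keepRejected = TRUE)
  sharedRows <- all_rows[all_rows$peptide_sequence %in%
                           p$truth$planted_shared, ]
  expect_true(all(!sharedRows$passed_filters))
  expect_true(all(grepl("present in background",
                        sharedRows$rejection_reasons)))
})

test_that("a background proteome never adds passing candidates", {
  for (seed in c(5L, 6L)) {
    p <- pairIndexes(seed = seed, shared = 0.5)
    accs <- accessions(p$records$fg)
    for (filters in list(uniquenessFilter(), filterConfig())) {
      withBg <- selectSurrogates(p$fg, p$bg, accs, filters)
      withoutBg <- queryAccession(p$fg, accs, filters)
      expect_true(all(withBg$peptide_sequence %in%
                        withoutBg$peptide_sequence))
    }
  }
})

test_that("tightening any single filter bound never adds a passing row", {
  p <- pairIndexes(seed = 37L, shared = 0.3)
  accs <- accessions(p$records$fg)
  base <- filterConfig(minLength = 6, maxLength = 20,
                       excludedResidues = "M", maxMissedCleavages = 1,
                       maxBgOccurrences = 1,
                       excludeFlags = c("has_ptm", "nonstandard"))
  tighter <- list(
    { f <- base; f@minLength <- 8; f },
    { f <- base; f@maxLength <- 15; f },
    { f <- base; f@excludedResidues <- c("M", "C"); f },
    { f <- base; f@maxMissedCleavages <- 0; f },
    { f <- base; f@maxBgOccurrences <- 0; f },
    { f <- base; f@excludeFlags <- c(f@excludeFlags, "has_conflict"); f })
  baseSet <- selectSurrogates(p$fg, p$bg, accs, base)$peptide_sequence
  for (f in tighter) {
    tightSet <- selectSurrogates(p$fg, p$bg, accs, f)$peptide_sequence
    expect_true(all(tightSet %in% baseSet))
  }
})

test_that("filters populate rejection reasons in a fixed order, idempotently", {
  rows <- data.frame(
    protein_accession = "P1", protein_name = "toy",
    peptide_sequence = c("AAAA", paste(rep("A", 23), collapse = ""),
                         "AACDEK", "AADDEK", "AAMCEK"),
    start = 1L, end = 4L,
    length = c(4L, 23L, 6L, 6L, 6L), missed_cleavages = 0L,
    mass = 500, fg_total_occurrences = 1L, fg_distinct_proteins = 1L,
    has_ptm = FALSE, has_variant = FALSE,
    has_conflict = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    in_signal = FALSE, isoform_variable = FALSE, nonstandard = FALSE,
    stringsAsFactors = FALSE)
  out <- applyFilters(rows, filterConfig())
  expect_identical(out$passed_filters,
                   c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$rejection_reasons[[1L]], "length < 5")
  expect_identical(out$rejection_reasons[[2L]], "length > 22")
  expect_match(out$rejection_reasons[[3L]], "excluded residue C")
  expect_match(out$rejection_reasons[[3L]], "sequence conflict")
  # residue reasons precede flag reasons in the fixed order
  expect_match(out$rejection_reasons[[3L]],
               "excluded residue C.*sequence conflict")
  expect_identical(out$rejection_reasons[[5L]],
                   "excluded residue M; excluded residue C")
  # idempotent and order-independent
  expect_identical(applyFilters(out, filterConfig()), out)
  perm <- sample(nrow(rows))
  out2 <- applyFilters(rows[perm, ], filterConfig())
  expect_identical(out2$rejection_reasons, out$rejection_reasons[perm])
})

test_that("flag-based rejections name the overlapping annotation", {
  ft <- data.frame(accession = "P1",
                   kind = c("ptm", "variant_snp", "signal_peptide"),
                   start = c(2L, 7L, 1L), end = c(2L, 7L, 3L),
                   description = "", source_key = "X",
                   stringsAsFactors = FALSE)
  ps <- proteinSet("P1", "toy", "syn", "AAAKGGGKWWWK", features = ft)
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 1L), "t")
  rows <- queryAccession(idx, "P1",
                         relaxed(excludeFlags = c("has_ptm", "has_variant",
                                                  "in_signal")),
                         keepRejected = TRUE)
  aaak <- rows[rows$peptide_sequence == "AAAK", ]
  expect_match(aaak$rejection_reasons, "modified residue")
  expect_match(aaak$rejection_reasons, "signal peptide")
  gggk <- rows[rows$peptide_sequence == "GGGK", ]
  expect_match(gggk$rejection_reasons, "sequence variant")
  wwwk <- rows[rows$peptide_sequence == "WWWK", ]
  expect_true(wwwk$passed_filters)
})

test_that("the m/z window filter passes when any configured charge fits", {
  rows <- data.frame(peptide_sequence = c("AAAAK", "AAAAK"),
                     length = 5L, missed_cleavages = 0L,
                     mass = c(430.2, 3600.0),
                     fg_total_occurrences = 1L, fg_distinct_proteins = 1L,
                     has_ptm = FALSE, has_variant = FALSE,
                     has_conflict = FALSE, in_signal = FALSE,
                     isoform_variable = FALSE, nonstandard = FALSE,
                     stringsAsFactors = FALSE)
  f <- filterConfig(minLength = 1, excludedResidues = character(),
                    excludeFlags = character(),
                    mzWindow = list(low = 400, high = 1600,
                                    charges = c(2L, 3L)))
  out <- applyFilters(rows, f)
  # 430 Da: only z=1 would fit below 400? (430+2p)/2 = 216 -> fails both
  expect_identical(out$rejection_reasons[[1L]], "m/z outside window")
  # 3600 Da: z=3 gives ~1201 Th -> inside
  expect_true(out$passed_filters[[2L]])
})

test_that("CSV export round-trips rows and quotes embedded commas", {
  ps <- proteinSet("P1", "Keratin, type I", "syn", "AAAKGGGR")
  idx <- buildPeptideIndex(ps, digestionParams(minPeptideLength = 3L), "t")
  rows <- queryAccession(idx, "P1", relaxed(), keepRejected = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  exportSelectionCsv(rows, f)
  expect_identical(length(readLines(f)), nrow(rows) + 1L)
  back <- readSelectionCsv(f)
  expect_equal(back, rows)
  expect_identical(back$protein_name[[1L]], "Keratin, type I")

  empty <- rows[0L, ]
  exportSelectionCsv(empty, f)
  expect_identical(length(readLines(f)), 1L)
  expect_identical(names(readSelectionCsv(f)), names(rows))
})

test_that("batch files ignore blanks and comments", {
  f <- withr::local_tempfile(lines = c("# header", "", "P1 ", "P2 # trailing"))
  expect_identical(readBatchFile(f), c("P1", "P2"))
})
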