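# Synthetic two-species proteome pairs with planted ground truth. Proteins
# are concatenations of globally distinct tryptic-style fragments (ending in
# K/R, no internal cleavage site), so the 0-missed-cleavage tryptic digest
# recovers exactly the planted fragment set: planted-unique fragments occur
# once in the foreground and never in the background (the surrogate
# candidates a xenograft query must find), shared fragments occur in both
# species, and the remaining fragments are duplicated within the foreground
# so that no incidental fragment is foreground-unique.

#' Specification of a synthetic proteome pair
#'
#' @param nProteinsFg,nProteinsBg number of proteins per species.
#' @param meanProteinLength approximate protein length in residues.
#' @param sharedFragmentFraction fraction in `[0, 1]` of the non-planted
#'   foreground fragments copied into the background proteome (emulating
#'   sequence identity between the two species).
#' @param nPlantedUnique number of fragments guaranteed to occur exactly
#'   once in the foreground and never in the background.
#' @param featureDensity expected features per 100 residues for each point
#'   feature kind (PTM, variant, conflict).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @param prolineGuards also inject internal K/R-P motifs (sites suppressed
#'   by the proline rule) to exercise that code path.
#' @param nonstandardResidues occasionally inject B/Z/X/U/O letters to
#'   exercise nonstandard-residue flagging.
#' @return A `FixtureSpec` list.
#' @export
fixtureSpec <- function(nProteinsFg = 20L, nProteinsBg = 20L,
                        meanProteinLength = 200L,
                        sharedFragmentFraction = 0.3,
                        nPlantedUnique = 10L,
                        featureDensity = 1,
                        seed = 1L,
                        prolineGuards = FALSE,
                        nonstandardResidues = FALSE) {
  stopifnot(nProteinsFg >= 1L, nProteinsBg >= 1L, meanProteinLength >= 20L,
            sharedFragmentFraction >= 0, sharedFragmentFraction <= 1,
            nPlantedUnique >= 0L, featureDensity >= 0)
  structure(list(nProteinsFg = as.integer(nProteinsFg),
                 nProteinsBg = as.integer(nProteinsBg),
                 meanProteinLength = as.integer(meanProteinLength),
                 sharedFragmentFraction = sharedFragmentFraction,
                 nPlantedUnique = as.integer(nPlantedUnique),
                 featureDensity = featureDensity,
                 seed = as.integer(seed),
                 prolineGuards = isTRUE(prolineGuards),
                 nonstandardResidues = isTRUE(nonstandardResidues)),
            class = "FixtureSpec")
}

#' Generate a synthetic two-species proteome pair with ground truth
#'
#' Writes the foreground and background proteomes as UniProt flat text and
#' FASTA plus a JSON ground-truth sidecar into `dir`, and returns the parsed
#' record sets together with the truth labels. Every foreground tryptic
#' fragment is labelled `planted_unique` (one foreground occurrence, absent
#' from the background), `planted_shared` (present in the background) or
#' `incidental` (duplicated within the foreground); the labels are verified
#' internally by brute-force digestion before returning.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return list with elements `fg`, `bg` ([ProteinSet-class]s), `truth`
#'   (list of label vectors), and `files` (named paths: `fg_dat`, `bg_dat`,
#'   `fg_fasta`, `bg_fasta`, `truth`).
#' @examples
#' out <- generateProteomePair(fixtureSpec(seed = 7L), tempdir())
#' lengths(out$truth)
#' @export
generateProteomePair <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  bodyAlpha <- setdiff(AA_STANDARD, c("K", "R"))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  randFragment <- function() {
    repeat {
      len <- sample(6:14, 1L)
      chars <- sample(bodyAlpha, len - 1L, replace = TRUE)
      if (chars[[1L]] == "P")
        chars[[1L]] <- sample(setdiff(bodyAlpha, "P"), 1L)
      if (spec$nonstandardResidues && stats::runif(1L) < 0.05 && len >= 4L)
        chars[[sample(2:(len - 2L), 1L)]] <- sample(AA_NONSTANDARD, 1L)
      if (spec$prolineGuards && stats::runif(1L) < 0.2 && len >= 5L) {
        pos <- sample(2:(len - 3L), 1L)
        chars[[pos]] <- sample(c("K", "R"), 1L)
        chars[[pos + 1L]] <- "P"
      }
      frag <- paste0(paste(chars, collapse = ""), sample(c("K", "R"), 1L))
      if (!exists(frag, envir = seen, inherits = FALSE)) {
        assign(frag, TRUE, envir = seen)
        return(frag)
      }
    }
  }

  fragsPerProtein <- max(2L, round(spec$meanProteinLength / 10))
  totalSlots <- spec$nProteinsFg * fragsPerProtein
  if (spec$nPlantedUnique > totalSlots)
    stop(sprintf(
      "infeasible spec: %d planted-unique fragments but only %d fragment slots",
      spec$nPlantedUnique, totalSlots))

  remaining <- totalSlots - spec$nPlantedUnique
  nShared <- round(spec$sharedFragmentFraction * remaining)
  slotsLeft <- remaining - nShared
  nDup <- slotsLeft %/% 2L
  extraDupCopy <- slotsLeft %% 2L == 1L && nDup >= 1L

  planted <- if (spec$nPlantedUnique)
    vapply(seq_len(spec$nPlantedUnique), function(i) randFragment(),
           character(1L)) else character()
  shared <- if (nShared) vapply(seq_len(nShared), function(i) randFragment(),
                                character(1L)) else character()
  dup <- if (nDup) vapply(seq_len(nDup), function(i) randFragment(),
                          character(1L)) else character()

  fgUsage <- c(planted, shared, rep(dup, each = 2L),
               if (extraDupCopy) dup[[1L]])
  fgUsage <- sample(fgUsage)
  fgGroups <- split(fgUsage,
                    rep(seq_len(spec$nProteinsFg), length.out = length(fgUsage)))

  bgSlots <- spec$nProteinsBg * fragsPerProtein
  nBgOnly <- max(0L, bgSlots - nShared)
  bgOnly <- if (nBgOnly) vapply(seq_len(nBgOnly), function(i) randFragment(),
                                character(1L)) else character()
  bgUsage <- sample(c(shared, bgOnly))
  bgGroups <- split(bgUsage,
                    rep(seq_len(spec$nProteinsBg), length.out = length(bgUsage)))

  makeFeatures <- function(accession, len) {
    feats <- list()
    for (kind in c("ptm", "variant_snp", "conflict")) {
      nk <- stats::rpois(1L, spec$featureDensity / 100 * len)
      nk <- min(nk, len)
      if (nk > 0L) {
        pos <- sort(sample.int(len, nk))
        feats[[length(feats) + 1L]] <- data.frame(
          accession = accession, kind = kind, start = pos, end = pos,
          description = "synthetic feature",
          source_key = unname(KIND_TO_UNIPROT_KEY[[kind]]),
          stringsAsFactors = FALSE)
      }
    }
    if (stats::rpois(1L, spec$featureDensity / 100 * len) > 0L)
      feats[[length(feats) + 1L]] <- data.frame(
        accession = accession, kind = "signal_peptide", start = 1L,
        end = min(20L, len), description = "synthetic signal peptide",
        source_key = "SIGNAL", stringsAsFactors = FALSE)
    if (stats::rpois(1L, spec$featureDensity / 100 * len) > 0L) {
      s <- sample.int(max(1L, len - 10L), 1L)
      feats[[length(feats) + 1L]] <- data.frame(
        accession = accession, kind = "isoform_variable", start = s,
        end = min(len, s + sample(9:29, 1L)),
        description = "synthetic isoform-variable region",
        source_key = "VAR_SEQ", stringsAsFactors = FALSE)
    }
    if (length(feats)) do.call(rbind, feats) else emptyFeatureTable()
  }

  assemble <- function(groups, prefix, organism, taxon) {
    acc <- sprintf("%s%04d", prefix, seq_along(groups))
    seqs <- vapply(groups, paste, character(1L), collapse = "")
    feats <- do.call(rbind, c(list(emptyFeatureTable()),
                              Map(makeFeatures, acc, nchar(seqs))))
    rownames(feats) <- NULL
    proteinSet(accession = acc,
               name = sprintf("Synthetic %s protein %d",
                              if (prefix == "FGP") "foreground" else "background",
                              seq_along(groups)),
               organism = organism, sequence = seqs,
               taxon_id = taxon, reviewed = TRUE, features = feats,
               source = "memory")
  }
  fg <- assemble(fgGroups, "FGP", "Synthetica prima", 900001L)
  bg <- assemble(bgGroups, "BGP", "Synthetica altera", 900002L)

  # Brute-force truth verification: re-digest both proteomes and check the
  # planted labels before anything is returned.
  countFragments <- function(ps) {
    params <- digestionParams(enzyme = "trypsin", maxMissedCleavages = 0L,
                              minPeptideLength = 1L, prolineRule = TRUE)
    tab <- table(unlist(lapply(as.character(ps@sequences),
                               function(s) digestSequence(s, params)$sequence)))
    stats::setNames(as.integer(tab), names(tab))
  }
  fgCounts <- countFragments(fg)
  bgCounts <- countFragments(bg)
  bgOf <- function(p) ifelse(is.na(bgCounts[p]), 0L, bgCounts[p])
  if (length(planted) &&
      (any(fgCounts[planted] != 1L) || any(bgOf(planted) > 0L)))
    stop("fixture truth verification failed: planted-unique labels wrong")
  if (length(shared) && any(bgOf(shared) < 1L))
    stop("fixture truth verification failed: planted-shared labels wrong")
  incidental <- setdiff(names(fgCounts), c(planted, shared))
  if (length(incidental) && any(fgCounts[incidental] < 2L))
    stop("fixture truth verification failed: incidental fragment is unique")

  truth <- list(planted_unique = sort(planted),
                planted_shared = sort(shared),
                incidental = sort(incidental))

  files <- list(fg_dat = file.path(dir, "fg_proteome.dat"),
                bg_dat = file.path(dir, "bg_proteome.dat"),
                fg_fasta = file.path(dir, "fg_proteome.fasta"),
                bg_fasta = file.path(dir, "bg_proteome.fasta"),
                truth = file.path(dir, "truth.json"))
  writeLines(renderUniProtFlat(fg), files$fg_dat)
  writeLines(renderUniProtFlat(bg), files$bg_dat)
  writeLines(renderFasta(fg), files$fg_fasta)
  writeLines(renderFasta(bg), files$bg_fasta)
  jsonlite::write_json(c(truth, list(seed = spec$seed,
                                     spec = unclass(spec))),
                       files$truth, auto_unbox = TRUE, pretty = TRUE)
  list(fg = fg, bg = bg, truth = truth, files = files)
}

#' Render protein records as UniProt flat text
#'
#' Writes records in the UniProt flat-text dialect accepted by
#' [readUniProt()]; rendering then re-parsing reproduces the records
#' (accession, name, organism, sequence, features).
#'
#' @param records a [ProteinSet-class].
#' @return character vector of lines (empty for an empty record set).
#' @export
renderUniProtFlat <- function(records) {
  stopifnot(is(records, "ProteinSet"))
  p <- records@proteins
  seqs <- as.character(records@sequences)
  out <- character()
  for (i in seq_len(nrow(p))) {
    seq <- seqs[[i]]
    len <- nchar(seq)
    lines <- c(
      sprintf("ID   %-19s %s; %14d AA.",
              paste0(gsub("[^A-Za-z0-9]", "", p$accession[[i]]), "_SYN"),
              if (isTRUE(p$reviewed[[i]])) "Reviewed" else "Unreviewed",
              len),
      sprintf("AC   %s;", p$accession[[i]]),
      sprintf("DE   RecName: Full=%s;", p$name[[i]]))
    if (!is.na(p$organism[[i]]))
      lines <- c(lines, sprintf("OS   %s.", p$organism[[i]]))
    if (!is.na(p$taxon_id[[i]]))
      lines <- c(lines, sprintf("OX   NCBI_TaxID=%d;", p$taxon_id[[i]]))
    ft <- records@features[records@features$accession == p$accession[[i]], ,
                           drop = FALSE]
    for (j in seq_len(nrow(ft))) {
      key <- ft$source_key[[j]]
      if (is.na(key) || !nzchar(key))
        key <- unname(KIND_TO_UNIPROT_KEY[[ft$kind[[j]]]])
      loc <- if (ft$start[[j]] == ft$end[[j]]) as.character(ft$start[[j]])
             else sprintf("%d..%d", ft$start[[j]], ft$end[[j]])
      lines <- c(lines, sprintf("FT   %-15s %s", key, loc))
      if (nzchar(ft$description[[j]]))
        lines <- c(lines, sprintf("FT                   /note=\"%s\"",
                                  ft$description[[j]]))
    }
    lines <- c(lines, sprintf("SQ   SEQUENCE %3d AA; 0 MW;  0 CRC64;", len))
    chunks <- substring(seq, seq(1L, len, 60L), pmin(seq(1L, len, 60L) + 59L, len))
    lines <- c(lines,
               vapply(chunks, function(ch) {
                 blocks <- substring(ch, seq(1L, nchar(ch), 10L),
                                     pmin(seq(1L, nchar(ch), 10L) + 9L,
                                          nchar(ch)))
                 paste0("     ", paste(blocks, collapse = " "))
               }, character(1L), USE.NAMES = FALSE),
               "//")
    out <- c(out, lines)
  }
  out
}

#' Render protein records as FASTA
#'
#' Generic-dialect FASTA (`>accession name`), 60 residues per line.
#'
#' @param records a [ProteinSet-class].
#' @return character vector of lines.
#' @export
renderFasta <- function(records) {
  stopifnot(is(records, "ProteinSet"))
  p <- records@proteins
  seqs <- as.character(records@sequences)
  out <- character()
  for (i in seq_len(nrow(p))) {
    len <- nchar(seqs[[i]])
    chunks <- substring(seqs[[i]], seq(1L, len, 60L),
                        pmin(seq(1L, len, 60L) + 59L, len))
    out <- c(out, sprintf(">%s %s", p$accession[[i]], p$name[[i]]), chunks)
  }
  out
}
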