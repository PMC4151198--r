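# Independent oracles used to check the digestion and mass code, kept
# deliberately naive: direct per-residue rule scans, explicit enumeration of
# fragment joins, and elemental-composition mass sums. They share no code
# with the implementation under test.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Cut positions by scanning each residue pair directly against the rule.
oracleCleavageSites <- function(seq, enzyme, prolineRule = TRUE) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  cuts <- integer()
  if (n < 2L) return(cuts)
  for (i in 1:(n - 1L)) {
    cut <- switch(enzyme,
      trypsin = ch[i] %in% c("K", "R") && !(prolineRule && ch[i + 1L] == "P"),
      lysc    = ch[i] == "K" && !(prolineRule && ch[i + 1L] == "P"),
      argc    = ch[i] == "R" && !(prolineRule && ch[i + 1L] == "P"),
      lysn    = ch[i + 1L] == "K")
    if (cut) cuts <- c(cuts, i)
  }
  cuts
}

# Brute-force digest: enumerate every pair of cut boundaries joining at most
# maxMissed internal cuts.
oracleDigest <- function(seq, enzyme, maxMissed, minLen, prolineRule = TRUE) {
  b <- c(0L, oracleCleavageSites(seq, enzyme, prolineRule), nchar(seq))
  nb <- length(b)
  rows <- list()
  for (i in 1:(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + maxMissed)) {
      s <- b[i] + 1L; e <- b[j]
      if (e - s + 1L < minLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, s, e), start = s, end = e,
        missed_cleavages = j - i - 1L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  out[order(out$start, out$end), , drop = FALSE]
}

digestKey <- function(df)
  sort(sprintf("%s|%d|%d|%d", df$sequence, df$start, df$end,
               df$missed_cleavages))

# Monoisotopic mass from elemental composition (atom counts per residue),
# independent of the residue-mass table used by the package.
oracleMass <- local({
  atoms <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)
  # residue formulas as c(C, H, N, O, S)
  formulas <- list(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
  residueMass <- vapply(formulas, function(f)
    sum(f * atoms[c("C", "H", "N", "O", "S")]), numeric(1L))
  water <- 2 * atoms[["H"]] + atoms[["O"]]
  function(seq) {
    ch <- strsplit(seq, "")[[1L]]
    sum(residueMass[ch]) + water
  }
})

randomSequence <- function(maxLen = 200L, nonstandardRate = 0) {
  n <- sample.int(maxLen, 1L)
  ch <- sample(AA20, n, replace = TRUE)
  if (nonstandardRate > 0) {
    odd <- runif(n) < nonstandardRate
    ch[odd] <- sample(c("B", "Z", "X", "U", "O"), sum(odd), replace = TRUE)
  }
  paste(ch, collapse = "")
}

seqsOf <- function(ps) unname(as.character(proteinSequences(ps)))

randomPeptide <- function(maxLen = 30L)
  paste(sample(AA20, sample.int(maxLen, 1L), replace = TRUE), collapse = "")

# A tiny hand-assembled UniProt flat entry for the parser tests.
miniUniProtEntry <- function(acc = "P00001", seq = "ACDEFKGHIK",
                             name = "Toy protein", ftLines = character()) {
  c(sprintf("ID   %s_SYN              Reviewed; %14d AA.", acc, nchar(seq)),
    sprintf("AC   %s;", acc),
    sprintf("DE   RecName: Full=%s;", name),
    "OS   Synthetica prima.",
    "OX   NCBI_TaxID=900001;",
    ftLines,
    sprintf("SQ   SEQUENCE %3d AA; 0 MW;  0 CRC64;", nchar(seq)),
    paste0("     ", seq),
    "//")
}
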