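# In-silico proteolytic digestion: cleavage-site detection, missed-cleavage
# enumeration, and peptide mass / m-over-z computation.

#' Find proteolytic cleavage sites in a protein sequence
#'
#' Returns the internal cleavage positions for the chosen enzyme as an
#' increasing integer vector, where a cut at position `i` means the peptide
#' bond between residues `i` and `i + 1` is hydrolysed (1-based). Trypsin
#' cleaves after K or R, Lys-C after K, Arg-C after R, and Lys-N before K
#' (a cut at `i` where residue `i + 1` is K). With `prolineRule = TRUE`
#' (default) cleavage after K/R is suppressed when the next residue is
#' proline; the rule does not apply to Lys-N. No cut is reported after the
#' terminal residue, and nonstandard letters (B, Z, X, U, O) never generate
#' a cut.
#'
#' @param sequence single protein sequence (upper-case amino-acid letters).
#' @param enzyme one of `"trypsin"`, `"lysc"`, `"argc"`, `"lysn"`.
#' @param prolineRule logical, see above.
#' @return integer vector of cut positions, strictly increasing, possibly
#'   empty.
#' @examples
#' cleavageSites("ARNDK", "trypsin")   # 2 (terminal K cuts nothing)
#' cleavageSites("AKPGK", "trypsin")   # empty: K2-P3 suppressed, K5 terminal
#' cleavageSites("GKAAK", "lysn")      # 1, 4 (cuts before each internal K)
#' @export
cleavageSites <- function(sequence, enzyme = c("trypsin", "lysc", "argc", "lysn"),
                          prolineRule = TRUE) {
  enzyme <- match.arg(enzyme)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (enzyme == "lysn") {
    idx <- which(chars == "K") - 1L
    idx <- idx[idx >= 1L]
  } else {
    after <- switch(enzyme,
                    trypsin = c("K", "R"),
                    lysc = "K",
                    argc = "R")
    idx <- which(chars %in% after)
    idx <- idx[idx < n]
    if (prolineRule && length(idx))
      idx <- idx[chars[idx + 1L] != "P"]
  }
  as.integer(idx)
}

#' Digest a protein sequence in silico
#'
#' Cuts the sequence at every cleavage site of `params@enzyme` and
#' enumerates, in order of (start, end), all maximal fragments between
#' consecutive cuts (`missed_cleavages = 0`) together with every
#' concatenation of up to `params@maxMissedCleavages + 1` consecutive
#' fragments (`missed_cleavages` = number of internal cuts joined).
#' Peptides shorter than `params@minPeptideLength` are dropped; peptides
#' containing nonstandard letters are retained but flagged.
#'
#' @param sequence single protein sequence.
#' @param params a [DigestionParams-class].
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, `length`, `nonstandard`; coordinates are 1-based
#'   inclusive on the parent protein.
#' @examples
#' digestSequence("AAAKGGGR", digestionParams(minPeptideLength = 3L))
#' @export
digestSequence <- function(sequence, params = digestionParams()) {
  stopifnot(is(params, "DigestionParams"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  cuts <- cleavageSites(sequence, params@enzyme, params@prolineRule)
  n <- nchar(sequence)
  bounds <- c(0L, cuts, n)
  nf <- length(bounds) - 1L
  fragStart <- bounds[-length(bounds)] + 1L
  fragEnd <- bounds[-1L]
  pieces <- vector("list", params@maxMissedCleavages + 1L)
  for (k in 0:params@maxMissedCleavages) {
    if (k + 1L > nf) break
    i <- seq_len(nf - k)
    pieces[[k + 1L]] <- data.frame(start = fragStart[i],
                                   end = fragEnd[i + k],
                                   missed_cleavages = k)
  }
  out <- do.call(rbind, pieces)
  out$length <- out$end - out$start + 1L
  out <- out[out$length >= params@minPeptideLength, , drop = FALSE]
  out$sequence <- if (nrow(out)) substring(sequence, out$start, out$end)
                  else character()
  out$nonstandard <- grepl("[BZXUO]", out$sequence)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("sequence", "start", "end", "missed_cleavages", "length",
          "nonstandard")]
}

#' Monoisotopic peptide mass
#'
#' Sum of the standard residue monoisotopic masses plus one water
#' (18.010565 Da). Defined only over the 20 standard amino-acid letters;
#' peptides containing B, Z, X, U or O have no defined mass and raise an
#' error.
#'
#' @param sequence character vector of peptide sequences.
#' @return numeric vector of masses in Da.
#' @examples
#' peptideMass("PEPTIDE")  # 799.35997
#' @export
peptideMass <- function(sequence) {
  stopifnot(is.character(sequence))
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    m <- AA_MONO_MASS[chars]
    if (anyNA(m))
      stop(sprintf("mass undefined for sequence '%s': nonstandard residue(s) %s",
                   s, paste(unique(chars[is.na(m)]), collapse = ", ")))
    sum(m) + MASS_WATER
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Mass-to-charge ratio of a peptide ion
#'
#' `(mass + charge * 1.007276) / charge`, i.e. the m/z of the protonated
#' peptide at the given charge state.
#'
#' @param mass neutral monoisotopic mass in Da (> 0); vectorised.
#' @param charge positive integer charge state; vectorised.
#' @return numeric vector of m/z values in Th.
#' @examples
#' peptideMz(1000, 1:3)
#' @export
peptideMz <- function(mass, charge) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be > 0")
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  (mass + charge * MASS_PROTON) / charge
}
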