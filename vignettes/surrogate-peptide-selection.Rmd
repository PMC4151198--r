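---
title: "Surrogate peptide selection against a host proteome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate peptide selection against a host proteome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SurrogatePeptides)
```

## The problem

In bottom-up targeted proteomics a protein is quantified through surrogate
peptides monitored by SRM. When the sample mixes proteomes from two species
— human tumor tissue xenografted into a rodent host being the motivating
case — a candidate peptide is only usable if its sequence is produced by
exactly one protein of the proteome of interest *and* by no protein of the
host proteome. Otherwise the measured signal aggregates contributions from
several proteins or from both species, and the quantification is biased by
the (variable) host content of each tissue piece.

This package implements the database side of that selection: in-silico
digestion of whole proteomes, an occurrence index over the resulting
peptides with protein-level annotations remapped to the peptide level, and
the dual-proteome uniqueness query with an explicit, relaxable filter set.
It deliberately stops where database information stops: detectability
prediction, cleavage-efficiency modelling and transition selection are
downstream concerns served by other tools and public repositories.

## Digestion model

Cleavage sites are defined per enzyme on the 1-based residue index, a cut
at `i` separating residues `i` and `i + 1`:

* trypsin — after K or R;
* Lys-C — after K;
* Arg-C — after R;
* Lys-N — *before* K (a cut at `i` when residue `i + 1` is K).

With the proline rule active (the default), cuts after K/R are suppressed
when the next residue is proline; the rule has no meaning for Lys-N, which
cleaves on the N-terminal side. Whether the rule should be applied is a
long-standing convention split in the field, so it is exposed as a
`DigestionParams` flag rather than hard-coded; indexes record the setting
and dual-proteome queries refuse to compare indexes that disagree on it.

Given the ordered cuts `c_1 < … < c_n`, the fragments between consecutive
cuts are the 0-missed-cleavage peptides, and the digest with up to `m`
missed cleavages is every concatenation of at most `m + 1` consecutive
fragments; a peptide joining `k` internal cuts carries `missed_cleavages =
k`. Two structural identities follow and are enforced as tests: the
0-missed peptides concatenate back to the protein exactly, and a protein
with `c` internal cuts has `max(0, c + 1 − k)` peptides with exactly `k`
missed cleavages. The engine itself is additionally checked against a
brute-force oracle (direct rule scan plus explicit enumeration of fragment
joins) on 1000 random sequences of length 1–200 in the acceptance suite.

Residues outside the 20 standard letters (B, Z, X, U, O) are treated as
opaque: they never create a cleavage site, have no defined monoisotopic
mass, and mark every peptide containing them with the `nonstandard` flag,
which the default filters exclude. The N-terminal methionine is not
clipped before digestion; initiator-Met processing is genuinely
protein-specific and modelling it heuristically would silently change
coordinates.

Two digestion parameters deserve a note on scope. `minPeptideLength`
(default 3) is a *build-time* economy: peptides shorter than it are never
stored, which keeps the database small. The stricter 5–22 residue window
commonly advised for quantification is a *query-time* filter
(`FilterConfig`), so one database serves both permissive exploration and
strict assay design.

## Masses and m/z

Monoisotopic peptide mass is the sum of the standard residue masses plus
one water (18.010565 Da); m/z at charge `z` is `(M + z · 1.007276)/z` Th.
Stored masses are rounded to 10^-6 Da so that the CSV round trip is exact;
the acceptance script verifies the residue table against an independent
computation from elemental compositions (maximum absolute deviation on the
order of 10^-6 Da for peptides up to 30 residues, well inside the 10^-4 Da
tolerance that matters at assay precision).

## Remapping annotations to the peptide level

UniProt and GenPept annotate proteins, not peptides, so feature intervals
are intersected with each peptide occurrence (1-based, inclusive on both
ends): an occurrence `[s, e]` raises a flag iff some feature of the
corresponding kind has `start ≤ e` and `end ≥ s`. The feature-key map is
fixed and versioned in code: `MOD_RES`, `LIPID`, `CROSSLNK` → `ptm`,
`CARBOHYD` → `glyco` (both raise `has_ptm`), `VARIANT` → `variant_snp`,
`CONFLICT` → `conflict`, `SIGNAL` → `signal_peptide`, `VAR_SEQ` →
`isoform_variable`; GenPept `Site`/`sig_peptide`/`variation`/
`misc_difference` route into the same vocabulary. Unknown keys map to
`other` and are retained rather than dropped — the database should never
silently lose annotation — but raise no occurrence flag.

Isoforms embedded as `VAR_SEQ` deltas are *not* expanded into separate
sequences. Only the canonical sequence is digested, and peptides
overlapping a `VAR_SEQ` region carry the `isoform_variable` flag, so the
user can see which candidates fail to represent all isoforms. Expanding
isoforms would multiply the database and change uniqueness semantics in
ways that depend on which isoform set a study targets; flagging keeps the
decision with the user.

## Uniqueness semantics

A "hit" is one occurrence: a (protein, position) pair in the digest. The
index stores both `total_occurrences` and `distinct_proteins` per peptide
because the two disagree exactly when a peptide repeats inside one protein
— such a peptide identifies its protein unambiguously but quantifies it
with a factor-2 ambiguity. The default pass condition is strict
(`total_occurrences == 1` in the foreground); `FilterConfig(uniqueBy =
"proteins")` relaxes it to one distinct protein for identification-style
queries.

Background matching is an exact lookup against the *background digest
under its own stored parameters*, not a substring scan of background
protein sequences: the question is whether the host sample can produce the
same peptide, which is a property of the host digest. Because the answer
depends on enzyme, missed-cleavage ceiling, proline rule and the optional
I/L collapse, a dual-proteome query first verifies that both indexes agree
on all four and errors out otherwise. The I/L collapse (isoleucine and
leucine are isobaric and indistinguishable by most MS readouts) is off by
default and recorded in the metadata when on.

Name queries use case-insensitive substring matching — the permissive
choice, since a missed candidate protein is worse than an extra row the
accession column disambiguates. Query results are ordered by (accession,
start, missed cleavages) so outputs are byte-deterministic.

## The filter set

`filterConfig()` defaults encode the advised values for SRM assay design:

| filter | default | rationale |
|---|---|---|
| length | 5–22 aa | shorter peptides are rarely unique and interference-prone; longer ones are hydrophobic and hard to synthesise |
| excluded residues | M, C | Met oxidises partially; Cys depends on complete reduction/alkylation |
| missed cleavages | 0 | quantification should not depend on digestion completeness |
| annotation flags | PTM, variant/SNP, conflict, signal, nonstandard | sites of known chemical, genetic or database-level sequence uncertainty |
| foreground | exactly 1 hit | proteotypic requirement |
| background | 0 hits | the xenograft requirement |
| m/z window | off (suggested 400–1600 Th, z ∈ {2, 3}) | instrument mass-range constraint; a peptide passes if *any* configured charge fits |

Rejection reasons are computed in a fixed order (length, residues, missed
cleavages, flags, foreground uniqueness, background presence, m/z) and
rows are never silently dropped when `keepRejected = TRUE`: the full
evidence stays available and `applyFilters()` is idempotent, so the same
table can be re-filtered under different configurations.

## The synthetic proteome generator

`generateProteomePair()` emulates the two-species scenario at the level
that matters for correctness testing: proteins are concatenations of
globally distinct tryptic-style fragments (each ends in K/R and contains no
internal cleavage site), so the 0-missed tryptic digest of the emitted
files is *exactly* the planted fragment multiset. Three fragment classes
give a complete, mutually exclusive ground truth:

* *planted unique* — one foreground occurrence, absent from the background
  (the peptides a correct selection must return, and nothing else);
* *planted shared* — copied into background proteins at the configured
  `sharedFragmentFraction`, emulating cross-species sequence identity;
* *incidental* — duplicated within the foreground, so no unplanted
  fragment is accidentally foreground-unique.

Features are scattered at a configurable density per 100 residues, and
optional switches inject proline-guarded K/R–P motifs and nonstandard
letters to exercise those code paths. The generator verifies its own labels
by brute-force digestion before returning, and writes UniProt flat text,
FASTA and a JSON truth sidecar; generation is fully deterministic given the
seed.

What the generator does **not** emulate: realistic inter-species homology
(fragments are either identical or absent, never one substitution apart),
realistic protein length and amino-acid composition distributions, signal
peptides placed with biological meaning, or redundant database entries.
Passing the planted-truth tests therefore demonstrates that the machinery
(digestion, indexing, counting, dual-proteome comparison) is exact, not
that selection performance on real proteomes has any particular yield;
with real UniProt releases the number of surviving candidates per protein
is an empirical property of the two proteomes.

## Numerical and representation choices

* Coordinates are 1-based inclusive everywhere, matching the UniProt
  feature-table convention, including CSV output.
* The persistent index is a single self-contained text file: one JSON
  metadata line plus tab-separated protein/peptide/occurrence sections.
  Any store satisfying the save/load round trip and exact-lookup contract
  would do; in-memory lookups run over a keyed `data.table` on the peptide
  sequence. The round trip is asserted to be answer-identical, not merely
  approximately equal.
* Parsing is tolerant per entry (a malformed entry is skipped and recorded
  in the parse report with its line number) but strict for structural
  corruption: an unterminated final entry or a duplicate primary accession
  aborts the parse, because both indicate a truncated or corrupted
  download rather than a single bad record.
* Degenerate inputs have defined behaviour: an empty stream parses to an
  empty record set; an empty record set refuses to build an index; a
  sequence with no cleavage site digests to itself; querying an absent
  peptide returns zero counts, not an error.
* CSV export writes RFC 4180 (quoted fields, CRLF, `true`/`false`
  booleans); masses are rounded to 10^-6 Da at index build so the write →
  read cycle reproduces rows exactly.

## Problem sizes used by the tests

The suite builds all fixtures programmatically at run time: the digestion
oracle comparison uses 1000 random sequences (length 1–200) in the
acceptance block and 150 in the module block; planted-truth recovery runs
21 proteome pairs of 10+10 proteins (~120 residues each) spanning shared
fractions 0–1; round-trip and filter checks use 6–8 protein pairs. These
sizes give full code-path coverage while keeping the whole suite in the
low minutes on one CPU; the properties asserted are size-independent.

## Known limitations

* No semi-specific or non-specific digestion, and no cleavage-probability
  modelling — only the four fully specific enzyme rules.
* No chemical-modification mass deltas (the m/z filter uses the unmodified
  monoisotopic mass).
* Isoform sequences are flagged, not expanded (see above).
* IPI flat files are not supported (the database was discontinued; the
  UniProt dialect is the closest surviving relative).
* Indexes are rebuilt, not incrementally updated, when the source database
  changes.
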