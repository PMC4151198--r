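# SurrogatePeptides

Targeted proteomics quantifies a protein through one or a few *surrogate
peptides* monitored by SRM on a triple-quadrupole instrument. Picking those
peptides is easy to get wrong when the sample mixes two species' proteomes —
the canonical case is a human tumor xenografted into a mouse or rat, where
every tryptic peptide of a human protein of interest may also be produced by
a host protein. A usable surrogate must be (i) **unique** within the proteome
of interest (exactly one occurrence across the digested proteome) and
(ii) **absent** from the host/background proteome, on top of the usual
physicochemical constraints (length, chemically fragile residues, annotated
sequence variability).

SurrogatePeptides builds searchable peptide databases from whole-proteome
protein databases and answers these uniqueness queries:

* **Ingest** — UniProt flat text (`.dat`/`.txt`), RefSeq GenPept (`.gpff`)
  and FASTA parsers producing `ProteinSet` objects, with the UniProt/GenPept
  feature tables (PTM sites, variants/SNPs, sequence conflicts, signal
  peptides, isoform-variable regions) lifted into a fixed feature-kind
  vocabulary.
* **Digestion** — in-silico proteolysis with trypsin, Lys-C, Arg-C or Lys-N,
  missed-cleavage enumeration (0–2), a configurable proline rule, and
  monoisotopic mass / m/z computation. For a protein with cut positions
  `c_1 < … < c_n`, the digest is every concatenation of up to `m + 1`
  consecutive fragments; a peptide joining `k` internal cuts carries
  `k` missed cleavages.
* **Index** — `buildPeptideIndex()` turns a proteome into a `PeptideIndex`:
  peptide → all (protein, start, end, missed-cleavage) occurrences, with
  per-occurrence annotation flags computed by interval overlap against the
  protein features, plus aggregate `total_occurrences` and
  `distinct_proteins` counts. Indexes persist to a single self-contained
  text file (`savePeptideIndex()` / `loadPeptideIndex()`).
* **Selection** — queries by accession, protein name or peptide sequence
  (single or batch), the dual-proteome `selectSurrogates()` search, an
  explicit `FilterConfig` with the advised defaults (length 5–22, no M/C,
  0 missed cleavages, no annotated or nonstandard residues, unique in the
  foreground, absent from the background, optional m/z window 400–1600 Th),
  and RFC 4180 CSV export with per-row rejection reasons.
* **Fixtures** — a deterministic generator of synthetic two-species proteome
  pairs with planted unique/shared peptides and machine-readable ground
  truth, used throughout the test suite.
* **CLI** — `inst/scripts/pepdb` with `build`, `info`, `query`, `select`
  and `fixtures` subcommands.

## Worked example

Build a synthetic tumor/host proteome pair, index both with identical
digestion settings, and select surrogate candidates for every foreground
protein under the advised default filters:

```r
library(SurrogatePeptides)

out <- generateProteomePair(fixtureSpec(nProteinsFg = 8, nProteinsBg = 8,
                                        meanProteinLength = 100,
                                        sharedFragmentFraction = 0.4,
                                        nPlantedUnique = 6, seed = 11),
                            tempdir())
params <- digestionParams(enzyme = "trypsin", maxMissedCleavages = 0,
                          minPeptideLength = 3)
fg <- buildPeptideIndex(out$fg, params, label = "tumor")
bg <- buildPeptideIndex(out$bg, params, label = "host")
fg
#> PeptideIndex 'tumor' (8 proteins, 58 distinct peptides, 80 occurrences)
#> DigestionParams: enzyme=trypsin, maxMissedCleavages=0, minPeptideLength=3, prolineRule=TRUE
#>   I/L collapsed for matching: FALSE

rows <- selectSurrogates(fg, bg, accessions(out$fg), filterConfig())
rows[, c("protein_accession", "peptide_sequence", "length", "mass",
         "fg_total_occurrences", "bg_total_occurrences")]
#>   protein_accession peptide_sequence length      mass fg_total_occurrences
#> 1           FGP0004       GWNVTDENHR     10 1226.5428                    1
#> 2           FGP0008          HAWGVGR      7  781.3984                    1
#> 3           FGP0008    HIHQWFYFWVPSK     13 1773.8780                    1
#>   bg_total_occurrences
#> 1                    0
#> 2                    0
#> 3                    0
```

Each surviving row is a candidate surrogate: exactly one hit in the tumor
proteome, zero hits in the host proteome, length 5–22, no methionine or
cysteine, and no overlap with an annotated PTM/variant/conflict/signal
feature. Re-querying the background confirms the absence:

```r
countHits(bg, rows$peptide_sequence[1:3])
#>        sequence total_occurrences distinct_proteins
#> 1    GWNVTDENHR                 0                 0
#> 2       HAWGVGR                 0                 0
#> 3 HIHQWFYFWVPSK                 0                 0
```

Run `selectSurrogates(..., keepRejected = TRUE)` to keep the rejected rows:
each carries its `rejection_reasons` (for example
`"excluded residue M; present in background"`), so no information is lost
when filters are relaxed. `exportSelectionCsv()` writes the result table.

The same pipeline from a shell:

```sh
pepdb=inst/scripts/pepdb
$pepdb fixtures --out-dir fx --seed 11 --fg-proteins 8 --bg-proteins 8
$pepdb build --in fx/fg_proteome.dat --format uniprot --min-len 3 --label tumor --out fg.idx
$pepdb build --in fx/bg_proteome.dat --format uniprot --min-len 3 --label host  --out bg.idx
$pepdb select --fg fg.idx --bg bg.idx --accessions FGP0001,FGP0004,FGP0008 \
       --defaults --out candidates.csv
```

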