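# hairpinforge

Small RNA sequencing analysis for plant transcriptomes: from raw reads to
annotated microRNA hairpins, predicted targets, and expression calls —
with a deterministic synthetic-data generator so every stage can be
validated against planted ground truth.

## Who this is for

Groups profiling small RNA populations in non-model plants typically have
a read library, an assembled unigene/EST set, and no genome. The standard
analysis chain is: clean and collapse reads into unique tags; identify
conserved miRNAs by mismatch-tolerant mapping to known hairpin
precursors; discover novel miRNAs by mapping tags to transcripts, excising
candidate windows, folding them and applying structural annotation
criteria; predict targets by complementarity scoring; and quantify
expression by qRT-PCR. `hairpinforge` implements that chain as a tested,
reusable R package.

## The statistics at the core

**Hairpin annotation.** A candidate precursor is accepted when it passes
the standard plant criteria: (1) ≥ 2 supporting reads; (2) folding free
energy dG < −30 kcal/mol; (3) ≤ 4 unpaired ("mismatched") mature bases in
the miRNA/miRNA\* duplex; (4) ≤ 2 asymmetric bulges in the duplex;
(5) minimal folding free energy index

        MFEI = (|dG| / L × 100) / GC%

of at least 0.85 — plus the structural bounds of the usual prediction
parameter set (≥ 16 paired mature bases, bulges ≤ 3 nt, total duplex
asymmetry ≤ 4 nt, mature–star spacer 5–450 nt, 20-nt flanks). Folding
uses a pluggable engine; the bundled deterministic engine is a weighted
maximum base-pairing dynamic program (GC −3, AU −2, GU −1 kcal/mol,
minimum loop 3 nt, +8 kcal/mol per helix initiation) so tests never
require external software.

**Target prediction.** Sites are scored in sliding 20-ish-base windows
with the classic plant penalty scheme — mismatch 1, G:U wobble 0.5,
gap 2, penalties doubled at miRNA positions 2–13 — and reported at an
inclusive cutoff of 3.0, with the predicted cleavage coordinate opposite
miRNA positions 10–11.

**Expression.** Relative abundance is 2^−ΔΔCq against an endogenous
reference (default `5.8S`); an assay is stress-responsive when some pair
of time points differs by more than two-fold.

## Worked example

```r
library(hairpinforge)

cfg <- sim_config(seed = 42, n_transcripts = 40, n_planted_mirnas = 12,
                  n_decoys = 10, n_clusters = 1, n_multi_mature = 1,
                  n_antisense_pairs = 1, background_tag_rate = 60)
sim   <- generate_transcriptome(cfg)   # transcripts + truth table
reads <- simulate_reads(sim$truth, cfg)
clean <- clean_reads(reads, adapter = cfg$adapter_seq)
tags  <- collapse_tags(clean)
cat("clean reads:", length(clean), " unique tags:", nrow(tags), "\n")
#> clean reads: 774  unique tags: 96
head(size_distribution(tags), 4)
#>   length read_count unique_count read_percent unique_percent
#> 1     18          7            4          0.9            4.2
#> 2     19          6            3          0.8            3.1
#> 3     20         70           14          9.0           14.6
#> 4     21         93            6         12.0            6.3

disc <- discover_mirnas(tags, sim$transcripts, discovery_params())
acc  <- disc$candidates[disc$candidates$accepted, ]
cat("accepted hairpins:", nrow(acc), "of", nrow(disc$candidates), "\n")
#> accepted hairpins: 13 of 23 candidates
acc[1, c("sequence", "dG", "mfei", "paired", "space")]
#>                 sequence  dG      mfei paired space
#>  AGACCGCUCAAUGAGGACGCAAA -43 0.9555556     20    27

feats <- detect_features(acc)
#> clusters: 1 | multi-mature: 1 | antisense pairs: 2
```

The 23 evaluated candidates are tag loci with enough read support; 13
planted hairpins pass all criteria (every decoy fails — most by dG/MFEI,
the rest on duplex geometry). `detect_features` recovers the planted
two-precursor cluster, the precursor that yields both a 5p and a 3p
mature, and the bidirectionally transcribed hairpin pair.

Scanning a "unigene" carrying a planted complementary site:

```r
sites <- scan_targets(mat, unigene, scoring_scheme(), mirna_id = "hf-mir-1")
sites[, c("mirna", "transcript_id", "start", "penalty", "cleavage_pos")]
#>     mirna transcript_id start penalty cleavage_pos
#>  hf-mir-1       PUT0001    60       0           74
#>  hf-mir-1       PUT0001    59       2           74
#>  hf-mir-1       PUT0001    61       2           74
```

The perfect site scores 0 at the planted coordinate (start 60, 0-based);
the two flanking starts are one-gap alignments at penalty 2. The
predicted cleavage position (1-based, opposite miRNA position 10) is the
same for all three.

qPCR analysis from a Cq table (condition, assay, replicate, cq):

```r
fc <- fold_changes(cq_records, "miR6136b", calibrator = "0h")
call_stress_responsive(fc, assay = "miR6136b")   # > 2-fold between any two
crosstalk(list(dehydration = deh_calls, heat = heat_calls))
```

## Layout

- `R/` — modules: `synthetic-data`, `preprocess`, `conserved`, `fold` +
  `discovery`, `targets`, `expression`, `genome`, `reporting`
- `src/fold.cpp` — the bundled folding engine and Hamming scan (Rcpp)
- `inst/extdata/` — reference-table fixtures (TSV, checksum-guarded)
- `vignettes/hairpinforge-methods.Rmd` — models, parameters, design
  choices, and what the synthetic data does and does not establish
- `tests/testthat/` — unit, property and oracle tests;
  `test-acceptance.R` holds the acceptance criteria
- `exec/hairpinforge` — command-line entry point (subcommands
  `preprocess`, `discover`, `targets`, `express`, `genomecov`)

Truth tables document their columns in `?generate_transcriptome`; the
collapsed FASTA uses `tag<N>_x<count>` headers; coordinates are 0-based
half-open internally and 1-based in exports.
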