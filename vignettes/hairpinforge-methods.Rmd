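---
title: "hairpinforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hairpinforge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hairpinforge` re-implements, as a reusable pipeline, the analysis chain
used to profile a plant small RNA population and annotate its microRNAs
when only a transcript (unigene/EST) set is available: read cleaning and
collapsing, conserved-miRNA identification against known precursors,
novel-miRNA discovery by hairpin excision and structural filtering,
penalty-score target prediction, 2^−ΔΔCq expression analysis, and
strand-resolved organelle coverage. This vignette records the models,
the tunable parameters, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. Read cleaning and collapsing

Raw reads are 3′-adaptered small RNA inserts. The adapter is located by
the best ungapped prefix match (≥ 6 nt of the adapter aligned, ≤ 1
mismatch) scanning from the 5′ end, and everything from the match on is
removed. Surviving inserts are kept when they are 18–30 nt, contain no
N, and have mean Phred ≥ 20.

*Open choice — the "low quality" rule.* Upstream pipelines built on
quality-trimming tools rarely state their thresholds. We define low
quality as mean Phred < 20 or any N; both knobs are arguments of
`clean_reads()`. Reads in which no adapter is found are kept when their
full length already lies in the length window, because real libraries
contain a fraction of non-adaptered inserts; `require_adapter = TRUE`
switches to the strict behaviour.

Collapsing produces one *unique tag* per distinct sequence with its read
multiplicity — the unit of every downstream analysis. The invariant
Σ tag counts = clean-read count is asserted in the tests on every
pipeline run. The internal alphabet is RNA (T is converted to U on
input); all I/O accepts either.

## 2. Conserved miRNA identification

Tags are scanned against known precursor sequences with an ungapped
Hamming distance of at most 2, sense strand only — hairpins are
oriented, so an antisense placement on a precursor is meaningless
(transcript and genome mapping elsewhere is two-stranded). A hit is
classified *mature* when its start lies within ±3 nt of an annotated
mature start and it overlaps the annotated interval by ≥ 16 nt,
analogously *star*, otherwise *other*, with precedence
mature > star > other.

*Open choice — the ±3 / ≥16 tolerance.* Published analyses group reads
"mapped to miRNA regions" without stating a window. ±3 nt absorbs the
end heterogeneity that processing leaves on real matures while ≥ 16 nt
of overlap excludes loop-spanning reads. Both are arguments of
`classify_hit()`.

Mature-region tags hitting the same family at the same locus (±3 nt)
merge into a candidate whose representative is the most abundant member
tag; family abundances are reported with one-decimal percentages
computed by `percent()` (decimal half-up rounding — see §8).

## 3. The bundled folding engine

Discovery must fold thousands of windows deterministically and without
external software. The bundled engine is a Nussinov-style dynamic
program minimizing a simple energy: GC −3, AU −2, GU −1 kcal/mol per
pair, minimum hairpin loop 3 nt, and **+8 kcal/mol charged once per
helix** at its outermost pair.

The helix-initiation penalty is the engine's essential calibration.
Pure maximum base-pairing pairs almost every base of *any* sequence, so
shuffled non-hairpin windows would sail past both the dG < −30 and the
MFEI ≥ 0.85 thresholds and the decoy-rejection guarantee of the
synthetic world would be unattainable. With the +8 penalty, short
opportunistic helices cost more than they gain: in the test suite's
random 72-mers the engine reports dG ≥ −22 and MFEI ≤ 0.6, while planted
near-perfect stems report dG ≤ −32 and MFEI ≥ 1. A side effect is that
the closed-form energy of a perfect single-helix stem is the sum of its
pair energies *plus one* initiation (asserted in the tests), and that
helices shorter than ~3–4 pairs do not form. All energies are
engine-relative: they are comparable between candidates folded by the
same engine, not to nearest-neighbour thermodynamics. `fold_rna()`
accepts any function returning `list(structure, dG)` as a drop-in
engine (e.g. a ViennaRNA wrapper), and the engine identity is recorded
in its output.

## 4. Hairpin discovery

Tags with ≥ 2 reads and 18–26 nt are mapped exactly to both transcript
strands (minus-strand hits are reverse-complement matches, reported in
forward coordinates). Tags mapping to more than `uniqueness = 280` loci
are dropped as repeats. Around each locus, candidate windows are excised
for a grid of spacer extents (15–450 nt, both star-downstream and
star-upstream), folded, and the miRNA\* is read off the structure as the
duplex partner span of the mature; the window is then trimmed to the
putative precursor (duplex ± 5 nt) and refolded, and dG, GC fraction and
MFEI are computed on the trimmed hairpin so that long windows do not
dilute MFEI.

Because a refold of the trimmed sequence can occasionally restructure,
the duplex is assessed both in the original window fold and in the
refold, and the better verdict is kept; per locus the best window wins
(accepted first, then fewest failed criteria, then lower dG), stopping
at the first accepted window.

The acceptance criteria are the standard plant set: ≥ 2 reads;
dG < −30; ≤ 4 unpaired mature bases in the duplex; ≤ 2 asymmetric
bulges; MFEI ≥ 0.85 — plus the structural bounds ≥ 16 paired mature
bases, single bulges ≤ 3 nt, total duplex asymmetry ≤ 4 nt, spacer
within 5–450 nt, and mature length within 18–26 nt. All thresholds live
in `discovery_params()`. Acceptance is monotone: tightening any
threshold can only reject (property-tested).

*Open choices.* "Mismatched miRNA bases" is read as unpaired mature
positions within the duplex (the usual structural reading); "duplex
asymmetry" as |unpaired on the mature arm − unpaired on the star arm|
summed over the duplex's internal loops. The star, when not sequenced,
is the duplex partner with a 2-nt 3′ overhang; sequenced star reads are
matched with ±2 nt tolerance. Families of accepted precursors are
grouped by single-linkage clustering at ≥ 80 % identity (the published
grouping states "sequence similarities" without a threshold).

`detect_features()` reports the precursor-level structures that real
populations show: clusters (≥ 2 disjoint precursors in one transcript),
multi-mature precursors (≥ 2 accepted mature loci in one hairpin, e.g. a
5p/3p pair), and antisense pairs (overlapping precursors on opposite
strands — the reverse complement of a hairpin is itself a hairpin, so
bidirectional transcription of one locus can yield two miRNAs).

## 5. Target prediction

The classic plant penalty scheme: mismatch 1.0, G:U wobble 0.5, gap 2.0,
all doubled when the miRNA position lies in the seed (2–13, 1-based from
the 5′ end); at most one gap; cutoff 3.0 *inclusive*. Scoring is an
optimal alignment over the ≤ 1-gap alignment space, verified in the
tests against a naive alignment enumerator. The predicted cleavage
coordinate is the transcript base opposite miRNA position 10 (1-based),
the canonical slicing register.

*Open choice.* The web service used in the original analyses does not
print its weight set, and its 2012 weights are unrecoverable; the scheme
above is the classic one and every weight is an argument of
`scoring_scheme()`. Parity with any external server's scores is
explicitly not promised; the packaged target-table fixture carries the
published penalty values as metadata only. Transcripts of unknown
orientation can be scanned on both strands (`both_strands = TRUE`) and
are flagged.

## 6. Expression analysis

ΔCq is the arithmetic mean Cq of the assay minus that of the reference
(default `5.8S`) per condition; ΔΔCq subtracts the calibrator; fold
change is 2^−ΔΔCq, so the calibrator is exactly 1. Replicate SD is
reported two ways — over per-replicate ΔCq and over per-replicate fold
changes — because published error bars rarely state which was used. A
condition lacking the reference is reported missing, never zero.
Stress-responsiveness means a > 2-fold difference between *some pair* of
time points (matching fluctuating published profiles, where the extremes
are often two non-baseline points); `mode = "baseline"` restricts to
ratios against the first time point. Crosstalk is the intersection of
responsive sets across ≥ 2 stressors.

## 7. Organelle coverage

Exact mapping of tags against a single reference on both strands, with
full read weight at every locus by default — a tag inside a plastid
inverted repeat is counted at both copies, matching genome-wide coverage
plots; `weight = "fractional"` divides instead. Coverage mass
conservation (Σ coverage = Σ count × length over mapped loci) is
property-tested. Clusters are runs of covered positions merged across
gaps < 100 nt and kept at ≥ 50 reads; antisense counts are stored
non-negative and negated only in exports.

## 8. Reporting arithmetic

`percent()` uses decimal half-up rounding to one decimal, matching how
percentages are conventionally printed (R's `round()` is banker's
rounding on binary floats and disagrees on exact halves). The packaged
reference tables are TSV transcriptions guarded by md5 checksums and
row-level invariants (printed size must equal sequence length; penalties
within [0, 3]); `fixture_counts()` derives mature, precursor, family and
target counts from them, collapsing rows that share a precursor key.
One published percentage (a family share printed as 74.8 % where the
quotient rounds to 74.7 %) is not reproducible under any standard
rounding; the package computes 74.7 and the discrepancy is documented
rather than patched.

## 9. The synthetic world: what a green test establishes

`sim_config()` describes a stated world, not a tuning dial:

- **50 planted precursors** (2 two-precursor clusters, 2 multi-mature,
  2 antisense pairs) and **50 decoys** among 120 transcripts of
  300–800 nt — large enough to exercise every feature detector, small
  enough to run in seconds.
- **Stems** are 32-bp inverted repeats with exactly ⌊9 %⌋ substitutions
  (≈ 91 % paired, the "near-perfect" regime of real pre-miRNAs), arm GC
  constrained to 0.45–0.65, and an A/C 12-nt loop. The substitutions sit
  in the middle half of the stem so every helix segment is long enough
  to form under the engine's initiation cost; replacements are chosen
  never to re-pair (no accidental wobble). This construction guarantees
  dG < −30 and MFEI ≥ 0.85 under the bundled engine — asserted, not
  assumed.
- **Decoys** are composition-shuffled windows re-sampled until the
  engine scores them as non-hairpins (fails dG or MFEI), so "0 decoys
  accepted" tests the duplex criteria as well as the energy ones. Decoys
  carry a read-source window (recorded in the truth table) so that decoy
  reads actually reach the discovery stage; they have no star.
- **Depths** are log-normal (meanlog log 20, sdlog 1.2) with a floor of
  5 reads, emulating the heavy skew of real tag-abundance distributions
  qualitatively, not numerically. Stars get 1 read each — below the
  2-read threshold, as sequenced stars are rare — which also prevents
  every star from being spuriously promoted to a second mature.
- **Reads** are error-free with constant Phred 40 by default;
  quality-filter behaviour is exercised by a separately planted
  low-quality fraction, and error/jitter knobs exist but default to 0.
- **Determinism:** one integer seed; `generate_transcriptome()` seeds
  the stream at `seed`, `simulate_reads()` at `seed + 1`, drawn in fixed
  order — identical configs give byte-identical outputs (asserted).

What a green recovery test does **not** establish: performance on real
error profiles, on multi-locus miRNA families with cross-mapping reads,
on AU-extreme genomes, or agreement with a thermodynamic folding engine.
The generator plants the structures the method is designed to find; it
validates the plumbing and the criteria logic, not biological recall.

## 10. Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally and 1-based in exports.
Ties in the folding traceback are broken deterministically (stacking
preferred, then leftmost split). Zero denominators in `percent()` yield
0.0. Empty tag sets, empty FASTQ files, windows shorter than 50 nt, and
profiles lacking the reference assay all return typed empty results or
documented errors rather than NA-laden frames. Configuration files for
the CLI are JSON (a YAML reader is deliberately not required — JSON
support ships with the dependency set already used for the acceptance
report).

## Known limitations

- The bundled engine's energies are not thermodynamic; dG/MFEI
  thresholds are engine-relative (the thresholds were designed for mfold
  energies, and with a real engine plugged in the same defaults apply).
- Exact mapping only for transcripts/genome (the mismatch-tolerant path
  exists only against known precursors, as in the original chain).
- Single-end, adapter-at-3′ libraries; no UMIs; no paired-end logic.
- `scan_targets()` is plain R; scanning many miRNAs against tens of
  thousands of unigenes would want the same treatment the folding engine
  got (a small C++ kernel).
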