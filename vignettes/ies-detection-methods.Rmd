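---
title: "Detecting internally eliminated sequences from mapped long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internally eliminated sequences from mapped long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `iesweave`, the
reasoning behind its tunable parameters and numerical choices, and what the
package's simulation-based validation does and does not demonstrate.

## Background and model

Ciliate somatic (MAC) genomes are edited copies of the germline (MIC)
genome: during development, thousands of internally eliminated sequences
(IESs) are excised and chromosomes are fragmented with de novo telomere
addition. An IES is typically flanked in the germline by a short tandem
repeat (the *pointer*), one copy of which remains in the MAC; in several
lineages excision is performed by domesticated piggyBac-family transposases
and the pointer is exactly `TA`.

When long reads from MIC-containing DNA are mapped to the MAC assembly:

* a retained IES inside a read appears as a CIGAR **insertion** (`I`) at
  the excision junction;
* a read crossing a chromosome breakage site carries the unaligned
  telomeric repeat as a terminal **soft clip** (`S`).

All internal coordinates are 0-based and half-open, matching the BAM frame.
An insertion is a zero-width event indexed by the first reference base
*after* it; GFF3 output converts to 1-based coordinates at exactly one
point (`write_gff3`). Only primary alignments are used anywhere, so each
sequenced molecule contributes once; secondary and supplementary records
are skipped on input.

Because one pointer copy flanks the insert, the junction coordinate is
ambiguous up to a shift: inserting the same sequence one base further left
or right can imply the identical germline sequence. The package
left-normalises every insertion (shift left while the last inserted base
equals the reference base left of the junction) and reports the pointer as
the prefix-side repeat. Normalisation never changes the implied MIC
sequence — this is a tested invariant.

## De novo IES calling

`call_iess()` proceeds per contig:

1. **Evidence extraction.** Every `I` operation of length ≥
   `min_insert_len` (default 10 bp) in a primary alignment with MAPQ ≥
   `min_mapq` (default 1) yields one insertion observation. The length
   floor separates IES-scale inserts from the 1–3 bp indel noise of raw
   subreads; MAPQ ≥ 1 excludes multimappers. Both are exposed because the
   right values depend on read chemistry.
2. **Clustering.** Observations are clustered by single linkage: a new
   cluster starts when the gap to the previous junction exceeds
   `max_cluster_dist`. Defaults are 3 bp for CCS (junctions are near
   exact) and 10 bp for subreads (alignment jitter). Within a cluster a
   read contributes once (its longest insert). Clusters below
   `min_coverage` distinct reads (default 5) are dropped — with fewer
   supporting molecules neither the junction nor the consensus is
   reliable.
3. **Length classes.** If member insert lengths are multimodal (a > 2×
   ratio between consecutive sorted lengths), the cluster is split by
   length class before consensus, preventing chimeric consensus sequences
   when two distinct events co-locate.
4. **Consensus.** In CCS mode the junction is the modal member junction
   and the insert consensus is taken directly over member insert
   sequences (polishing is cheap and removes residual ~1% errors; taking a
   single representative was the alternative and is strictly worse). In
   subread mode, each member read is sliced around its insert with up to
   `flank_len` = 100 bp of read sequence per side (truncated at read
   ends), and the segments are assembled to a consensus.
5. **Realignment.** The flank-anchored consensus is globally realigned to
   the reference window spanning the cluster; the longest consensus-only
   run in the traceback is the insert, and the reference coordinate at
   that run is the junction. The flanks anchor the alignment so junction
   and sequence are re-estimated jointly. If no run reaches
   `min_insert_len` the cluster is rejected (reported, not fatal).
6. **Annotation and scoring.** Pointer and TA status are annotated after
   left-normalisation. The per-site retention score is computed from all
   primary reads spanning the refined junction (below). Records whose
   spanning-read support falls below `min_coverage` after refinement are
   rejected: a call must still be backed by `min_coverage` molecules that
   carry the insert *at the refined junction*, which removes clusters of
   scattered error insertions.

### The consensus primitive

The consensus is an iterative star alignment. The member of median length
seeds the backbone; every member is globally aligned to it
(match +2, mismatch −4, gap open −4, gap extend −2); each backbone column
is called by majority vote, with deletions voting gaps; bases inserted
relative to the backbone are accepted only when more than half of the
members insert at the same backbone junction (the most frequent inserted
string wins). The vote is then repeated with the round-1 consensus as
backbone (2 rounds by default, `rounds`). The second round matters: a raw
read backbone has private indels, and gap-placement wobble around them
leaves transposition-like artefacts that a re-vote against a
majority-structured backbone resolves. Under insertion-dominated long-read
noise this design is robust by construction — independent error insertions
never reach majority, while a base the backbone happens to lack is
recovered from the other reads. All tie-breaks are fixed (base order
A < C < G < T, a base beats a gap, insertion strings by count then
lexicographic order), so output is deterministic for a given input order,
and inputs are pre-sorted — identical inputs give byte-identical GFF3/FASTA.

### Numerical choices

* **Realignment scoring** (match +2, mismatch −4, gap extend −2,
  configurable): the gap-opening penalty defaults to −12, deliberately
  stiffer than the star-alignment's −4. Ciliate MAC genomes are AT-rich
  (~72% AT here); with a weak opening penalty the optimal global alignment
  of a consensus against its window profitably *fragments* a genuine
  60 bp insertion into several short runs by collecting chance ~6-mer
  matches from the flank, mis-placing the junction by ~10 bp and
  truncating the insert. Opening at −12 makes fragmentation unprofitable
  (splitting a run to harvest k matched bases gains 2k but pays 12) while
  leaving isolated error indels cheap.
* **Traceback ties** go to the single longest insertion run, then the
  leftmost; junctions are then left-normalised, so shift-ambiguity never
  reaches the output.
* **Degenerate inputs**: empty BAMs yield empty (but valid) outputs; a
  consensus identical to the reference window is a rejected cluster;
  IUPAC ambiguity codes other than N in the reference are mapped to N
  with a warning at load time.

## Retention scoring and read binning

A read **spans** a junction when its aligned reference interval covers
`junction ± buffer` (default 15 bp): enough context to distinguish a true
pass over the junction from an alignment ending nearby, but small relative
to IES spacing. A spanning read **retains** the IES when it has an
insertion ≥ `min_insert_len` within `buffer` of the junction. A read
clipped inside the insert does not cover both flanks and is counted
`not_spanning` — it gives no evidence either way.

The per-site score is `retained / (retained + excised)`; sites with no
spanning read report a missing score rather than 0. The per-read score is
the fraction of spanned annotated sites at which the IES is retained; reads
spanning no site are *unscored*. Both scores are aggregations of one
spanning-status classification — the same code path — so the sum of
per-read retained counts equals the sum of per-site `ies_plus` by
construction (and by test). `bin_reads` uses inclusive-outward thresholds
(≥ 0.9 MIC-like, ≤ 0.1 MAC-like); a pure germline read scores 1 and a pure
somatic read 0, so the wide middle band flags chimeras, partially edited
molecules, and annotation errors.

## Breakage-site detection

Soft clips of ≥ 24 bp whose sequence is at least 70% covered by exact,
overlapping occurrences of any rotation of the telomere unit (or of its
reverse complement's rotations — clip sequences are reference-oriented, so
both strands occur) are breakage evidence. Rotation invariance removes the
repeat-phase nuisance; exact matching plus the coverage threshold, the
clip-length floor, and single-linkage clustering (≤ 10 bp) with a
`min_break_coverage` of 3 reads absorb ~10% read error without
alignment-based repeat scoring. The default unit `TTGGGG` is the ciliate
G4T2 repeat; a vector of units is accepted for mixed-repeat genomes.

## The simulator: what it emulates, and what it does not

`make_genomes()` builds MAC contigs as iid sequence at 28% GC (AT-rich,
Paramecium-like) and plants IESs with guaranteed junction spacing
(≥ 2 × 100 bp, so flank windows never straddle two IESs; real IESs can sit
closer). Each IES is pointer + random core; the MAC bases right of the
junction are set to the pointer, giving the germline form the repeat at
both ends. Defaults: uniform 26–100 bp lengths (the short-IES regime;
26 bp is the canonical minimum in *Paramecium*) and `ta_fraction = 1`
(essentially all *Paramecium* IESs are TA-bounded); both are free
parameters, and the non-TA fraction draws pointer lengths 0–8. Planted
junctions are left-normalised by construction and pointers are exact (the
core never extends the repeat), so truth coordinates are directly
comparable to normalised calls. Re-inserting every IES must reproduce the
MIC contig exactly; the generator verifies this before returning.

`simulate_reads()` draws reads at the requested depths (defaults 20× MAC +
20× MIC; lengths normal with mean 8 kb, sd 2 kb, floor 500 bp) and applies
an iid per-base error model: substitutions 2%, insertion events 3% with
geometric (mean 2) lengths, deletions 2% — about 10% base-level error,
insertion-dominated like PacBio subreads. It emits the *error-aware true
alignment* of every read as a sorted, indexed BAM: planted IESs appear as
`I` operations at the true junctions, errors as short indels, partial IESs
at read ends as soft clips. This truth-BAM path makes the pipeline
testable hermetically and is the primary validation route; the FASTQ is
also written so a real mapper can be substituted.

Two idealisations matter when reading validation numbers. First, truth
alignments have no mapping error: junction positions in the BAM are exact
up to simulated indels, whereas a real mapper adds placement jitter and
occasional mismapping — so recall/precision and assembly-accuracy figures
from this simulator are upper bounds on real-mapper performance, and the
package's figures on its own simulation exceed those achievable on real
subread data. Second, the iid error model has no context-dependent error
hot-spots and the genome has no true repeats or scrambled regions.
Passing tests therefore demonstrate the correctness of the evidence
extraction, clustering, consensus, realignment, annotation and scoring
machinery under realistic noise *rates*, not performance on repetitive or
scrambled genomic context.

Determinism: every generator function seeds R's RNG from `sim_params`
(`seed` for the genome, `seed + 1` for reads by default), so outputs —
including BAM bytes — are identical across runs and platforms.

## Evaluation

`evaluate_calls()` matches predictions to truth one-to-one, greedily by
junction distance within `tol_bp` (closest first; ties to the leftmost).
Recall is matched/truth, precision matched/predictions. For matched pairs
the insert sequences are compared under a Levenshtein-style global
alignment; the evaluator reports the counts assembled exactly and within
at most one mismatch and one indel base. Greedy matching equals optimal
bipartite matching on realistic instances (tested by enumeration on small
cases); recall is non-decreasing in `tol_bp`.

## Validation scales used by the test suite

The test suite validates against independent oracles (per-base CIGAR
walks, transitive-closure clustering, shift-enumeration pointer search,
exhaustive matching) and runs an end-to-end parameter recovery on a
seeded 0.5 Mb genome with 120 IESs at 20× + 20× coverage and ~10% error,
plus 10× vs 30× MIC coverage on the same genome for the coverage-response
check. These sizes keep the statistical regime of interest (short IESs,
20× depth, subread noise) while remaining quick to run; the acceptance
script (`scripts/acceptance.R`) re-runs the same design from scratch under
a caller-supplied seed.

## Known limitations

* Scrambled rearrangements are out of scope; only non-scrambled,
  insertion-type IESs are called.
* IESs longer than the typical read cannot be reconstructed — too few
  reads span the full insert; such loci surface as rejected clusters.
  Binning germline-like reads with `bin_reads` and assembling them is the
  intended workaround.
* Deletion-type evidence (reads mapped to an IES-containing reference) is
  not extracted; the reference is assumed to be the edited MAC form.
* Breakage-site detection reports telomere-bearing clip clusters; it does
  not estimate telomere length, and it cannot distinguish genuine
  alternative breakage from assembly artefacts at contig ends.
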