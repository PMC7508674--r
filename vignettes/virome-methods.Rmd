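---
title: "Methods: RdRP discovery from bulk metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RdRP discovery from bulk metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `viromescan`, and what the synthetic-virome tests do and do
not demonstrate about real data.

## The problem

Bulk RNA sequencing of an aquatic habitat captures the transcriptomes of the
whole community — hosts, bacteria, and the RNA viruses that are invisible to
DNA sequencing. The one protein shared by all RNA viruses is the
RNA-dependent RNA polymerase (RdRP), whose catalytic core carries three
conserved sequence motifs (A, B, C). The pipeline discovers RdRP cores in
assembled contigs and characterizes three complications that real surveys
encounter: contamination of the RNA library with DNA-derived reads,
RNA viruses that use alternative genetic codes (reassigned stop codons,
typically in ciliate hosts), and a circular permutation of the RdRP in which
motif C precedes motifs A and B.

## Read preparation

Ends of reads are trimmed to the longest run whose first and last bases have
quality at least Q20 (Phred+33); interior low-quality bases are retained, as
end-trimming tools do. Subtraction indexes every unique 30-mer of the DNA
library and removes any RNA read — and its mate — with one exact match. Two
choices are deliberate:

* **Canonical k-mers.** cDNA libraries sample both strands, so k-mers are
  strand-collapsed (lexicographic minimum of a k-mer and its reverse
  complement). A `stranded` flag disables this for directional protocols.
* **N handling.** Windows containing non-ACGT characters are neither
  indexed nor matched: an N never matches exactly.

Subtraction is idempotent, and decreasing k can only grow the removed set
(every 30-mer match implies a 25-mer match); both properties are asserted in
the tests, along with exact agreement with a brute-force window-matching
oracle.

## Contig unification and the long-ORF screen

When two assemblies are merged (e.g. a paired-end random-priming assembly
and a single-end template-switching assembly), a secondary contig is dropped
iff strictly more than 90% of its distinct canonical 15-mers occur in the
primary set. The denominator is the contig's own distinct-k-mer count; the
boundary is exclusive, so a contig sharing exactly 90.0% is retained. The
screen for highly divergent candidates translates contigs strictly longer
than 1,200 nt stop-to-stop in six frames and reports open reading frames
strictly longer than 400 amino acids under the standard code.

## RdRP core detection

Contigs are translated end-to-end in all six frames (forward offsets 0–2 and
the same on the reverse complement); each frame is segmented into maximal
stop-free runs, and every segment is scanned by a local
(Smith–Waterman-style) alignment of a position-specific scoring matrix with
affine gap costs. Parameters:

* **Scores** are log-odds of column frequency over fixed
  Robinson–Robinson-style background frequencies, in half-bit units
  (2·log2), with one background-proportional pseudocount per column; columns
  with more than 50% gaps are dropped.
* **Gap penalties**: open 11, extend 1 (half-bits), the BLAST convention for
  protein search.
* **Coverage** is the number of profile columns consumed between the first
  and last aligned column — matched *or deleted* — divided by the profile
  length. A hit with coverage ≥ 0.75 (inclusive) is a full-length core.
* **Reporting threshold**: 0.02 bits per profile column, a declared knob;
  no e-value machinery is attempted.

Two scanning modes exist. The default scans each maximal stop-free segment
separately, which is the right contract for a standalone search. The
pipeline, however, scans each frame end-to-end with stops scored as unknown
residues (`stop_tolerant`): a virus using a reassigned genetic code shows
in-frame standard-code stop codons *inside* its core, and only an alignment
that crosses them can establish core boundaries whose stop-codon census then
reveals the alternative code. Without this mode, alternative-code cores
fragment into stop-free pieces and are mis-censused as standard-code.

The aligner is implemented in C++ (three-state affine dynamic programming
with start-coordinate propagation); the test suite checks its scores against
an independent full-matrix dynamic program written in plain R on randomized
instances. Reverse-frame hits are mapped back to forward-strand coordinates;
all coordinates inside the package are 0-based half-open, converted to
1-based inclusive only in exported report tables.

## Alternative genetic codes

Cores whose standard-code translation contains stop codons are re-translated
in the call's frame under every table of the bundled NCBI genetic-code
collection, and the table yielding the longest stop-free protein containing
the core is selected; stop-free cores keep the standard code without
scanning, and ties resolve to the standard table first, then the lowest
table id. Core boundaries are *not* re-mapped after reassignment: the frame
and span established by the profile search are kept fixed.

An identifiability caveat shapes the synthetic defaults. Many NCBI tables
share the effective stop set {TAA, TAG} and are mutually indistinguishable
by any stop-codon census — for such truth tables the longest-protein rule
resolves by flank noise or tie-break, and no method can recover the exact
table. The generator therefore defaults to `identifiable_code_pool()`: the
tables whose reassigned standard stops collectively block every other
bundled table inside a core that carries all of them (tables 6 and 14 in the
current collection — including the ciliate-type TAA/TAG → Gln code that
dominates real surveys). The generator plants at least five in-frame
occurrences of *each* reassigned stop codon, which both guarantees
identifiability and mirrors the observation that alternative-code cores show
many in-frame standard stops. The pool is a visible, configurable parameter.

## De-permutation

Motifs are placed by gapless alignment of each motif sub-profile at every
offset (motifs are 6–8 columns; gapped placement adds nothing at this
scale). The best non-overlapping triple among the top five placements per
motif (≤ 125 combinations, exhaustive) gives the annotation; a placement
scoring below half the motif's maximum attainable score is reported as
"motif not found" — a floor the tests validate against the score maxima of
hundreds of random proteins. A protein is permuted iff motif C starts before
motif A.

Restoration excises the fragment from the start of motif C up to (not
including) motif A and reinserts it immediately after motif B. Two
consequences follow by construction:

* Linker residues between the catalytic loop and motif A travel with the
  fragment; leaving them behind would break round-trip identity.
* The generator's canonical layout places motif C immediately after motif B
  (zero B–C linker), because the restore rule inserts the fragment at
  motif B's end; any canonical B–C linker would be relocated and the exact
  round trip would fail. The permuted fragment is motif C plus a fixed
  16-residue loop.

With the deletion-counting coverage definition above, a *full-length*
permuted core still reaches high coverage (the aligner bridges the displaced
loop with one insertion and one deletion), so permutation mainly distorts
coordinates and alignments rather than suppressing detection; the test suite
demonstrates the coverage effect of restoration on cores truncated right
after motif B scanned with a 210-column sub-profile, where the permuted form
scores 156/210 ≈ 0.74 (below the full-length rule) and the restored form
178/210 ≈ 0.85 (above it).

## Clustering, trees and clades

Pairwise identity is identical residue pairs from a global BLOSUM62
alignment (gap open 11 / extend 1) divided by the length of the shorter
sequence (an MMseqs-like convention; an aligned-columns denominator is
available). Greedy clustering sorts sequences by length (ties by id) and
assigns each to the first representative with identity at or above the
threshold — deterministic and order-invariant by construction. Default
thresholds are 0.50 (similarity-level) and 0.75 (between the species and
genus ranks for RdRPs).

Trees are neighbor-joining on Poisson-corrected distances
d = −ln(1 − p) with p = 1 − identity capped at 0.95 (cap keeps distances
finite for unrelated sequences). Externally computed Newick trees (e.g.
maximum-likelihood trees) are accepted through the same reader. Clade
delineation traverses internal nodes from the root and accepts a node when
at least 90% of its leaves are metagenome-derived or when its depth is below
1.0 substitutions/site; accepted subtrees are pruned, making calls maximal
and non-nested. "Depth" is read as the node-to-deepest-descendant-leaf
distance — the rule describes the internal shallowness of a group, not its
distance from the root. Unrooted inputs are midpoint-rooted. Leaves are
candidates only as members of internal nodes; isolated leaves are reported
unassigned.

## Spacers and abundance

CRISPR protospacers are matched on both strands by local alignment
(match +2, mismatch −3, gap open 5 / extend 2 — declared knobs); identity is
counted over aligned columns and coverage over the spacer length, both
thresholds at 0.90 inclusive. Abundance is
RPKM = m / (L/1000) / (N/10^6) with per-read (not per-fragment) counting;
covered fraction is the union of aligned reference spans. Distribution
summaries report the median of positive RPKMs, the modal peak as the center
of the highest Freedman–Diaconis bin of log2 RPKM (back-transformed), the
mean/sd of ln RPKM as a log-normal fit, and right-skew excess as the
observed over expected count above the fit's 99.9th percentile.

## The synthetic virome: what it emulates and what it does not

`generate_genomes()` draws genome lengths uniformly on 2.5–12 kb, embeds one
780-nt core on a forward frame with random flanks, mutates the consensus
core at a configurable per-site rate (default 0.1, tests use up to 0.2)
outside the conserved blocks, draws abundance weights log-normally
(meanlog 3, sdlog 1 — the survey literature reports a log-normal-like
abundance shape but not its dispersion, so sdlog is a free generator
parameter), and emits 150-nt paired or single reads with uniform per-base
substitution errors and flat qualities `round(−10·log10(error_rate))`
(capped at Q40, also used when the error rate is zero).

Deliberate idealizations, hence limits of what green tests prove:

* **Conserved terminal anchors.** Besides motifs A/B/C, the first and last
  three core residues are never mutated. Local alignment provably trims
  mutated terminal residues, so exact nucleotide-level span recovery at
  divergence 0.2 is impossible for any local aligner without some terminal
  conservation; real surveys report core spans only up to alignment
  resolution. Recovery rates on real data will be bounded by terminal
  variability.
* **Substitutions only** — no indels in genomes or reads, no quality drift
  along reads, no chimeras, and assembly is out of scope (contigs are taken
  as given; a perfect-assembly hand-off is used in tests).
* **One consensus family.** All synthetic cores descend from a single
  260-residue consensus with fixed motif strings; detection profiles are
  built from generator output at test time, never from hard-coded motif
  strings, but profile diversity is far below a real RdRP profile
  collection.
* **Reverse-strand genomes are not generated** (+RNA biology); strand
  handling is still exercised because reads and spacers come from both
  strands and scanning covers all six frames.

## Problem sizes in the shipped checks

The test suite and the acceptance script exercise: subtraction on 1,000
reads against a brute-force oracle with k ∈ {20, 25, 30}; span-exact core
recovery on 300–500 genomes at divergence 0.15; genetic-code recovery on
150–300 alternative-code genomes plus a 1,500–2,000-genome virome at 1.3%
alternative-code incidence (the zero-stop fraction is checked against the
exact binomial interval around 98.7%); de-permutation round trips on
100–200 permuted cores; clustering of 8–12 synthetic families; clade calls
against brute-force enumeration on 100 random trees of up to 50 leaves; and
abundance with a genome planted at 800× the median weight under multinomial
read allocation. These sizes keep a complete run in minutes on one CPU
while leaving every statistical check well-powered.
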