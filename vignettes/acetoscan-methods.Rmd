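---
title: "Methods: FTHFS amplicon profiling with acetoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTHFS amplicon profiling with acetoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

Acetogens — anaerobic bacteria running the complete Wood–Ljungdahl pathway —
are polyphyletic, so they are surveyed through the formyltetrahydrofolate
synthetase (FTHFS) marker gene rather than 16S rRNA. The degenerate primer
pair targeting FTHFS (`CCIACICCISYIGGNGARGGNAA` forward,
`ATITTIGCIAAIGGNCCNSCNTG` reverse, written 5'→3', `I` = inosine) yields
amplicons of roughly 635 bp. Because that exceeds the merge reach of
2 × 300 bp short-read chemistry, forward (R1) and reverse (R2) reads are
analyzed separately as single-end data; antisense orientation of R2 reads
needs no special handling because frame selection considers both strands.

The pipeline runs four stages: read QC, OTU inference, translated-search
taxonomy, and phylogeny plus community summaries. This vignette records the
model behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic data generator does and does not
emulate.

## Stage 1: primer trimming and quality filtering

*Primer matching* is substitution-only: the leftmost window whose Hamming
mismatch count under IUPAC set-intersection matching is at most
`floor(error_rate × L)` wins (`error_rate` default 0.10; the 23-symbol
primers therefore tolerate 2 mismatches). Inosine and primer `N` match any
base; a read `N` matches only primer `N`/`I`, so uncalled bases never count
as evidence. Indels are not modeled: the primers are short, degenerate, and
short-read errors are substitution-dominated, and a pure Hamming scan is
exactly testable against a brute-force oracle. The primer may start anywhere
in the read (tolerating ligation-adapter remnants); everything through the
primer's 3' end is removed. Reads without a primer match are discarded by
default (`require_primer = TRUE`) since non-amplicon reads cannot be FTHFS;
a flag retains them for diagnostics.

*Quality trimming* uses the running-sum rule: scanning from the 3' end with
cutoff `Q` (default 20), the read is cut at the point maximizing
`sum(Q − q_j)` over the trimmed suffix, keeping as much sequence as possible
on ties. The rule is idempotent, leaves all-good reads untouched, and
empties uniformly bad reads.

Order of operations is primer removal → quality trim → truncation to
`max_length` (300 nt, the read-length ceiling of the chemistry; truncation
rather than rejection because over-length input only arises synthetically)
→ rejection below `min_length` (120 nt). Each rejection is tallied by
reason (`no_primer`, `too_short`, `empty_after_trim`) and read counts are
conserved across the tally.

## Stage 2: dereplication, chimeras, clustering

Dereplication is exact string collapse over all samples jointly, sorted by
total abundance then lexicographically — this sort makes every downstream
step invariant to read order.

*Chimera flagging* is de novo and two-parent: for query `q`, candidate
parents are sequences at least `abundance_skew` (2.0) times more abundant;
`q` is aligned to its top 8 candidates by identity, and for every ordered
parent pair and crossover position the model identity (query positions
matching parent A left of the crossover, parent B right of it) is computed
from per-position match vectors in O(n) via prefix sums. `q` is flagged when
the best model identity is ≥ 0.99 and beats the best single parent by
≥ 0.04. The 0.99/0.04 margins are package defaults: 0.99 demands the
crossover model explain essentially every base, and 0.04 is large enough
that a pair of 0.90-identity parents (typical for congeneric templates)
cannot trip it by chance. Detection is de novo because no reference
nucleotide set is guaranteed to exist for this marker.

*Clustering* is greedy and centroid-based: sequences are scanned in
abundance order and join the first centroid (in creation order) whose
identity reaches the threshold, else found a new cluster. Identity comes
from a semi-global Needleman–Wunsch alignment (match +2, mismatch −4, gap
open −10, gap extend −1, affine cost `open + L × ext`): terminal gaps are
free only on the longer sequence's side, so the shorter sequence is aligned
end to end and identity is counted over alignment columns excluding
terminal-gap columns. This makes a 300 nt read and its own 150 nt prefix
score 1.0 — required for mixed-length datasets — while divergent
equal-length sequences are compared over their full span (a fully free
"dovetail" alignment would instead collapse to a trivial corner overlap of
a few matching bases and report spurious identity 1.0). At a threshold of
exactly 1.0, membership requires string equality, so clusters are
exact-duplicate groups and clustering coincides with dereplication. The
scoring constants are package choices (configurable); the published
parameter set fixes only the 80% threshold — chosen because ~78% similarity
in translated-vs-protein searches suffices for genus-level classification
of this marker — and the minimum cluster size of 2, which is also the
pipeline's entire "denoising" model: OTUs below the minimum size are
discarded, with chimera removal applied first, both before taxonomy.

## Stage 3: best-frame selection and translated search

Each centroid is translated in all six frames (standard genetic code;
ambiguity codes translate to `X` unless redundancy still determines the
residue), and the longest contiguous stop-free run is selected; ties go to
frame order +1, +2, +3, −1, −2, −3, then to the leftmost run. Runs under 10
residues flag the sequence as degenerate (frame choice would be noise). The
stop-free *segment*, not the whole frame, is carried forward. A known
stochastic limit of this rule: an antisense frame of a ~240 nt coding read
is fully stop-free a few percent of the time, and if its run is at least as
long as the true frame's, the wrong frame wins — occasionally costing one
OTU's classification. This ambiguity is inherent to single-read frame
selection, and the tie-break keeps it deterministic.

The selected protein is aligned to every reference entry by Smith–Waterman
with BLOSUM62 and affine gaps (open 11, extend 1, cost `11 + L`);
traceback is deterministic (highest cell, ties to smallest row then
column). Significance uses the Karlin–Altschul form with the published
gapped BLOSUM62-11-1 constants λ = 0.267, K = 0.041:
`bit = (λS − ln K)/ln 2`, `E = m·n·2^(−bit)` with `m` the query length and
`n` the total database residues. An OTU is a target when its best hit's
E-value is at or below 1e-3; its lineage is the best hit's lineage
verbatim — best-hit semantics, no lowest-common-ancestor voting, matching
how misassignments were anatomized for this marker. Hits are ranked by bit
score, then E-value, then lexicographic accession, which makes
classification invariant to database order.

Lineages are prefix-annotated: once a rank is missing all lower ranks are
missing (mid-lineage gaps are truncated at load time with a warning, so
rank-collapse logic never sees a hole). Display labels at a missing rank
use the deepest annotated ancestor suffixed `.NA`; fully unannotated
lineages render `Unclassified`.

## Stage 4: alignment, tree, community summaries

The progressive MSA builds a UPGMA guide tree from fractional common 6-mer
distances (`1 − shared/min(|A|,|B|)` over distinct 6-mer sets) and merges
profiles by global profile–profile alignment (match +5, mismatch −4, gap
open −10, extend −0.5, sum-of-pairs column scores averaged over residue
pairs; gaps contribute nothing to column scores and are handled by the gap
moves). Inputs are processed in lexicographic id order so the result is
independent of input order; ungapping any row recovers its input exactly.

Distances are Jukes–Cantor, `d = −(3/4)·ln(1 − (4/3)p)`, with `p` computed
over columns where neither row has a gap (pairwise deletion — robust for
mixed-length OTUs) and capped at 0.749 to keep the logarithm finite. The
tree is Saitou–Nei neighbor joining with Studier–Keppler branch lengths
(via `ape::nj`), negatives clamped to zero. Neighbor joining is used rather
than approximate maximum likelihood: it preserves the deliverable (a
supported Newick tree) with an exactly testable consistency guarantee — NJ
recovers any additive distance matrix exactly — and that guarantee is
tested on random additive matrices up to 12 leaves. This is the package's
largest intentional fidelity gap relative to likelihood-based tree tools.
Bootstrap supports resample alignment columns with replacement (default
`B = 100`; the knob is exposed but no published default exists) and score
each internal bipartition of the point-estimate tree by the fraction of
replicate trees containing it; a replicate pair left with no comparable
columns receives the capped maximum distance. Runs are reproducible under
the configured seed. Newick output writes branch lengths as `%.6f` and
quotes labels containing metacharacters.

Rank tables sum OTU counts by rendered label; the "Minor" rule merges a
label only when its relative abundance is strictly below the threshold
(default 1%) in *every* sample — strictness and the every-sample quantifier
follow the convention that a taxon at 1.06% in a single sample is still
shown. Diversity uses natural logarithms (Shannon `−Σ p ln p`, Simpson
`1 − Σ p²`, Pielou `H/ln S`); Bray–Curtis is `Σ|x−y| / Σ(x+y)`, reported NA
for a pair of empty samples (it is not a metric and no triangle inequality
is asserted). Run comparison (e.g. forward- vs reverse-read analyses)
applies a `log10(x+1)` transform to per-label totals and reports two-sample
t, Mann–Whitney U and Kruskal–Wallis p-values plus the unique/shared label
breakdown; group sizes below 2 are reported as underpowered rather than
tested.

## The synthetic mock community

`build_mock_reference` generates a hierarchical taxonomy (two genera per
family, three families per phylum) and per-genus ancestral proteins mutated
along the hierarchy at amino-acid substitution fractions 0.40
(root→phylum), 0.25 (phylum→family) and 0.18 (family→genus); within a
genus, variants diverge by `divergence` (default 0.05) with a synonymous
codon redraw rate of 0.15. These rates were fixed once so that within-genus
nucleotide identity sits near 0.90 and between-genus identity near 0.72 —
either side of the 0.80 clustering default, which is exactly the resolution
the threshold is meant to have. At least two variant substitutions fall in
the first 40 internal codons so taxa stay distinguishable at every analyzed
read length. An error guards against parameter choices that leave
inter-genus protein identity above 0.97.

Each amplicon is laid out as a concrete instantiation of the forward primer
(23 nt), one pad base, 196 ± 2 internal codons and the reverse-complemented
reverse-primer instantiation (23 nt): 635 ± 6 nt total, frame-aligned so
the whole molecule translates stop-free in frame +1 (both primer regions
are stop-free in that frame for every degenerate instantiation — a property
of the primer patterns). The reference protein is that frame +1 translation
(~211 residues). Length datasets are 5' prefixes (trimmed / 300 / 150 nt),
because the forward read is 5'-anchored by the chemistry; `full` adds
random 30–60 nt flanks. `conserved_prefix_aa` copies a shared prefix across
all taxa to emulate a marker whose 5' region is uninformative — used to
demonstrate that misassignment grows as reads shorten.

Read simulation emits R1 reads as the 5' 300 nt of the flanked molecule and
R2 reads as the 5' 300 nt of its reverse complement; substitution errors
are Bernoulli per base with quality dropped to Phred 14 at error positions
(constant Phred 40 elsewhere, matching constant-quality FASTQ conversion of
reference data); chimeras are single-crossover joins of two distinct taxa's
amplicons at an *exact* count of `round(rate × n)` per sample — exactness
makes ground-truth assertions deterministic rather than binomial. The
generator does **not** emulate position-dependent quality decay, indels,
PCR bias, or real FTHFS homology — biological realism is out of scope;
distinguishability and ground truth are in scope. Passing tests therefore
demonstrate correctness of the machinery under substitution-dominated,
primer-bearing input, not performance on real sequencer error profiles.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes that exercise every code path meaningfully: a 20-taxon
reference (10 genera × 2 variants), 5 samples × 2,000 error-free reads for
ground-truth recovery, 500 random sequences against the exhaustive
best-frame oracle, 200 random protein pairs (≤ 60 aa) against a quadratic
Smith–Waterman oracle, 500 random quality vectors against the all-cut-points
trimming oracle, 100 constructed chimeras against 100 non-chimeric uniques,
and 50 random additive matrices (6–12 leaves) for NJ consistency.

Conventions worth stating explicitly: Phred+33 is the only supported FASTQ
encoding (Phred+64 is rejected, not auto-detected); FASTA ids split at the
first whitespace; duplicate ids are written verbatim with a warning; all
sorting tie-breaks are lexicographic; gap costs are `open + L × ext`
everywhere; empty samples and degenerate test group sizes yield NA markers
rather than errors; a run ending with zero surviving OTUs completes with
empty outputs and a warning rather than an error; and every stochastic step
(bootstrap, simulation) takes an explicit integer seed.

## Known limitations

- Single-read frame selection occasionally picks a stop-free antisense
  frame (see Stage 3); this is the dominant failure mode observed on
  synthetic data and mirrors best-hit/frame ambiguity known for this
  marker.
- The tree is NJ with bootstrap, not maximum likelihood.
- Greedy clustering is order-dependent by design (abundance order); it is
  deterministic but not a global optimum.
- The reference database format (protein FASTA + 7-column taxonomy TSV) is
  defined by this package; no converter from other database layouts is
  provided.
- Paired-end merging is deliberately absent: the ~635 bp amplicon cannot be
  merged from 2 × 300 bp reads.
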