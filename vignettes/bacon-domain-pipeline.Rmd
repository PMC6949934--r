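---
title: "Discovering and analysing tandem BACON-domain repeats in phage genomes"
author: "baconscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and analysing tandem BACON-domain repeats in phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baconscope)
```

## The problem

BACON domains (*Bacteroides*-associated carbohydrate-binding often
N-terminal) are ~45-residue immunoglobulin-like β-sandwich domains found in
surface proteins of gut *Bacteroidetes* and, strikingly, in tandem repeats
within tail-fibre ORFs of crAss-like gut bacteriophages. Characterising
these repeats raises a chain of computational questions that this package
answers end to end:

1. **Find the domains.** The domains are short and divergent; a single
   profile search misses many. We build profile HMMs and refine them
   iteratively against the target proteome until the hit set converges.
2. **Classify the contigs.** Viral contigs lack a reference taxonomy, so we
   cluster them by *significantly shared gene content*: a protein homology
   graph, Markov clustering into gene families, hypergeometric tests on
   shared family counts, and Ward.D2 clustering with silhouette-selected k.
3. **Describe the architecture.** Domains per ORF, tandem-array detection
   with bounded inter-domain gaps, and the genomic neighbourhood (±5 ORFs)
   of every array, with a permutation test for association with tail genes.
4. **Reconstruct the evolution.** Progressive alignment, gap-column
   trimming, bootstrapped neighbor-joining trees, monophyly of
   position-in-array classes, and duplication-mode inference from the
   within-array similarity matrix.
5. **Predict the host.** Order-k Markov models trained on candidate
   bacterial genomes score phage contigs by mean log-likelihood per base;
   representatives per genus are chosen by completeness − 5 × contamination.

Every stage is exercised against a seeded synthetic-genome generator whose
ground truth (planted domains, duplication histories, lineage labels,
transfer events, neighbourhood labels) is emitted alongside the sequences.

## Models and assumptions

### Profile HMM and search

`buildProfile()` constructs a Plan7-style model from an alignment: columns
with non-gap fraction ≥ 0.5 become match states (unweighted rule; no
sequence weighting); emissions are `(counts + α·background)/(total + α)`
with uniform-Dirichlet α = 1 over Robinson–Robinson background frequencies;
transitions get a Laplace pseudocount. Insert states emit the background, so
their emission log-odds are zero and inserts are penalised purely through
transitions. Occupancy of a node is the non-gap fraction of its source
column.

`searchProfile()` is a local Viterbi scan: uniform entry `log2(1/L)` into
any match state, free exit after any match state, score in log2-odds (bits)
against the background. Multi-domain ORFs are handled by mask-and-rescan:
the best local alignment is reported, its envelope residues are masked, and
the scan repeats — sufficient for non-overlapping tandem arrays, and exactly
testable against brute-force path enumeration.

**Score threshold.** The default reporting threshold is 22 bits. We
calibrated it by scoring length-matched residue-shuffled decoys
(200 decoys, ~105 residues, 45-state profiles): the null maximum ranges over
12–19 bits, so a threshold in the noise floor would admit chance hits, while
22 bits keeps sensitivity ≥ 0.97 on domains planted at 0.35
substitutions/site (~66–68% identity to the seed consensus) with zero decoy
hits. The threshold is a free parameter of `profileParams()`.

`iterativeSearch()` repeats search → realign hit envelopes on the
Viterbi-implied match columns → rebuild, until the set of (ORF, envelope)
hits is identical between successive passes. Set equality is stricter than
a converged hit *count* and is stable; convergence on matching proteins
occurs at the second pass by construction.

### Gene-sharing classification

All-vs-all protein similarity uses Smith–Waterman with BLOSUM62 and affine
gaps (open 11, extend 1), converted to bits with the gapped Karlin–Altschul
constants λ = 0.267, K = 0.041; edges are kept above 50 bits. Pairs are
pre-screened by a shared 5-mer word index, the same seeded heuristic BLAST
uses — pairs without one exact shared word cannot plausibly exceed the
50-bit gate at these protein lengths (`prefilterK = 0` disables the screen).
Families come from Markov clustering (inflation 2, self-loops at each
node's maximum edge weight, pruning at 1e-6, convergence when the maximum
entry change falls below 1e-9; families are the connected components of the
limit support). For each contig pair the upper-tail hypergeometric
probability of the observed shared-family count is computed with `phyper`,
contigs are clustered with Ward.D2 on Euclidean distances between rows of
the *raw* p-value matrix (a −log10 transform is deliberately not the
default), and the cluster number maximises the mean silhouette over a k
range — silhouette is used directly rather than a multi-index vote, since
it is also the diagnostic we report. Contigs with ≤ 10 ORFs are dropped
before clustering.

### Architecture and tail association

A tandem array is ≥ 2 hits in one ORF with every inter-envelope gap ≤ 30
residues (~2/3 of a domain length; configurable). Neighbourhoods collect
±5 ORFs around each focal ORF, truncated at contig ends; a neighbourhood is
informative if any neighbour label differs from "hypothetical protein", and
tail genes are flagged by case-insensitive keywords (tail, tail
fibre/fiber, tail spike, baseplate). The association statistic is the
difference in tail-flanking fractions between tandem-array and
single-domain ORFs, with a one-sided add-one permutation p-value over the
tandem/single labels.

The permutation p-value is discrete and therefore *conservative*
(super-uniform) under the null — this is a property of add-one permutation
tests, not a defect. The null-calibration check consequently asserts the
one-sided property that matters for validity: the empirical CDF of null
p-values never rises above the uniform CDF (KS with
`alternative = "greater"`), plus a type-I coverage bound at 5%.

### Phylogeny and duplication mode

Alignment is progressive: a UPGMA guide tree on Euclidean distances between
normalised 3-mer profiles, then profile–profile Needleman–Wunsch with
BLOSUM62 (gap open 10, extend 1), column scores being
frequency-weighted sums of pairs. Input ids are sorted lexicographically
first so the result cannot depend on input order; DP ties prefer
diagonal > up > left. Trimming keeps columns with non-gap fraction ≥ gt (the
trimal convention: gt = 0.05 removes columns with more than 95% gaps;
gt = 0.4 is used for the short domain alignments and retains all four
conserved residues).

Distances are Kimura-corrected p-distances, `d = −ln(1 − p − 0.2 p²)`, with
pairwise deletion of gapped columns (complete deletion would discard most
of a trimmed domain alignment); saturated pairs are capped at 10 and
flagged, as are pairs sharing fewer than 10 columns. Trees are
neighbor-joining with ordinary column-resampling bootstrap. A
maximum-likelihood search would not change what the downstream analyses
consume — clade membership and support — and a distance method is exactly
verifiable: NJ recovers additive matrices perfectly, which the tests assert
up to 12 taxa.

Monophyly of a position class on an unrooted tree is tested by rooting at a
tip outside the class (a set is a clade for *some* rooting iff it forms a
split). Bacterial (unlabelled) leaves vote for the position of their
nearest labelled leaf in cophenetic distance; the class with the most votes
is the candidate ancestral domain.

Duplication mode is read from the m×m within-array bit-score matrix via the
offset profile s(d) = mean score at position offset d. Block duplication of
size b elevates s at *every multiple* of b, so the robust baseline for
candidate b excludes offsets divisible by b; b is called when s(b) exceeds
that baseline median by more than 2 MAD (configurable) and s(b) > s(1), with
candidates restricted to b ≤ m/2 (offsets near m average a single noisy
pair). On replayed histories at 0.08 substitutions/site per event the
classifier separates single-domain from block-of-2 histories with accuracy
1.0/1.0 (100 + 100 arrays).

### Host prediction

Order-k Markov chains (default k = 3; WIsH-style tools use larger k on
full-size genomes) are trained on both strands with add-one smoothing, so
models are strand-symmetric by construction. Contigs are scored by mean
log-likelihood per transition and hosts ranked; only the ranking and the
top-two margin are reported. Genus representatives maximise C − 5·M
(completeness, contamination), ties broken by coarse consistency, then
lexicographic id.

## The synthetic generator

`simulateDataset()` emulates the study conditions: 7 lineages × 4 contigs,
12–20 genes per contig laid head-to-tail with stop-terminated spacers, and
per-lineage domain arrays (default sizes 8, 5, 3, 1, 1, 1, 1 — three tandem
lineages, the first carrying the prototypical eight-domain repeat). Gene
content has a core/accessory structure: 10 core families appear in every
contig of a lineage, accessory slots draw from the lineage pool with a 15%
chance of drawing from a shared cross-lineage pool. Domains descend from a
common 45-residue ancestor with four conserved residues (W, N, R, Q at
positions 5, 20, 26, 40) held invariant; arrays are built by replaying an
explicit duplication-event history (single-domain or block copies, each
event followed by 0.05 substitutions/site on all domains), contig instances
diverge a further 0.02, and each domain instance loses its flexible
10-residue N-terminus with probability 0.1. Substitutions follow
BLOSUM62-conditional exchange probabilities so diverged copies stay
alignable. With probability 0.1 per lineage a domain ORF is copied into
another lineage (horizontal transfer). Tail labels are placed on the ±2
neighbours of tandem-array ORFs only (policy `tandem_only`); single-domain
ORFs get informative non-tail neighbours so their neighbourhoods still count.

Two generator details exist purely so that ground truth is exactly
recoverable: one codon per amino acid with a preference for codons whose
reverse complement is a stop (the reverse strand of coding regions stays
stop-rich, so the maximal-ORF caller emits few spurious reverse-strand
ORFs), and spacers that end with an in-frame stop (every planted ORF is
provably the maximal ORF of its frame).

What the generator does *not* emulate: codon-level evolutionary models,
sequencing error and assembly artifacts, genuine annotation noise in
functional labels, compositional biases of real genomes, and realistic
family-size distributions. Passing the recovery tests therefore shows the
pipeline's inferential machinery is correct at realistic signal strengths —
not that real metagenomes are this clean.

## Numerical choices and degenerate inputs

* Viterbi and the brute-force oracle share the exact state space (entry
  into any match state at cost log2(1/L); exit after any match emission);
  equality is asserted to 1e-8 over all profiles L ≤ 5 × proteins ≤ 6.
* MCL: pruning 1e-6, convergence 1e-9 on the max entry change, hard error
  after 10,000 iterations; node order cannot affect the partition.
* Ward.D2 heights are validated against a hand-applied Lance–Williams
  recurrence; degenerate all-zero distance matrices collapse to a single
  flagged cluster rather than an arbitrary k.
* Codons containing ambiguity codes are skipped during translation (no X),
  keeping proteins scoreable; a 120-N contig yields no ORFs.
* All randomised APIs (`bootstrapNj`, `tailAssociation`, `replayHistory`,
  `simulateDataset`) take explicit seeds and restore the caller's RNG
  stream.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
every stage completes in seconds while the statistical claims keep
comfortable margins: 28 contigs (≈ 480 planted ORFs plus predicted
reverse-strand ORFs) for cluster recovery; 200 positives + 200 shuffled
decoys for search sensitivity; 100 + 100 replayed histories for duplication
mode; 10 replicates of 12 × 8 domain copies for position-clade recovery;
999 permutations for the tail test and 200 × 199 for its null calibration.

## Known limitations

* The most recently duplicated array positions sit on very short internal
  stems; at copy divergence 0.02 a replicate occasionally resolves only 6
  of 8 position classes as clades, with NJ, BIONJ and FastME alike — a data
  limit, not an implementation one.
* The maximal-ORF caller has no coding statistics; on real (non-synthetic)
  contigs it will emit more spurious short ORFs than a gene caller with
  codon-usage models, which mildly inflates the gene-family universe.
* The 5-mer prescreen can in principle drop a true homolog pair with no
  exact shared word; at the 50-bit edge gate such pairs are already
  borderline.
* Bit scores are Viterbi-only; no forward/E-value stage is provided, so
  thresholds are in bits, not E-values.
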