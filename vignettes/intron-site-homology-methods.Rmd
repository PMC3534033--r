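---
title: "Mapping intron insertion-site homology and twintron evolution in euglenid plastids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intron insertion-site homology and twintron evolution in euglenid plastids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euglintron)
```

## The character being analysed

The unit of comparison throughout this package is the **intron insertion
site**, not the intron sequence. Two introns in two species are *cognate*
when they interrupt the homologous position of the host protein: the same
column of the ortholog alignment, at the same offset within the codon
(phase 0, 1 or 2). Sequence similarity between the introns themselves is
deliberately not part of the homology call — euglenid plastid introns are
short, U-rich and fast-evolving, so position is the durable signal. Two
consequences of this definition are enforced exactly:

* insertions within the same amino acid but at different positions within
  the codon are **distinct** sites;
* a site whose interrupted residue falls in an alignment gap of a partner
  species cannot be cognate with that partner (there is no shared column).

A phase-0 insertion sits exactly between two codons; we assign it to the
*following* residue's column. This is a pure convention (the literature
leaves it implicit) but it must be fixed for the arithmetic
`residue = floor(offset/3)` to be stable, and every projection and
simulation in the package uses it consistently.

Sites flagged *ambiguous* (the divergent *rpoB* case, where positional
homology cannot be established from the alignment) never merge with other
sites: they are carried as singletons, which matches how the pairwise
sharing analysis treats them.

## Genome partition accounting

`partition_stats()` classifies every genomic position exactly once with
precedence **intron > exon > intergenic**. The precedence rule is what
turns overlapping annotations (an intronic maturase ORF, the *psbD/psbC*
style gene overlap) into a true partition, so
`gene_bp + intron_bp + intergenic_bp = genome length` holds identically —
that conservation is asserted for every parsed or simulated genome in the
test suite, and for fixtures reproducing all six published size partitions.
Counting rules follow the field's table conventions: duplicated genes count
once (their bp count every occurrence — bp is physical), free-standing
ORFs are excluded from gene counts, intronic ORFs are reported in their own
row, and a twintron is one insertion site.

Internally all coordinates are 0-based half-open on the forward strand with
a per-gene strand flag; user-facing output is 1-based inclusive. Features
spanning the origin of a circular molecule are normalised by rotating the
sequence at parse time; the rotation offset is retained for reporting.

## Alignment

Pairwise alignment is affine-gap global Needleman–Wunsch (BLOSUM62 by
default, gap open 10, extension 0.5 per position — a gap run of length
*L* costs `open + ext × L`). The multiple alignment used as the projection
frame is a centre-star construction: the centre maximises summed pairwise
score and gaps propagate by "once a gap, always a gap". This is not an
iterative-refinement aligner; for the purpose of projecting insertion
points in well-conserved plastid proteins it is sufficient, and externally
produced alignments (e.g. MAFFT L-INS-i) can be imported and used instead
— they take precedence when supplied. The alignment engine is delegated to
Biostrings, whose traceback is deterministic; the package's own tests pin
the optimal score to a brute-force enumeration over all alignments of
short peptides.

## Group III consensus scanning

Euglenid group III introns retain two landmarks of their group II
ancestry: a relaxed 5′ terminus matching N-U-N-N-G, and near the 3′ end a
*pseudo-domain VI* — a 6-bp stem whose arms flank a short terminal loop,
with the branch-point adenosine bulged between the arm positions d′ and c′
and a short tail to the 3′ splice boundary:

```
5'  a b c d e f  (loop 3-8 nt)  f' e' d'  A*  c' b' a'  (tail 4 nt) 3'
```

The scanner enumerates every placement that ends at the intron's 3′
terminus with a tail in the configured range (the published consensus
states exactly 4 nt; a 2–6 range is exposed), requires all six stem
pairings (Watson–Crick plus optional G·U wobble, mismatch tolerance 0 by
default) and the bulged A, and lies within 40 nt of the 3′ end. The motif
span is `13 + loop + tail` nt (6 stem + 3 + 1 + 3 arm/bulge positions plus
loop and tail). Hits sort by fewest mismatches, then shortest loop, then
3′-most placement. Equivalence with an independent exhaustive enumerator
is asserted on hundreds of random sequences, and relaxing any parameter
can only add hits (monotonicity), which the tests check as a property.

Classification is rule-based: *group III* requires the 5′ consensus, at
least one domain VI hit and length ≤ 150 nt; a longer sequence with a
domain VI hit is called *group II*; anything else is *unclassified*. The
150 nt ceiling is **not** a published value — it is a configuration knob
(group III introns in these genomes are typically ~90–110 nt) and is
flagged as such in reports. U-content is reported as a diagnostic, never
used as a criterion.

## Twintron decomposition

Whether a candidate site shares a twintron with a reference genome is
decided from two alignment views, mirroring the two-way strategy used in
the comparative literature: the full reference twintron against the target
intron, and each component (the external intron with internals excised;
each internal) separately against the target. Component alignments are
semi-global ("glocal": the reference component fully aligned, target
flanks free), under a nucleotide scheme of match +2 / mismatch −3 / gap
open 10 / extension 1. That gap regime was chosen so that a component
alignment can affordably jump the large insertion that a nested internal
creates in a target, while spurious gap-chasing on unrelated sequence
stays unrewarding.

A component is **supported** when coverage ≥ 0.5 *and* identity ≥ 0.5
*and* its identity exceeds a permutation null (identities against seeded
shuffles of the target, 30 by default) by ≥ 3 standard deviations. The
z-guard matters: the identity of an *optimal* alignment of unrelated
sequences is inflated by the optimisation itself and can exceed 0.5, while
true orthologs at the divergences involved sit far outside the null
(z ≈ 6 versus z ≈ 0–1 in the synthetic cohort). The 0.5/0.5/3 thresholds
are configuration, reported alongside the raw evidence — the original
analyses used expert judgment here, and reproducibility was preferred over
fidelity to an unstated rule.

The classification is then structural: *complete twintron* (external and
all internals supported), *partial twintron* (external plus a proper,
non-empty subset of internals — the intermediate evolutionary stage in
which the external intron is in place before all internals have arrived),
*external-only*, or *unrelated*. "Shares a twintron" for counting purposes
means complete or partial, which is how the published count of six shared
twintrons (four complete, two intermediates) is composed. When unsupported
internals leave an unexplained length surplus above 60 nt, the target is
additionally scanned for the 5′/domain VI consensuses, so that an
unusually long single intron is not mistaken for a twintron.

`decompose_nested()` returns the excision plan of an annotated twintron,
innermost first — excising in plan order yields the mature external
intron, and the tests verify that excision reconstitutes an intron-encoded
ORF fragmented by an internal intron.

## Phylogenetic mapping

Because insertion-site homology implies a unique origin, presence/absence
of a cognate site is mapped under **Dollo parsimony**: exactly one gain,
on the branch above the MRCA of the carriers, and losses on the minimal
set of branches below it whose applicable descendants are all absent. Taxa
that have lost the host gene entirely (e.g. *psbC* in the
non-photosynthetic *E. longa*) are *inapplicable*: they constrain nothing
and cost nothing. Minimality of the reconstruction is asserted against a
brute-force search over all single-gain placements and loss-branch subsets
on hundreds of random trees and patterns. Unordered (Fitch) parsimony is
available as a sensitivity check; the default sharing matrix covers the
photosynthetic taxa, with *E. longa* entering only the gain/loss map. The
species tree is always an input (newick, rooted), never inferred.

## The simulator and what passing it does (and does not) show

`simulate_clade()` evolves sites down a rooted tree: per-branch Poisson
gains at uniformly chosen, never-reused (gene, codon, phase) positions,
per-branch Bernoulli losses, per-branch twintron nesting, intron sequences
from the consensus-compliant generator, and exon backgrounds at ~70% A+T
(stop-codon-free so translated orthologs align). The default clade
emulation (`euglenid_demo_config()`) transcribes the qualitative published
pattern at reduced scale — a small ancestral contribution on the stem of
the photosynthetic taxa, larger waves on the branches toward the
*Euglena*/*Monomorphina* ancestor, and strong terminal-branch gain in the
intron-rich lineages, reflecting that most published sites are
species-specific (21 of 23 in *Eta. viridis*, 12 unique sites in
*M. aenigmatica*). Problem sizes used by the validation analyses: ~35
sites per replicate over 4 genes and 6 taxa, 20 replicates for the
loss-recovery check, 3 for the zero-loss exactness check.

With zero loss, running the full pipeline (write → parse → translate →
align → project → cluster) must recover the truth sharing matrix
*exactly*; at 5% per-branch loss, Dollo gain-branch assignment stays above
95% (the residual error is intrinsic: losing the basal-most carrier of a
clade moves the apparent MRCA down one node). What this validates is the
bookkeeping and the reconstruction logic — not alignment robustness:
simulated exons are identical across taxa, so projections are exact by
construction. Real data add alignment uncertainty in divergent genes
(*rpoB*, *rpoC1*), which is exactly why the ambiguous-site flag exists and
why imported curated alignments take precedence over the built-in star
aligner.

## Numerical and degenerate-input choices

* Tie-breaking in alignment traceback is delegated to the (deterministic)
  engine; scores, not paths, are the tested contract.
* An empty genome partitions to 100% intergenic; an empty FASTA scan
  returns an empty report with a warning rather than an error.
* Frame violations in annotated protein genes warn but do not fail: one
  published *rpoC1* insertion could not be RT-PCR-verified and may hide a
  small unannotated exon, so hard-failing would reject real records.
* Two sites of one species at an identical (gene, column, phase) are a
  data error (duplicate annotation), not a cluster of size two.
* All randomness (generator, simulator, permutation nulls) flows from a
  single user-supplied seed; fixed-seed runs are byte-identical, which the
  tests assert on written GFF3/FASTA/TSV output.

## Known limitations

* The star MSA is not consistency-based; for publication-grade alignments
  of divergent genes, import MAFFT L-INS-i output.
* Group II secondary structure beyond pseudo-domain VI (domains I–V,
  folding energetics) is out of scope; classification is consensus- and
  length-based.
* The twintron support rule is a reproducible surrogate for expert
  judgment; borderline components (z near 3) deserve manual inspection of
  the reported evidence.
* Intron sequence-similarity homology searches at non-cognate positions
  are not attempted.
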