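# euglintron

Comparative analysis of group II/III intron and twintron evolution in
euglenid plastid genomes.

## The problem

Photosynthetic euglenids acquired their plastid by secondary endosymbiosis
of a green alga, and some lineages — most famously *Euglena gracilis* —
subsequently accumulated extraordinary numbers of degenerate group II
introns, euglenid-specific group III introns, and *twintrons*
(introns nested within other introns, which must be excised innermost-first
for the host transcript to splice). Comparing *which positions* are
interrupted across related genomes, rather than the intron sequences
themselves, is the key to reconstructing how this proliferation happened:
an intron insertion site is a homologous character — the same aligned amino
acid, interrupted at the same position within its codon — that can be
gained once and subsequently lost.

`euglintron` implements that comparison end to end for a small clade of
annotated plastid genomes:

* **Genome accounting** — parse GenBank/EMBL flat files or GFF3+FASTA and
  partition every position into coding / intergenic / intronic
  (precedence intron > exon > intergenic, so the three classes tile the
  genome exactly), with the field's counting rules: duplicated genes count
  once, free-standing ORFs are excluded, intronic ORFs (maturases) are
  reported separately, a twintron is a single insertion site.
* **Site homology** — project each intron insertion point onto an ortholog
  protein alignment as (alignment column, codon phase ∈ {0,1,2}); sites are
  cognate iff gene, column and phase all agree. Insertions within the same
  amino acid but at different codon positions are distinct.
* **Group III consensus scanning** — the 5′ N-U-N-N-G terminus and the 3′
  pseudo-domain VI `abcdef (3–8) f′e′d′ A* c′b′a′ (4)` stem–bulged-A–tail
  motif, scanned by exhaustive placement against the 3′ end.
* **Twintron decomposition** — each reference twintron is split into its
  external and internal components; every component is aligned
  semi-globally against the target intron and supported when coverage ≥ 0.5,
  identity ≥ 0.5 and the identity exceeds a permutation null by ≥ 3 SD.
  Sites classify as complete twintron / partial (intermediate stage, the
  external plus a subset of internals) / external-only / unrelated.
* **Phylogenetic mapping** — pairwise shared-site matrices and Dollo
  parsimony on a rooted species tree: one gain on the branch above the MRCA
  of the carriers, a provably minimal set of losses below it; taxa that
  lost the host gene are masked as inapplicable.
* **Simulation** — a seeded clade simulator with per-branch Poisson gains
  (burst branches supported), Bernoulli losses, twintron nesting, and
  consensus-compliant intron sequences, recording the full truth so the
  pipeline can be validated end to end.

## Worked example

The shipped transcriptions of the published shared/unique site tables can
be clustered and cataloged in seconds:

```r
library(euglintron)
fx     <- build_paper_fixture()
groups <- cluster_cognate_sites(fx$sites)
site_catalog(groups, "Maen")$summary
#>  total shared unique
#>     53     41     12
count_shared_with(groups, "Maen", "Egra")
#> [1] 40
```

53 insertion sites in the *M. aenigmatica* genome, 41 shared with at least
one other euglenid, 40 of them (75%) with *E. gracilis*; exactly one site
is common to all four photosynthetic euglenids and exactly one
(`rpoC1.Maen.6`) is shared with *E. longa* but absent from *E. gracilis*.
The full drivers live under `analysis/` (`01_site_catalog.R` …
`05_simulation_validation.R`); each writes its tables under `results/`.
For example `analysis/03_twintron_decomposition.R` classifies the 12-site
candidate twintron cohort and prints

```
sites sharing a twintron (complete or partial): 6 of 12
external-only (intermediate-precursor) sites: 6
```

i.e. 4 complete twintron orthologs, 2 partial intermediates, and 6 sites
holding only the external intron.

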