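---
title: "Methods: comparative exon-intron architecture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative exon-intron architecture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonarch)
```

## The problem

Gene families such as the heterotrimeric G protein alpha subunits (GNA-)
evolve by duplication, whole-genome duplication, retrotransposition,
intron gain and loss, and lineage-specific gene loss. Protein sequences of
old paralogs are often too diverged for tree topology alone to resolve how
the families relate, but the *exon-intron architecture* -- where the
introns interrupt the coding sequence, and in which codon phase -- changes
slowly and independently of sequence drift. Two paralogs that share most
exon border positions, including split codons (codons written across two
exons), almost certainly share a filled-in intron history; a paralog that
shares none and has fewer introns than its relatives carries the signature
of a retrotransposed mRNA reinserted into the genome.

`exonarch` turns this reasoning into a testable pipeline: derive
architectures from genome + coding annotation, compare them across a
family on a protein alignment, classify retro-origin candidates, polarize
intron gains and losses on a species tree, detect splice-level
consequences of local exon duplications, classify candidate retrogene
loci, reconcile gene trees with species trees, and test positional motif
enrichment around unusual splice sites.

## Core definitions

For a transcript with exon lengths $l_1, \dots, l_k$ (in nt, transcription
order), the internal borders are the cumulative sums
$o_j = \sum_{i \le j} l_i$ for $j < k$, expressed as offsets into the
spliced CDS. The phase of a border is $o_j \bmod 3$; a border with nonzero
phase is a split codon. Only internal borders are counted -- the CDS start
and stop are properties of every gene and carry no comparative signal.

Coordinates are 0-based half-open internally; GFF3 I/O converts to the
1-based inclusive convention and recomputes the CDS phase column
("bases to remove", $(3 - o \bmod 3) \bmod 3$) from exon lengths. A stored
phase that disagrees is reported as a warning rather than an error,
because annotations lifted from fragmented assemblies are legitimate
inputs.

## Border projection and shared-architecture counting

Borders are compared between genes on a protein multiple sequence
alignment (computed elsewhere; alignment inference is out of scope). A
border at offset $o$ maps to residue $\lfloor o/3 \rfloor$ -- for a split
codon this is the residue whose codon is interrupted; for phase 0 it is
the first residue fully downstream -- and then to that residue's alignment
column, skipping gaps. Two borders of different genes match when they sit
within `slack` columns of each other *and* have identical phase; matching
is greedy nearest-column, leftmost on ties, one-to-one. Phase is never
conflated: a phase-1 and a phase-2 border at the same column are different
characters, and treating them as shared would manufacture homology.

`slack` defaults to 0 columns. The notion of a "major" shared border in
the motivating literature is visual and never formalized; rather than
hard-code a guess we expose slack as a parameter and default to the
strictest value. Shared-border counts are invariant under inserting
all-gap columns (verified by test).

## Retro-origin classification

`classify_retro_origin()` labels a candidate architecture against its
family: `retro_candidate` when it shares fewer than `min_shared` borders
with *every* member and has fewer introns than the family median;
`vertical` when it shares at least half of the family-consensus borders;
`ambiguous` otherwise. This is deliberately a coarse screen -- it mirrors
the inference that an intron-poor paralog sharing no borders or split
codons with its family arose by retrotransposition (and may have regained
introns at novel positions afterwards), while avoiding any claim when the
evidence cuts both ways (equal intron counts, partial sharing).

## Polarizing border characters

Presence/absence of a border character across taxa is polarized on a
rooted species tree by Sankoff parsimony with configurable gain:loss costs
(default 1:1, which equals Fitch counts on binary characters). Unknown
states -- missing exons, unresolved assemblies -- are unconstrained. All
co-optimal scenarios are enumerated by DP backtracking and the result is
flagged ambiguous when more than one distinct event placement is optimal.
A Dollo mode (one gain at the LCA of the taxa carrying the character,
minimal losses below) is available for characters where independent gain
is implausible, such as gene presence itself.

## Splice events

*Splice-site classification.* Per intron, the donor is the literal first
two nucleotides and the acceptor the last two, strand-aware. GT-AG is
canonical; GC-AG is the recurrent non-canonical donor class. Introns
shorter than 7 nt are flagged rather than classified. An alternative
upstream acceptor is reported when intron positions $-5,-4$ read `TG`:
splicing there transfers the final 3 nt of the intron (typically `CAG`)
onto the downstream exon. Other NAGNAG-type variants are out of scope.

*Mutually exclusive exons.* Candidate alternatives are runs of one or two
consecutive exons (this covers single-exon and exon-pair duplications;
longer runs would explode combinatorially without a motivating case). Two
adjacent runs group when (a) their lengths are congruent mod 3, so that
spliced *mutually exclusively* both alternatives enter and exit at
identical phases, and (b) each exon of one run aligns to its counterpart
in the other with amino-acid identity at least `identity_min` (default
0.30). Identity is scored by a deliberately simple global alignment
(match 1, mismatch 0, free gaps; identity = matches / alignment length):
the threshold is a tunable screen, not a score of record. Note the
congruence is evaluated on the runs as alternatives, not on the annotated
chain -- a duplicated run whose length is not a multiple of 3 still forms
a valid mutually exclusive pair, because each alternative substitutes for
the other. At the default threshold the screen is permissive: on random
sequence, gap-free-cost alignments of short exons occasionally exceed 0.30
identity, so reported groups are candidates for inspection; raising
`identity_min` isolates recent duplicates.

*Isoform enumeration.* Cassette exons, mutually exclusive groups and
alternative acceptors are treated as independent choices; isoforms are
their Cartesian product, each translated and flagged for frame validity
and premature stops. A cassette exon flanked by split codons reproduces
the classic pattern in which inclusion contributes its full codons plus
one residue completed across the junction, and the junction residue
changes identity between inclusion and exclusion forms; with a TG
acceptor on the downstream intron this yields four isoforms around one
junction.

## Retrogene locus classification

Similarity hits (12-column tabular, the standard nucleotide-search
output) are merged per locus when HSPs overlap or sit within 1 kb. More
than one remaining ordered hit marks a multi-exon match and excludes the
locus. A single hit is banded by query coverage: at least 50% of the
parent CDS is a retrogene candidate, 30-50% is terminal manual review
(the source procedure resolves this band by eye), below 30% is a single
exon fragment. Coverage is computed on the parent CDS (the longest
protein-coding isoform), a choice flagged to users since the alternative
(mRNA) is defensible.

ORFs are scanned in the hit window extended by 300 nt on both sides, both
strands, three frames each, bounded by stop codons or window edges;
reported when at least 40 codons long and containing an initiation
methionine (both configurable). Parent similarity is a local alignment
(simple scores: match +2, mismatch -1, gap open/extend 5/2) requiring at
least 40 aligned residues at 50% identity or more. Conservation across a
clade requires a qualifying Met-containing ORF at the homologous
(alignment-column) region in every species; an all-gap region fails.
Functional status then follows a pure decision table: conserved ORF +
at least one expression experiment with RPKM > 0.5 gives `functional`;
conserved ORF alone `conserved_unexpressed`; expression alone
`expressed_only`; neither `pseudo`. Promoter annotation is recorded as
evidence but never required or computed -- it is browser-derived input.

An exact Smith-Waterman scorer with the retrieval settings (+1/-3, gaps
5/2) is included so hit tables can be produced in-repo for tests; real
analyses consume external search output.

## Reconciliation

`lca_reconcile()` implements the standard LCA mapping: each gene-tree node
maps to the LCA of its descendant species; a node is a duplication when it
maps with a child; losses on an edge equal the species-path length between
images minus one unless the parent is a duplication, floored at zero.
Support-based preprocessing mirrors the collapse-then-resolve strategy:
edges below the support threshold (default 90, following common practice
for bootstrapped gene trees) are contracted, and the resulting polytomies
are re-resolved to minimize duplications + losses -- exhaustively over all
$(2k-3)!!$ rooted arrangements up to degree 6 (postorder, first optimum in
a fixed enumeration order on ties), greedily by cheapest cherry-join
beyond. This replaces the rearrangement heuristic of interactive
reconciliation tools with simpler, testable semantics pursuing the same
objective. Dollo gain/loss mapping of presence/absence matrices places
each family's gain at the LCA of the species carrying it and cuts the
minimal set of loss edges below; unknown cells are free.

Raw parsimony counts are reported as-is. Duplication/loss totals from real
gene trees are known to be overpredicted when the gene tree is distorted
by fast-evolving paralogs or missing data; expert overrides (synteny,
WGD timing) are left to the user.

## Positional motif enrichment

PWMs (MEME minimal format, or constructed directly) are scanned as
log-odds against the background (default uniform; pseudocount 0.01 per
cell) over every window, both strands for DNA. Exactly one best site per
sequence is recorded (ties: leftmost center, then forward strand), because
the positional test counts best matches. The binomial test compares the
count of best-site centers inside a window against the uniform null
$\pi = w_\text{win} / (L - w + 1)$, upper tail $P(X \ge k)$; when no
window is given, all windows of a chosen width are scanned and the
minimum-p window is reported with a Bonferroni adjustment over windows
tried. The differential test is a one-sided Fisher exact test on the
in-window / out-of-window table of a primary versus a control set.
Adjustment defaults to Bonferroni with Benjamini-Hochberg as the
alternative; the upstream convention says only "corrected for multiple
testing", so the method is a flag. The cited scanning tool's E-value
filter has no restated definition, so this package reports adjusted
p-values and documents the difference.

## The simulator

`evolve_family()` evolves a single ancestral multi-exon gene (complete
ORF, canonical GT..AG introns, border phases drawn rather than forced to
zero) along a rooted species tree. Per branch and per gene, event counts
are drawn as Poisson variables (rate x branch length) for, in fixed
order: tandem duplication, retrotransposition (an intron-free copy on its
own scaffold), intron gain (a new canonical intron at a random in-exon
position, with CDS offset and phase recorded), intron loss, tandem exon
duplication (a run of 1-2 exons copied in place -- the mutually exclusive
exon generator), donor GT to GC mutation, and gene loss. Substitution is
Jukes-Cantor -- divergence magnitude, not realism, is what recovery tests
need -- and never touches splice-site dinucleotides, so splice
classification errors cannot arise from drift. All randomness flows
through one seeded stream in documented draw order; a fixed configuration
reproduces every output byte (verified). Copies created on a branch begin
evolving on the following branches, a deliberate simplification that
keeps the draw order independent of event outcomes.

Default conditions: a four-taxon balanced tree of total length 6, an
eight-exon root gene (exons 30-120 nt, introns 20-60 nt), substitution
rate 0.02/site/unit, and per-unit event rates of 0.05 (tandem
duplication, retrotransposition, gene loss), 0.03 (intron gain/loss), and
0.02 (exon tandem duplication, GC donor). These are chosen once as a
small, plausibly scaled caricature of a vertebrate gene family -- a
handful of events per family history -- and recovery tests run across
hundreds of seeds at these settings.

*Ground truth and observability.* The ledger records every raw event.
Separately, the simulator tracks the full gene genealogy and reports
*observable* duplication and loss counts: what a most-parsimonious reading
of the surviving gene tree can recover. The distinction matters -- a
duplication whose second copy dies out leaves no trace, and when both
copies of a duplication independently lose the same species subtree,
parsimony necessarily places the duplication below the losses and sees
fewer events. Observable counts are computed by species-set images
directly on the genealogy table, a separate code path from
`lca_reconcile()` on the emitted Newick tree, and the two are required to
agree exactly across seeded runs. Truth labels for retro-origin
classification come from ledger ancestry: a tandem duplicate of a
retrocopy is itself retro-origin, matching the biology of duplicated
retrogenes.

What the simulator does not emulate: indels within exons, codon-level
selection, synteny, assembly gaps inside genes, annotation error beyond
incomplete CDS flags, and alignment uncertainty (recovery tests of
alignment-dependent steps use undiverged or lightly diverged families
where the true alignment is trivial). Passing recovery tests therefore
demonstrates the correctness of the inference logic under clean
conditions, not robustness to noisy annotation or deep divergence.

## Numerical choices and degenerate inputs

* Codons containing N translate to X and never count as stops; partial
  or internally interrupted CDS are flagged, not rejected.
* All tie-breaks are deterministic and documented: leftmost column in
  border matching, leftmost center and forward strand in PWM scanning,
  first optimum in polytomy enumeration order, smallest index in
  simulator event draws.
* Families absent everywhere, empty hit sets, single-leaf gene trees and
  windows clipped at sequence edges produce warnings or empty results
  with defined shapes rather than errors, except where the input is
  unambiguously malformed (mixed strands in a transcript, unrooted trees,
  species missing from the species tree).
* Test problem sizes: recovery suites run 40-200 simulated families per
  property; oracle suites enumerate all rooted gene-tree topologies up to
  5 leaves, all polytomy resolutions up to degree 4, all 2x2 tables up to
  n = 30, and 6-frame ORF enumeration on 50 random 1-kb sequences; the
  binomial null calibration uses 1000 replicates of 8 sequences of 50 nt.
  These sizes were chosen to make the combinatorial checks exhaustive
  where exhaustiveness is the point and to keep the full suite fast
  enough to run on every change.

## Known limitations

* `manual_review` is a terminal classification; the package does not
  attempt to automate what the source procedure resolved by eye.
* Architecture comparison requires a protein MSA of reasonable quality;
  badly misaligned regions shift projected columns and deflate shared
  counts (slack can absorb small shifts).
* The MXE screen reports structural candidates; it cannot confirm
  mutually exclusive usage without transcript evidence, which enters only
  as optional input.
* Reconciliation handles duplications and losses only -- no transfers, no
  branch-length-aware (dated) variants.
* The duplication/loss totals published for the motivating family
  depended on an unpublished genome-scale gene tree and interactive
  rearrangement; they are not recomputable at package scale and are not
  targets of the test suite.
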