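# exonarch

Comparative exon-intron architecture analysis for gene families, built
around the questions raised by the heterotrimeric G protein alpha (GNA-)
family: which paralogs share an intron history, which arose by
retrotransposition, where introns were gained and lost on the species
tree, what local exon duplications did to splicing, and which retrogene
copies remain functional.

The package is aimed at molecular-evolution researchers who have genome
sequences (FASTA), coding-exon annotations (GFF3), protein alignments,
and rooted trees (Newick), and want reproducible, testable versions of
the classic comparative analyses instead of by-hand bookkeeping.

## What it computes

* **Architectures.** For each transcript, internal exon borders as
  offsets into the spliced CDS with their phase (`offset mod 3`); a
  border with nonzero phase is a *split codon*, a codon written across
  two exons. Borders are projected onto a protein MSA and shared
  borders/split codons are counted pairwise and family-wide
  (phase-exact, gap-aware, greedy nearest-column matching).
* **Retro-origin classification.** A paralog sharing no borders with any
  family member and carrying fewer introns than the family median is a
  retrotransposition candidate; one matching the family consensus is
  vertical; everything else is ambiguous.
* **Border polarization.** Sankoff parsimony (configurable gain:loss
  costs, unknowns free, all co-optimal scenarios enumerated) and Dollo
  parsimony on a rooted species tree.
* **Splice events.** Strand-aware GT-AG / GC-AG / other splice-site
  classification, TG-acceptor detection 3 nt upstream of the canonical
  AG, mutually exclusive duplicated-exon detection (runs of 1-2 exons),
  isoform enumeration over cassette/MXE/acceptor choices, and isoform
  protein comparison.
* **Retrogenes.** Locus classification from 12-column similarity hits
  (coverage bands 50%/30%), six-frame ORF discovery in +/-300 nt windows,
  parent-protein similarity (>=40 aa, >=50% identity), cross-species ORF
  conservation with a methionine requirement, and a functional-status
  decision table using expression (RPKM > 0.5) evidence.
* **Reconciliation.** LCA gene-tree/species-tree mapping with duplication
  and loss counts, support-threshold edge collapse (default 90),
  minimum-cost polytomy resolution (exhaustive to degree 6), and Dollo
  gain/loss mapping of presence/absence matrices.
* **Motif enrichment.** PWM scanning (MEME minimal format), one best site
  per sequence, binomial positional test against a uniform null, Fisher
  differential test against a control set, Bonferroni/BH adjustment.
* **Simulator.** A seeded gene-family evolution simulator (duplication,
  retrotransposition, intron gain/loss, tandem exon duplication, GC
  donors, gene loss, Jukes-Cantor drift) that emits FASTA + GFF3 +
  Newick plus a ground-truth event ledger, so every stage above is
  tested against known histories.

## Worked example

Simulate a family with retrotransposition on a four-species tree, then
recover the events from the emitted annotation alone:

```r
library(exonarch)

cfg <- sim_config(seed = 42, event_rates = list(retrotransposition = 0.1))
sim <- evolve_family(cfg)
sim
#> sim_result: seed 42 - 4 species with genes, 3 events, 2 observable duplication(s), 0 observable loss(es)
cat(sim$gene_tree_newick)
#> ((A|g1,(B|g1,B|g2)),(C|g1,(D|g1,D|g3)));

lca_reconcile(sim$gene_tree, sim$species_tree)
#> reconciliation: 2 duplication(s), 0 loss(es)

archs <- lapply(names(sim$models$B), function(g)
  derive_architecture(sim$models$B[[g]]))
archs[[1]]
#> exon_architecture B_g1: 9 exon(s), 8 internal border(s), 7 split codon(s)
archs[[2]]
#> exon_architecture B_g2: 1 exon(s), 0 internal border(s), 0 split codon(s)

cl <- classify_retro_origin(archs[[2]], archs[-2])
cl$class
#> [1] "retro_candidate"
```

The two retrocopies (`g2` in B, `g3` in D) appear as duplications in the
reconciliation, and the intron-free copy is flagged as a
retrotransposition candidate because it shares zero of the family's eight
borders and sits far below the family's median intron count. The extra
ninth exon of `B_g1` relative to the eight-exon ancestor is a simulated
intron gain, recoverable with `polarize_border_characters()`.

Splice-level analysis of a cassette exon flanked by split codons (the
GNAS exon3 geometry) with a TG acceptor on the downstream intron yields
four isoforms; inclusion versus exclusion differs by 15 residues (14
encoded by the exon plus one completed across the junction):

```r
# toy: exon2 ends "GA" (phase-2 border), exon3 = "A" + 14 codons + "GG",
# exon4 starts "T", downstream intron ends "TGCAG"
# (scripts/acceptance.R builds exactly this construct)
iso <- enumerate_isoforms(toy$model, toy$genome,
                          cassette_exons = 2, alt_acceptors = 2)
nrow(iso)
#> [1] 4
inc <- iso[iso$label == "e2+_i2AG", ]; exc <- iso[iso$label == "e2-_i2AG", ]
isoform_delta(inc, exc)$length_difference
#> [1] 15
```

A YAML-configured end-to-end run (simulate or load inputs, write TSV
reports) is available as `run_pipeline()`, with a thin script wrapper in
`inst/scripts/exonarch-pipeline.R`.

## Scope

Alignment and tree inference, selection analyses, recombination tests,
structural modeling and database mining are out of scope: alignments,
trees, similarity hits and expression tables are consumed as standard
files. See the methods vignette
(`vignettes/exon-architecture-methods.Rmd`) for the models, parameter
defaults, simulator semantics, and known limitations.
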