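toy_two_exon <- function(e1, intron, e2, strand = "+") {
  chrom <- paste0(e1, intron, e2)
  if (strand == "-") {
    n <- nchar(chrom)
    g <- genome(c(chr = revcomp(chrom)))
    exons <- list(coding_exon("chr", n - nchar(e1), n, "-"),
                  coding_exon("chr", 0, nchar(e2), "-"))
  } else {
    g <- genome(c(chr = chrom))
    exons <- list(coding_exon("chr", 0, nchar(e1), "+"),
                  coding_exon("chr", nchar(e1) + nchar(intron),
                              nchar(chrom), "+"))
  }
  list(model = gene_model("t", "sp", "fam", list(t1 = exons)), genome = g)
}

test_that("donor/acceptor dinucleotides classify canonically and strand-aware", {
  t1 <- toy_two_exon("ATGAAA", paste0("GTAAGT", strrep("T", 10), "TTACAG"),
                     "GGGTAA")
  ss <- scan_splice_sites(t1$model, t1$genome)
  expect_equal(ss$classification, "canonical_GT_AG")
  expect_false(ss$alt_acceptor)

  t2 <- toy_two_exon("ATGAAA", paste0("GCAAGT", strrep("T", 10), "TTACAG"),
                     "GGGTAA")
  expect_equal(scan_splice_sites(t2$model, t2$genome)$classification,
               "noncanonical_GC_AG")

  t3 <- toy_two_exon("ATGAAA", paste0("GTAAGT", strrep("T", 10), "TGCAG"),
                     "GGGTAA")
  ss3 <- scan_splice_sites(t3$model, t3$genome)
  expect_equal(ss3$classification, "canonical_GT_AG")
  expect_true(ss3$alt_acceptor)
  expect_equal(ss3$alt_included_nt, "CAG")

  # strand symmetry: the same gene annotated on the minus strand of the
  # reverse-complemented genome yields identical calls
  t3m <- toy_two_exon("ATGAAA", paste0("GTAAGT", strrep("T", 10), "TGCAG"),
                      "GGGTAA", strand = "-")
  expect_equal(scan_splice_sites(t3m$model, t3m$genome)[, -1],
               ss3[, -1])

  t4 <- toy_two_exon("ATGAAA", "GTAAG", "GGGTAA")
  ss4 <- scan_splice_sites(t4$model, t4$genome)
  expect_true(ss4$too_short)
})

test_that("splice-site calls are strand-symmetric on simulated genes", {
  sim <- evolve_family(sim_config(seed = 6, event_rates = list(
    donor_gc_mutation = 0.2)))
  for (sp in names(sim$models)) {
    gid <- names(sim$models[[sp]])[1]
    m <- sim$models[[sp]][[gid]]
    if (length(m$transcripts[[1]]) < 2L) next
    fwd <- scan_splice_sites(m, sim$genomes[[sp]])
    # flip: reverse-complement every scaffold and mirror the annotation
    g <- sim$genomes[[sp]]
    flipped <- genome(stats::setNames(revcomp(unclass(g)), names(g)))
    ex <- m$transcripts[[1]]
    L <- nchar(g[[ex[[1]]$seq_id]])
    ex_m <- lapply(ex, function(e) {
      coding_exon(e$seq_id, L - e$end, L - e$start, "-")
    })
    m_m <- gene_model(m$gene_id, m$species_id, m$family_label,
                      list(t1 = ex_m))
    rev_ss <- scan_splice_sites(m_m, flipped)
    expect_equal(rev_ss, fwd)
  }
})

test_that("simulated GC-donor events are recovered with full recall", {
  total <- 0L; recovered <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = s, event_rates = list(
      tandem_duplication = 0, retrotransposition = 0, intron_gain = 0,
      intron_loss = 0, exon_tandem_duplication = 0,
      donor_gc_mutation = 0.15, gene_loss = 0))
    sim <- evolve_family(cfg)
    led <- sim$ledger[sim$ledger$event == "donor_gc_mutation", , drop = FALSE]
    for (i in seq_len(nrow(led))) {
      j <- as.integer(sub("intron=", "", led$detail[i]))
      for (sp in tips_below(sim$species_tree, led$branch[i])) {
        m <- sim$models[[sp]][[paste0(sp, "_", led$parent_gene[i])]]
        if (is.null(m)) next
        total <- total + 1L
        ss <- scan_splice_sites(m, sim$genomes[[sp]])
        if (ss$classification[ss$intron == j] == "noncanonical_GC_AG") {
          recovered <- recovered + 1L
        }
      }
    }
  }
  expect_gt(total, 0L)
  expect_equal(recovered, total)
})

test_that("mutually exclusive exon groups are found for simulated duplications", {
  sim <- NULL; led <- NULL
  for (s in 1:20) {
    cfg <- sim_config(seed = s, substitution_rate = 0, event_rates = list(
      tandem_duplication = 0, retrotransposition = 0, intron_gain = 0,
      intron_loss = 0, exon_tandem_duplication = 0.08,
      donor_gc_mutation = 0, gene_loss = 0))
    cand <- evolve_family(cfg)
    l <- cand$ledger
    if (nrow(l) == 1L && l$event == "exon_tandem_duplication") {
      sim <- cand; led <- l; break
    }
  }
  expect_false(is.null(sim))
  i <- 1L
  run_len <- as.integer(sub(".*run_length=", "", led$detail[i]))
  first_exon <- as.integer(sub("first_exon=(\\d+);.*", "\\1", led$detail[i]))
  for (sp in tips_below(sim$species_tree, led$branch[i])) {
    m <- sim$models[[sp]][[paste0(sp, "_", led$parent_gene[i])]]
    # at the default permissive threshold the duplicated run is recovered
    groups <- find_mutually_exclusive_exons(m, sim$genomes[[sp]])
    expect_equal(length(groups), 1L)
    alt <- groups[[1]]$alternatives
    expect_equal(alt[[1]], first_exon:(first_exon + run_len - 1L))
    expect_equal(alt[[2]], alt[[1]] + run_len)
    # at a strict threshold only the exact (undiverged) copy survives
    strict <- find_mutually_exclusive_exons(m, sim$genomes[[sp]],
                                            identity_min = 0.9)
    expect_equal(length(strict), 1L)
    expect_equal(length(strict[[1]]$alternatives), 2L)
    expect_equal(strict[[1]]$identity, 1)
    expect_equal(strict[[1]]$entering_phase %% 3L,
                 strict[[1]]$entering_phase)
  }
})

test_that("dissimilar exons never group and thresholds act monotonically", {
  # gene with clearly distinct exons
  e1 <- paste0("ATG", strrep("GCT", 10))      # poly-Ala
  e2 <- strrep("TGG", 11)                      # poly-Trp
  e3 <- paste0(strrep("CAT", 10), "TAA")       # poly-His
  i1 <- paste0("GT", strrep("A", 16), "AG")
  chrom <- paste0(e1, i1, e2, i1, e3)
  g <- genome(c(chr = chrom))
  offs <- cumsum(c(0, nchar(c(e1, i1, e2, i1))))
  m <- gene_model("t", "sp", "f", list(t1 = list(
    coding_exon("chr", offs[1], offs[1] + nchar(e1), "+"),
    coding_exon("chr", offs[3], offs[3] + nchar(e2), "+"),
    coding_exon("chr", offs[5], offs[5] + nchar(e3), "+"))))
  expect_length(find_mutually_exclusive_exons(m, g), 0L)

  # diverged duplicate: found only once the threshold is low enough
  e2b <- paste0(strrep("TGG", 5), strrep("CGG", 6))  # half Trp, half Arg
  chrom2 <- paste0(e1, i1, e2, i1, e2b, i1, e3)
  g2 <- genome(c(chr = chrom2))
  offs2 <- cumsum(c(0, nchar(c(e1, i1, e2, i1, e2b, i1))))
  m2 <- gene_model("t2", "sp", "f", list(t1 = list(
    coding_exon("chr", offs2[1], offs2[1] + nchar(e1), "+"),
    coding_exon("chr", offs2[3], offs2[3] + nchar(e2), "+"),
    coding_exon("chr", offs2[5], offs2[5] + nchar(e2b), "+"),
    coding_exon("chr", offs2[7], offs2[7] + nchar(e3), "+"))))
  hi <- find_mutually_exclusive_exons(m2, g2, identity_min = 0.8)
  lo <- find_mutually_exclusive_exons(m2, g2, identity_min = 0.3)
  expect_length(hi, 0L)
  expect_length(lo, 1L)
})

test_that("isoform enumeration multiplies independent feature choices", {
  toy <- gnas_like_toy()
  iso <- enumerate_isoforms(toy$model, toy$genome, cassette_exons = 2L,
                            alt_acceptors = 2L)
  expect_equal(nrow(iso), 4L)                   # cassette x acceptor
  expect_true(all(iso$frame_ok))
  expect_false(any(iso$premature_stop))

  iso1 <- enumerate_isoforms(toy$model, toy$genome)
  expect_equal(nrow(iso1), 1L)

  expect_error(enumerate_isoforms(toy$model, toy$genome,
                                  cassette_exons = 2L,
                                  mxe_groups = list(structure(list(
                                    gene_id = "GNASlike",
                                    alternatives = list(2L, 3L)),
                                    class = "mxe_group"))),
               "conflicting")

  # an MXE group alone yields one isoform per alternative
  sim <- NULL; led <- NULL
  for (s in 1:20) {
    cand <- evolve_family(sim_config(seed = s, substitution_rate = 0,
                                     event_rates = list(
      tandem_duplication = 0, retrotransposition = 0, intron_gain = 0,
      intron_loss = 0, exon_tandem_duplication = 0.1,
      donor_gc_mutation = 0, gene_loss = 0)))
    l <- cand$ledger[cand$ledger$event == "exon_tandem_duplication", ,
                     drop = FALSE]
    if (nrow(l) > 0L) { sim <- cand; led <- l; break }
  }
  expect_false(is.null(sim))
  sp <- tips_below(sim$species_tree, led$branch[1])[1]
  m <- sim$models[[sp]][[paste0(sp, "_", led$parent_gene[1])]]
  groups <- find_mutually_exclusive_exons(m, sim$genomes[[sp]])
  iso2 <- enumerate_isoforms(m, sim$genomes[[sp]], mxe_groups = groups[1])
  expect_equal(nrow(iso2), length(groups[[1]]$alternatives))
})

test_that("the cassette-exon inclusion adds 15 residues, one via a split codon", {
  toy <- gnas_like_toy()
  iso <- enumerate_isoforms(toy$model, toy$genome, cassette_exons = 2L,
                            alt_acceptors = 2L)
  inc <- iso[iso$label == "e2+_i2AG", ]
  exc <- iso[iso$label == "e2-_i2AG", ]
  d <- isoform_delta(inc, exc)
  expect_equal(d$length_difference, 15L)
  # junction residues: E...G with the cassette, D without; the TG
  # acceptor appends an S in both backgrounds
  inc_s <- iso[iso$label == "e2+_i2TG", ]
  exc_s <- iso[iso$label == "e2-_i2TG", ]
  expect_equal(substr(exc$protein, 7, 7), "D")
  expect_equal(substr(inc$protein, 7, 7), "E")
  expect_equal(substr(exc_s$protein, 7, 8), "DS")
  expect_equal(isoform_delta(inc_s, exc_s)$length_difference, 15L)
  expect_equal(isoform_delta(inc, inc)$length_difference, 0L)
  expect_equal(isoform_delta(inc, inc)$substitutions, 0L)
})

test_that("swapping equal-length diverged exons changes residues, not length", {
  a <- "MAAAWWWAAA"
  b <- "MAAAYYWAAA"
  d <- isoform_delta(a, b)
  expect_equal(d$length_difference, 0L)
  expect_equal(d$substitutions, 2L)
})
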