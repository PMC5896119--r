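hit_row <- function(qstart, qend, sstart, send, pident = 98) {
  data.frame(query = "q", subject = "s", pident = pident,
             length = qend - qstart + 1L, mismatch = 0L, gapopen = 0L,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = 1e-30, bitscore = 200,
             strand = ifelse(sstart <= send, "+", "-"),
             stringsAsFactors = FALSE)
}

test_that("locus classification follows the coverage bands", {
  expect_equal(classify_locus(hit_row(1, 850, 5001, 5850), 1000)$class,
               "retrogene_candidate")
  expect_equal(classify_locus(hit_row(1, 400, 5001, 5400), 1000)$class,
               "manual_review")
  expect_equal(classify_locus(hit_row(1, 200, 5001, 5200), 1000)$class,
               "exon_fragment")
  # two collinear hits far apart on the subject: exon-by-exon match
  two <- rbind(hit_row(1, 300, 5001, 5300), hit_row(301, 600, 9001, 9300))
  call <- classify_locus(two, 1000)
  expect_equal(call$class, "excluded_multi_hit")
  expect_true(call$collinear)
  # overlapping duplicate HSPs merge into one hit first
  dup <- rbind(hit_row(1, 500, 5001, 5500), hit_row(100, 600, 5101, 5600))
  expect_equal(classify_locus(dup, 1000)$class, "retrogene_candidate")
  expect_error(classify_locus(hit_row(1, 1, 1, 1)[0, ], 1000), "empty")
})

test_that("the tabular hit reader handles strand encoding", {
  f <- withr::local_tempfile()
  writeLines(paste(c("q", "s", "97.5", "300", "5", "1",
                     "1", "300", "9300", "9001", "1e-50", "400"),
                   collapse = "\t"), f)
  h <- read_similarity_hits(f)
  expect_equal(h$strand, "-")
  expect_equal(h$pident, 97.5)
})

test_that("ORF discovery respects bounds, strand and the Met rule", {
  set.seed(31)
  orf <- paste0("ATG", random_codons(40), "TAA")
  win <- paste0(rand_dna(30), orf, rand_dna(30))
  found <- find_orfs(win, min_aa = 40)
  expect_gte(nrow(found), 1L)
  best <- found[1, ]
  expect_equal(best$length_aa, 41L)
  expect_true(best$has_met)
  expect_match(best$protein, "^M")

  # all-sense window too short for the threshold
  expect_equal(nrow(find_orfs(random_codons(30), min_aa = 40)), 0L)

  # minus-strand ORF
  found_m <- find_orfs(revcomp(win), min_aa = 40)
  expect_true(any(found_m$strand == "-" & found_m$length_aa == 41L))

  # windowing clips at edges with a warning
  expect_warning(find_orfs(win, hit_start = 31, hit_end = 60, flank = 300,
                           min_aa = 40), "clipped")
})

test_that("the ORF scanner agrees with a six-frame translation oracle", {
  oracle_orfs <- function(seqs, min_aa, require_met) {
    out <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs else revcomp(seqs)
      for (frame in 0:2) {
        sub <- substr(s, frame + 1L, nchar(s))
        sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
        if (nchar(sub) < 3L) next
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(sub), no.init.codon = TRUE))
        segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
        for (seg in segs) {
          if (require_met) {
            mpos <- regexpr("M", seg, fixed = TRUE)
            if (mpos < 0) next
            seg <- substr(seg, mpos, nchar(seg))
          }
          if (nchar(seg) >= min_aa) {
            out[[length(out) + 1L]] <- c(strand, nchar(seg))
          }
        }
      }
    }
    out
  }
  set.seed(77)
  for (i in 1:12) {
    s <- rand_dna(1000)
    mine <- find_orfs(s, min_aa = 15)
    ref <- oracle_orfs(s, 15, TRUE)
    expect_equal(nrow(mine), length(ref))
    expect_equal(sort(paste(mine$strand, mine$length_aa)),
                 sort(vapply(ref, paste, "", collapse = " ")))
    # reported windows really are stop-free Met-initiated frames
    for (k in seq_len(nrow(mine))) {
      seg <- substr(s, mine$start[k], mine$end[k])
      if (mine$strand[k] == "-") seg <- revcomp(seg)
      aa <- translate_cds(seg)
      expect_match(aa$protein, "^M")
      expect_false(aa$internal_stop)
    }
  }
})

test_that("parent similarity separates true fragments from shuffles", {
  set.seed(41)
  parent <- translate_cds(paste0("ATG", random_codons(200), "TAA"))$protein
  frag <- substr(parent, 50, 109)
  r <- check_parent_similarity(frag, parent)
  expect_true(r$similar)
  expect_equal(r$identity, 100)
  shuffled <- paste(sample(strsplit(frag, "")[[1]]), collapse = "")
  r2 <- check_parent_similarity(shuffled, parent)
  expect_false(r2$similar)
  # a 99%-identity near-full copy qualifies (the gorilla-type case)
  mut <- strsplit(parent, "")[[1]]
  mut[10] <- if (mut[10] == "A") "V" else "A"
  r3 <- check_parent_similarity(paste(mut, collapse = ""), parent)
  expect_true(r3$similar)
  expect_gt(r3$identity, 99)
})

test_that("accumulating premature stops degrades parent-similar ORFs to zero", {
  set.seed(19)
  parent_nt <- paste0("ATG", random_codons(120), "TAA")
  parent_aa <- translate_cds(parent_nt)$protein
  counts <- integer(0)
  for (nstops in 0:3) {
    mutated <- parent_nt
    at <- 3L * c(30L, 60L, 90L) + 1L
    for (a in at[seq_len(nstops)]) substr(mutated, a, a + 2L) <- "TAA"
    orfs <- find_orfs(mutated, min_aa = 40)
    # restrict to the reading frame of the parent to keep the measure
    # deterministic under the induced frame changes
    orfs <- orfs[orfs$strand == "+" & orfs$frame == 0L, , drop = FALSE]
    similar <- sum(vapply(seq_len(nrow(orfs)), function(k) {
      check_parent_similarity(orfs$protein[k], parent_aa)$similar
    }, TRUE))
    counts <- c(counts, similar)
  }
  expect_true(all(diff(counts) <= 0L))
  expect_gte(counts[1], 1L)
  expect_equal(counts[4], 0L)
})

test_that("novel-ORF conservation requires an intact Met ORF in every species", {
  set.seed(53)
  core <- paste0("ATG", random_codons(50), "TAA")
  locus <- paste0(rand_dna(12), core, rand_dna(12))
  four <- stats::setNames(rep(locus, 4), paste0("sp", 1:4))
  expect_true(check_novel_orf_conservation(four, min_aa = 40)$conserved)

  # one species gains a premature stop
  broken <- four
  s <- broken[2]
  substr(s, 13 + 60, 13 + 62) <- "TGA"
  broken[2] <- s
  expect_false(check_novel_orf_conservation(broken, min_aa = 40)$conserved)

  # conserved frame but no methionine anywhere
  no_met <- gsub("ATG", "GCG", four)
  expect_false(check_novel_orf_conservation(no_met, min_aa = 40)$conserved)

  # an all-gap species counts as not conserved
  gappy <- four
  gappy[3] <- strrep("-", nchar(locus))
  expect_false(check_novel_orf_conservation(gappy, min_aa = 40)$conserved)
})

test_that("functional status follows the evidence decision table", {
  expr <- data.frame(locus = rep(c("L1", "L3"), c(6, 1)),
                     experiment = paste0("e", 1:7),
                     tissue = "testis",
                     rpkm = c(rep(2.0, 6), 0.8))
  expect_equal(assign_status("L1", TRUE, expr)$status, "functional")
  expect_equal(assign_status("L1", TRUE, expr)$n_expressed_experiments, 6L)
  expect_warning(s2 <- assign_status("L2", TRUE, expr), "absent")
  expect_equal(s2$status, "conserved_unexpressed")
  expect_equal(assign_status("L3", FALSE, expr)$status, "expressed_only")
  expect_warning(s4 <- assign_status("L4", FALSE, expr), "absent")
  expect_equal(s4$status, "pseudo")
  # the RPKM threshold is exclusive
  low <- data.frame(locus = "L5", experiment = "e1", tissue = "liver",
                    rpkm = 0.5)
  expect_equal(assign_status("L5", FALSE, low)$status, "pseudo")
})

test_that("simulated retrocopies classify as candidates from coverage", {
  n <- 0L; ok <- 0L
  for (s in 1:25) {
    cfg <- sim_config(seed = s, substitution_rate = 0, event_rates = list(
      tandem_duplication = 0, retrotransposition = 0.12, intron_gain = 0,
      intron_loss = 0, exon_tandem_duplication = 0, donor_gc_mutation = 0,
      gene_loss = 0))
    sim <- evolve_family(cfg)
    retro <- unique(sim$ledger$child_gene[
      sim$ledger$event == "retrotransposition"])
    for (sp in names(sim$models)) {
      for (gid in names(sim$models[[sp]])) {
        if (!(sub(paste0(sp, "_"), "", gid) %in% retro)) next
        parent_cds <- assemble_cds(sim$models[[sp]][[1]],
                                   sim$genomes[[sp]])$sequence
        locus <- sim$genomes[[sp]][[
          sim$models[[sp]][[gid]]$transcripts[[1]][[1]]$seq_id]]
        al <- sw_align(parent_cds, locus)
        h <- data.frame(query = "p", subject = "l", pident = al$pident,
                        length = al$length, mismatch = 0, gapopen = 0,
                        qstart = al$qstart, qend = al$qend,
                        sstart = al$sstart, send = al$send,
                        evalue = 0, bitscore = al$score, strand = "+")
        n <- n + 1L
        if (classify_locus(h, nchar(parent_cds))$class ==
              "retrogene_candidate") ok <- ok + 1L
      }
    }
  }
  expect_gte(n, 10L)
  expect_gte(ok / n, 0.95)
})
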