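# shared fixtures, all built in code

# tips below a simulation branch label ("A" or "n6")
tips_below <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  nd <- as.integer(sub("^n", "", label))
  ape::extract.clade(tree, nd)$tip.label
}

# architecture with given exon lengths (coordinates are arbitrary)
make_arch <- function(id, lens) {
  starts <- cumsum(c(0L, lens + 10L))[seq_along(lens)]
  exons <- lapply(seq_along(lens), function(i) {
    coding_exon("c", starts[i], starts[i] + lens[i], "+")
  })
  derive_architecture(gene_model(id, "sp", "fam", list(t1 = exons)))
}

random_codons <- function(n) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    !grepl("[^ACGT]", names(Biostrings::GENETIC_CODE))],
    c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# GNAS-like three-segment toy: exon2 ends mid-codon ("GA", phase-2
# border), cassette exon3 carries 14 full codons plus the two split
# codons, exon4 starts "T" so that skipping is frame-preserving and gives
# the D / E...G junction pattern; the exon3/exon4 intron ends TGCAG so
# the upstream TG acceptor can add "CAG" to exon4.
gnas_like_toy <- function(seed = 1) {
  set.seed(seed)
  e2 <- paste0("ATG", random_codons(5), "GA")
  e3 <- paste0("A", random_codons(14), "GG")
  e4 <- paste0("T", random_codons(6), "TAA")
  i1 <- paste0("GT", strrep("A", 20), "AG")
  i2 <- paste0("GT", strrep("C", 16), "TGCAG")
  lens <- nchar(c(e2, i1, e3, i2, e4))
  starts <- cumsum(c(0L, lens[-5]))
  model <- gene_model("GNASlike", "hs", "GNAS", list(t1 = list(
    coding_exon("chr", starts[1], starts[1] + lens[1], "+"),
    coding_exon("chr", starts[3], starts[3] + lens[3], "+"),
    coding_exon("chr", starts[5], starts[5] + lens[5], "+"))))
  list(model = model, genome = genome(c(chr = paste0(e2, i1, e3, i2, e4))))
}

# all rooted topologies as a plain list ([[ on multiPhylo reattaches the
# compressed tip labels; raw iteration would drop them)
all_rooted_trees <- function(tips) {
  mp <- phangorn::allTrees(length(tips), rooted = TRUE, tip.label = tips)
  lapply(seq_along(mp), function(i) mp[[i]])
}

# independent LCA reconciliation oracle built on ape primitives
oracle_reconcile <- function(gene_tree, species_tree, sep = "|") {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(text = species_tree)
  }
  gn <- length(gene_tree$tip.label)
  sp_root <- length(species_tree$tip.label) + 1L
  sp_depth <- function(nd) length(ape::nodepath(species_tree, sp_root, nd)) - 1L
  clade_tips <- function(nd) {
    if (nd <= gn) gene_tree$tip.label[nd]
    else ape::extract.clade(gene_tree, nd)$tip.label
  }
  image <- function(nd) {
    sp <- unique(leaf_species(clade_tips(nd), sep))
    tips <- match(sp, species_tree$tip.label)
    if (length(tips) == 1L) tips else ape::getMRCA(species_tree, tips)
  }
  nnode <- gn + gene_tree$Nnode
  dup <- logical(nnode)
  for (nd in (gn + 1L):nnode) {
    ch <- gene_tree$edge[gene_tree$edge[, 1] == nd, 2]
    dup[nd] <- any(vapply(ch, function(c2) image(c2) == image(nd), TRUE))
  }
  losses <- 0L
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    d <- sp_depth(image(v)) - sp_depth(image(u))
    losses <- losses + max(0L, d - (if (dup[u]) 0L else 1L))
  }
  list(duplications = sum(dup), losses = losses)
}

# brute-force minimum-change count for a binary character on a rooted tree
# by exhaustive enumeration of internal-node state assignments
oracle_min_changes <- function(states, tree, gain_cost = 1, loss_cost = 1) {
  ntip <- length(tree$tip.label)
  ninternal <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^ninternal - 1)) {
    lab <- integer(ntip + ninternal)
    lab[seq_len(ntip)] <- states[tree$tip.label]
    lab[ntip + seq_len(ninternal)] <- bitwAnd(mask %/% 2^(seq_len(ninternal) - 1L), 1L)
    ok <- TRUE
    cost <- 0
    for (i in seq_len(nrow(tree$edge))) {
      u <- lab[tree$edge[i, 1]]; v <- lab[tree$edge[i, 2]]
      if (is.na(v)) next  # unknown leaf: free
      if (is.na(u)) { ok <- FALSE; break }
      if (u == 0 && v == 1) cost <- cost + gain_cost
      if (u == 1 && v == 0) cost <- cost + loss_cost
    }
    if (ok) best <- min(best, cost)
  }
  # unknown leaves: rerun allowing both leaf states
  unk <- which(is.na(states[tree$tip.label]))
  if (length(unk)) {
    combos <- expand.grid(rep(list(0:1), length(unk)))
    best <- Inf
    for (ci in seq_len(nrow(combos))) {
      st2 <- states
      st2[tree$tip.label[unk]] <- unlist(combos[ci, ])
      best <- min(best, oracle_min_changes(st2, tree, gain_cost, loss_cost))
    }
  }
  best
}
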