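# Gene-family evolution simulator. Evolves a multi-exon gene along a
# species tree with tandem duplication, retrotransposition, intron
# gain/loss, tandem exon duplication (mutually exclusive exon variants),
# donor GT->GC mutation and gene loss, under Jukes-Cantor substitution.
# Emits genomes + annotations + the true gene tree + a ground-truth event
# ledger, so every downstream analysis stage can be tested against a known
# history.

SIM_EVENT_TYPES <- c("tandem_duplication", "retrotransposition",
                     "intron_gain", "intron_loss",
                     "exon_tandem_duplication", "donor_gc_mutation",
                     "gene_loss")

#' Build a simulation configuration
#'
#' Defaults describe a small deuterostome-like study setting: a four-taxon
#' species tree, an eight-exon root gene, and low per-branch event rates of
#' the classes inferred for the GNA- family (retrotransposition, intron
#' gain/loss, tandem exon duplication creating mutually exclusive variants,
#' GC donors, gene loss). Rates are per unit branch length; substitution is
#' Jukes-Cantor per site per unit branch length.
#'
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @param species_tree rooted binary `phylo` or Newick string with branch
#'   lengths.
#' @param root_exon_count number of exons of the ancestral gene.
#' @param exon_length_range,intron_length_range nt length ranges.
#' @param substitution_rate Jukes-Cantor rate per site per unit branch.
#' @param event_rates named list of per-unit-branch rates for the event
#'   types `r paste(SIM_EVENT_TYPES, collapse = ", ")`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       species_tree = "((A:1,B:1):1,(C:1,D:1):1);",
                       root_exon_count = 8L,
                       exon_length_range = c(30L, 120L),
                       intron_length_range = c(20L, 60L),
                       substitution_rate = 0.02,
                       event_rates = list()) {
  defaults <- list(tandem_duplication = 0.05, retrotransposition = 0.05,
                   intron_gain = 0.03, intron_loss = 0.03,
                   exon_tandem_duplication = 0.02, donor_gc_mutation = 0.02,
                   gene_loss = 0.05)
  if (!all(names(event_rates) %in% SIM_EVENT_TYPES)) {
    stop("unknown event rate name(s): ",
         paste(setdiff(names(event_rates), SIM_EVENT_TYPES), collapse = ", "))
  }
  defaults[names(event_rates)] <- event_rates
  if (any(unlist(defaults) < 0) || substitution_rate < 0) {
    stop("rates must be >= 0")
  }
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  if (is.null(species_tree$edge.length)) {
    stop("species tree needs branch lengths")
  }
  if (root_exon_count < 1L) stop("need at least one exon")
  if (exon_length_range[1] < 3L || diff(exon_length_range) < 0) {
    stop("infeasible exon length range")
  }
  if (intron_length_range[1] < 8L || diff(intron_length_range) < 0) {
    stop("infeasible intron length range (minimum 8 nt)")
  }
  structure(list(seed = as.integer(seed), species_tree = species_tree,
                 root_exon_count = as.integer(root_exon_count),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 substitution_rate = substitution_rate,
                 event_rates = defaults),
            class = "sim_config")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  !grepl("[^ACGT]", names(Biostrings::GENETIC_CODE))], STOP_CODONS)

rand_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_intron <- function(config) {
  len <- sample(seq(config$intron_length_range[1],
                    config$intron_length_range[2]), 1L)
  paste0("GT", rand_nt(len - 4L), "AG")
}

# Internal gene representation during simulation: exon/intron sequences.
make_root_gene_seqs <- function(config) {
  k <- config$root_exon_count
  lens <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                 k, replace = TRUE)
  lens[k] <- lens[k] + (3L - sum(lens) %% 3L) %% 3L
  ncod <- sum(lens) %/% 3L
  if (ncod < 2L) stop("exon length range too small for an ORF")
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, ncod - 2L, replace = TRUE),
                      collapse = ""),
                "TAA")
  ends <- cumsum(lens)
  starts <- c(1L, ends[-k] + 1L)
  exons <- substring(cds, starts, ends)
  introns <- if (k > 1L) vapply(seq_len(k - 1L), function(i) rand_intron(config),
                                "") else character(0)
  list(id = "g1", exons = exons, introns = introns, retro = FALSE)
}

# Lay a gene out on its own scaffold with random flanking pads, and return
# the scaffold sequence plus the coding-exon annotation.
realize_gene <- function(g, species_id, pad = 25L) {
  pre <- rand_nt(pad); post <- rand_nt(pad)
  body <- character(0)
  for (i in seq_along(g$exons)) {
    body <- c(body, g$exons[i])
    if (i <= length(g$introns)) body <- c(body, g$introns[i])
  }
  scaf <- paste0(pre, paste(body, collapse = ""), post)
  scaf_id <- paste0(species_id, "_", g$id, "_scaf")
  pos <- pad
  exons <- vector("list", length(g$exons))
  for (i in seq_along(g$exons)) {
    len <- nchar(g$exons[i])
    exons[[i]] <- coding_exon(scaf_id, pos, pos + len, "+")
    pos <- pos + len
    if (i <= length(g$introns)) pos <- pos + nchar(g$introns[i])
  }
  model <- gene_model(paste0(species_id, "_", g$id), species_id,
                      "simfam", stats::setNames(list(exons),
                                                paste0(species_id, "_", g$id, ".t1")))
  list(scaf_id = scaf_id, seq = scaf, model = model)
}

#' Generate the ancestral (root) gene of a simulation
#'
#' @param config a [sim_config()].
#' @return list with the realized `model` ([gene_model()]), `genome`
#'   fragment ([genome()]) and the internal `gene` representation.
#' @export
generate_root_gene <- function(config) {
  set.seed(config$seed)
  g <- make_root_gene_seqs(config)
  r <- realize_gene(g, "root")
  list(gene = g, model = r$model,
       genome = genome(stats::setNames(r$seq, r$scaf_id)))
}

jc_mutate <- function(seqs, p) {
  # Jukes-Cantor: each site changes with prob p = 3/4 (1 - exp(-4/3 r t)),
  # uniformly to one of the other three bases.
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return(s)
    hit <- which(stats::runif(n) < p)
    if (length(hit) == 0L) return(s)
    chars <- strsplit(s, "")[[1]]
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

mutate_gene <- function(g, rate, t) {
  if (rate <= 0 || t <= 0) return(g)
  p <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  g$exons <- jc_mutate(g$exons, p)
  # splice-site dinucleotides are never touched by background substitution
  g$introns <- vapply(g$introns, function(intr) {
    n <- nchar(intr)
    if (n <= 4L) return(intr)
    mid <- jc_mutate(substr(intr, 3L, n - 2L), p)
    paste0(substr(intr, 1L, 2L), mid, substr(intr, n - 1L, n))
  }, "", USE.NAMES = FALSE)
  g
}

#' Simulate gene-family evolution along a species tree
#'
#' Events are drawn as Poisson processes per branch (rate x branch length)
#' and applied gene by gene in a fixed documented order from a single
#' random stream, so a fixed seed reproduces every output byte. Copies
#' created on a branch start evolving on the following branches.
#' Retrocopies are intron-free single-exon genes; every gene is emitted on
#' its own scaffold, mimicking fragmented assemblies.
#'
#' @param config a [sim_config()].
#' @return a `sim_result` list: `genomes` and `models` per species,
#'   `ledger` (data.frame of raw events), `gene_tree` (`phylo` of surviving
#'   gene copies, leaf labels `species|gene`, or NULL if fewer than 2
#'   survive), `observable` (duplication/loss counts recoverable from the
#'   surviving gene tree; see the methods vignette), `species_tree`, and
#'   `config`.
#' @export
evolve_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$species_tree
  ntip <- length(tree$tip.label)
  node_label <- function(n) {
    if (n <= ntip) tree$tip.label[n] else paste0("n", n)
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2])

  env <- new.env()
  env$gene_counter <- 1L
  env$nodes <- list()   # genealogy: id, type, parent, species, gene
  env$ledger <- list()
  env$out <- list()     # per species leaf: list of genes
  add_node <- function(type, parent, species, gene) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(id = id, type = type, parent = parent,
                            species = species, gene = gene)
    id
  }
  add_event <- function(type, branch, parent_gene, child_gene, detail) {
    env$ledger[[length(env$ledger) + 1L]] <-
      data.frame(event = type, branch = branch, parent_gene = parent_gene,
                 child_gene = child_gene, detail = detail,
                 stringsAsFactors = FALSE)
  }
  new_gene_id <- function() {
    env$gene_counter <- env$gene_counter + 1L
    paste0("g", env$gene_counter)
  }

  apply_events <- function(lineages, branch_label, t) {
    # lineages: list of list(gene=..., node=genealogy parent node id)
    created <- list()
    keep <- rep(TRUE, length(lineages))
    for (li in seq_along(lineages)) {
      lin <- lineages[[li]]
      g <- lin$gene
      lost <- FALSE
      for (ev in SIM_EVENT_TYPES) {
        nev <- stats::rpois(1L, config$event_rates[[ev]] * t)
        if (nev == 0L) next
        for (rep_i in seq_len(nev)) {
          if (lost) break
          if (ev == "tandem_duplication") {
            child <- g; child$id <- new_gene_id()
            dup <- add_node("dup", lin$node, branch_label, g$id)
            lin$node <- dup
            created[[length(created) + 1L]] <- list(gene = child, node = dup)
            add_event(ev, branch_label, g$id, child$id, "")
          } else if (ev == "retrotransposition") {
            child <- list(id = new_gene_id(),
                          exons = paste(g$exons, collapse = ""),
                          introns = character(0), retro = TRUE)
            dup <- add_node("dup", lin$node, branch_label, g$id)
            lin$node <- dup
            created[[length(created) + 1L]] <- list(gene = child, node = dup)
            add_event(ev, branch_label, g$id, child$id, "intronless_copy")
          } else if (ev == "intron_gain") {
            ok <- which(nchar(g$exons) >= 2L)
            if (length(ok) == 0L) next
            j <- if (length(ok) == 1L) ok else sample(ok, 1L)
            pos <- sample(nchar(g$exons[j]) - 1L, 1L)
            offset <- sum(nchar(g$exons[seq_len(j - 1L)])) + pos
            newint <- rand_intron(config)
            left <- substr(g$exons[j], 1L, pos)
            right <- substr(g$exons[j], pos + 1L, nchar(g$exons[j]))
            g$exons <- append(g$exons[-j], c(left, right), after = j - 1L)
            g$introns <- append(g$introns, newint, after = j - 1L)
            add_event(ev, branch_label, g$id, g$id,
                      paste0("offset=", offset, ";phase=", offset %% 3L))
          } else if (ev == "intron_loss") {
            if (length(g$introns) == 0L) next
            j <- if (length(g$introns) == 1L) 1L else sample(length(g$introns), 1L)
            g$exons <- append(g$exons[-c(j, j + 1L)],
                              paste0(g$exons[j], g$exons[j + 1L]),
                              after = j - 1L)
            g$introns <- g$introns[-j]
            add_event(ev, branch_label, g$id, g$id, paste0("intron=", j))
          } else if (ev == "exon_tandem_duplication") {
            n <- length(g$exons)
            L <- if (n >= 2L) sample(1:2, 1L) else 1L
            i <- if (n - L + 1L == 1L) 1L else sample(n - L + 1L, 1L)
            run_ex <- g$exons[i:(i + L - 1L)]
            run_in <- if (L == 2L) g$introns[i] else character(0)
            sep <- if (i > 1L) g$introns[i - 1L] else if (length(g$introns)) {
              g$introns[min(i + L - 1L, length(g$introns))]
            } else rand_intron(config)
            # insert copy right after the original run
            g$exons <- append(g$exons, run_ex, after = i + L - 1L)
            g$introns <- append(g$introns, c(sep, run_in), after = i + L - 2L)
            add_event(ev, branch_label, g$id, g$id,
                      paste0("first_exon=", i, ";run_length=", L))
          } else if (ev == "donor_gc_mutation") {
            gt <- which(substr(g$introns, 1L, 2L) == "GT")
            if (length(gt) == 0L) next
            j <- if (length(gt) == 1L) gt else sample(gt, 1L)
            substr(g$introns[j], 1L, 2L) <- "GC"
            add_event(ev, branch_label, g$id, g$id, paste0("intron=", j))
          } else if (ev == "gene_loss") {
            lin$node <- add_node("loss", lin$node, branch_label, g$id)
            add_event(ev, branch_label, g$id, "", "")
            lost <- TRUE
          }
        }
        if (lost) break
      }
      if (lost) {
        keep[li] <- FALSE
      } else {
        lin$gene <- g
        lineages[[li]] <- lin
      }
    }
    out <- c(lineages[keep], created)
    # background substitution over the branch (splice dinucleotides exempt)
    for (li in seq_along(out)) {
      out[[li]]$gene <- mutate_gene(out[[li]]$gene, config$substitution_rate, t)
    }
    out
  }

  root_node <- ntip + 1L
  root_gene <- make_root_gene_seqs(config)
  top <- add_node("root", 0L, node_label(root_node), root_gene$id)
  # one 'spec' genealogy node per gene per species-tree internal node; both
  # child branches descend from it, so speciation nodes are binary
  recurse2 <- function(species_node, lineages) {
    if (species_node <= ntip) {
      sp <- tree$tip.label[species_node]
      for (lin in lineages) add_node("leaf", lin$node, sp, lin$gene$id)
      env$out[[sp]] <- lapply(lineages, `[[`, "gene")
      return(invisible(NULL))
    }
    spec_nodes <- vapply(lineages, function(lin) {
      add_node("spec", lin$node, node_label(species_node), lin$gene$id)
    }, 0L)
    for (child in kids[[as.character(species_node)]]) {
      branch_lineages <- lapply(seq_along(lineages), function(i) {
        list(gene = lineages[[i]]$gene, node = spec_nodes[i])
      })
      evolved <- apply_events(branch_lineages, node_label(child),
                              edge_len[[as.character(child)]])
      recurse2(child, evolved)
    }
  }
  recurse2(root_node, list(list(gene = root_gene, node = top)))

  # realize genomes + annotations per species (deterministic order)
  genomes <- list(); models <- list()
  for (sp in tree$tip.label) {
    genes <- env$out[[sp]] %||% list()
    if (length(genes) == 0L) next
    seqs <- character(0); mods <- list()
    for (g in genes) {
      r <- realize_gene(g, sp)
      seqs[r$scaf_id] <- r$seq
      mods[[r$model$gene_id]] <- r$model
    }
    genomes[[sp]] <- genome(seqs)
    models[[sp]] <- mods
  }

  ledger <- if (length(env$ledger)) {
    do.call(rbind, env$ledger)
  } else {
    data.frame(event = character(0), branch = character(0),
               parent_gene = character(0), child_gene = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  }

  gt <- genealogy_summary(env$nodes, tree)
  structure(list(config = config, genomes = genomes, models = models,
                 ledger = ledger, gene_tree = gt$tree,
                 gene_tree_newick = gt$newick,
                 observable = gt$observable,
                 species_tree = tree,
                 genes = env$out),
            class = "sim_result")
}

# Prune the event genealogy to surviving lineages; derive the true gene
# tree and the observable duplication/loss counts: the events recoverable
# from the surviving copies under most-parsimonious placement. Computed
# directly on the genealogy node table with species-set images, so it is a
# separate code path from lca_reconcile() on the emitted Newick tree.
genealogy_summary <- function(nodes, species_tree) {
  n <- length(nodes)
  parent <- vapply(nodes, `[[`, 0L, "parent")
  type <- vapply(nodes, `[[`, "", "type")
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  surv <- rep(FALSE, n)
  for (i in rev(seq_len(n))) {  # parents precede children in creation order
    surv[i] <- type[i] == "leaf" || any(surv[children[[i]]])
  }
  surv_kids <- function(i) children[[i]][surv[children[[i]]]]
  root <- which(type == "root")
  if (length(root) == 0L || !surv[root]) {
    return(list(tree = NULL, newick = NULL,
                observable = list(duplications = 0L, losses = 0L)))
  }
  # walk down the single-survivor chain to the pruned root
  cur <- root
  repeat {
    sk <- surv_kids(cur)
    if (length(sk) >= 2L || type[cur] == "leaf") break
    cur <- sk
  }
  pruned_root <- cur
  sidx <- species_index(species_tree)
  sp_of <- function(lab) match(lab, species_tree$tip.label)
  dups <- 0L; losses <- 0L
  # returns list(newick, image); counts events via <<-
  build <- function(i) {
    if (type[i] == "leaf") {
      return(list(nwk = paste0(nodes[[i]]$species, "|", nodes[[i]]$gene),
                  image = sp_of(nodes[[i]]$species)))
    }
    sk <- surv_kids(i)
    if (length(sk) == 1L) return(build(sk))
    parts <- lapply(sk, build)
    image <- parts[[1]]$image
    for (p in parts[-1]) image <- species_lca(image, p$image, sidx)
    isdup <- any(vapply(parts, function(p) p$image == image, TRUE))
    if (isdup) dups <<- dups + 1L
    for (p in parts) {
      d <- sidx$depth[p$image] - sidx$depth[image]
      losses <<- losses + max(0L, d - (if (isdup) 0L else 1L))
    }
    list(nwk = paste0("(", paste(vapply(parts, `[[`, "", "nwk"),
                                 collapse = ","), ")"),
         image = image)
  }
  res <- build(pruned_root)
  nwk <- paste0(res$nwk, ";")
  tr <- if (type[pruned_root] != "leaf") ape::read.tree(text = nwk) else NULL
  list(tree = tr, newick = nwk,
       observable = list(duplications = dups, losses = losses))
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: seed", x$config$seed, "-",
      length(x$genomes), "species with genes,",
      nrow(x$ledger), "events,",
      x$observable$duplications, "observable duplication(s),",
      x$observable$losses, "observable loss(es)\n")
  invisible(x)
}

#' Gene ids of retrotransposition origin in a simulation ledger
#'
#' A gene is of retro origin when its creation chain includes a
#' retrotransposition: the direct product of such an event, or a tandem
#' duplicate of a retro-origin gene (retrogenes do duplicate further, as
#' observed for primate GNA- retrocopies).
#'
#' @param ledger simulation ledger data.frame.
#' @return character vector of gene ids.
#' @export
retro_origin_gene_ids <- function(ledger) {
  retro <- unique(ledger$child_gene[ledger$event == "retrotransposition"])
  dups <- ledger[ledger$event == "tandem_duplication", , drop = FALSE]
  repeat {
    more <- dups$child_gene[dups$parent_gene %in% retro &
                              !(dups$child_gene %in% retro)]
    if (length(more) == 0L) break
    retro <- c(retro, more)
  }
  retro
}

#' Presence/absence (copy count) matrix of a simulation
#' @param sim a `sim_result`.
#' @return integer matrix 1 x species of surviving copy counts.
#' @export
sim_presence_matrix <- function(sim) {
  sp <- sim$species_tree$tip.label
  counts <- vapply(sp, function(s) length(sim$genes[[s]] %||% list()), 0L)
  matrix(counts, nrow = 1, dimnames = list("simfam", sp))
}

#' Write simulation outputs to disk
#'
#' Emits one FASTA + GFF3 per species, the species and true gene trees as
#' Newick, and the event ledger as TSV. Output bytes are a pure function of
#' the configuration.
#'
#' @param sim a `sim_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    write_fasta(unclass(sim$genomes[[sp]]),
                file.path(dir, paste0(sp, ".fa")))
    write_gene_models_gff3(sim$models[[sp]],
                           file.path(dir, paste0(sp, ".gff3")))
  }
  ape::write.tree(sim$species_tree, file.path(dir, "species_tree.nwk"))
  if (!is.null(sim$gene_tree_newick)) {
    writeLines(sim$gene_tree_newick, file.path(dir, "gene_tree.nwk"))
  }
  utils::write.table(sim$ledger, file.path(dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("seed\t", sim$config$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
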