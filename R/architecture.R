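# Exon-border architecture comparison: projection of borders onto protein
# alignments, shared-border/split-codon counting between paralogs,
# retrotransposition-origin classification, and parsimony polarization of
# border characters on a species tree.

#' Project exon borders onto a protein alignment
#'
#' A border at CDS offset `o` maps to the residue whose codon it interrupts
#' (`floor(o/3)`, 0-based) when its phase is nonzero (a split codon), and
#' to the first residue fully downstream (`o/3`) when the phase is zero.
#' The residue index is then mapped to its alignment column, skipping gap
#' columns of that row.
#'
#' @param arch an `exon_architecture` (see [derive_architecture()]).
#' @param msa a [protein_msa()].
#' @param gene_id row of the MSA to project onto; defaults to
#'   `arch$gene_id`.
#' @return data.frame with columns `gene_id`, `column` (0-based alignment
#'   column), `phase`.
#' @export
project_borders <- function(arch, msa, gene_id = NULL) {
  gene_id <- gene_id %||% arch$gene_id
  if (!gene_id %in% names(msa)) stop("gene ", gene_id, " not in MSA")
  row <- msa[[gene_id]]
  chars <- strsplit(row, "")[[1]]
  resid_cols <- which(chars != "-") - 1L   # 0-based columns of residues
  nres <- length(resid_cols)
  if (!(nres * 3L) %in% c(arch$total_length, arch$total_length - 3L)) {
    stop("ungapped length of ", gene_id, " (", nres,
         " aa) inconsistent with CDS length ", arch$total_length)
  }
  if (nrow(arch$borders) == 0L) {
    return(data.frame(gene_id = character(0), column = integer(0),
                      phase = integer(0)))
  }
  # phase != 0: the residue whose codon is split is floor(o/3); phase 0:
  # the first residue fully downstream is o/3 -- both reduce to o %/% 3
  res_idx <- arch$borders$offset %/% 3L
  if (any(res_idx >= nres)) {
    stop("border beyond protein length for ", gene_id)
  }
  data.frame(gene_id = gene_id,
             column = resid_cols[res_idx + 1L],
             phase = arch$borders$phase)
}

match_borders <- function(a, b, slack) {
  # greedy nearest-column matching within identical phase, leftmost on tie;
  # each border matches at most once
  used_b <- rep(FALSE, nrow(b))
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    cand <- which(!used_b & b$phase == a$phase[i] &
                    abs(b$column - a$column[i]) <= slack)
    if (length(cand) == 0L) next
    d <- abs(b$column[cand] - a$column[i])
    j <- cand[order(d, b$column[cand])][1]
    used_b[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  pairs
}

#' Count shared exon borders and split codons between aligned genes
#'
#' Two borders of different genes match when they fall within `slack`
#' alignment columns of each other and carry the same phase; a matched pair
#' with nonzero phase is a shared split codon. Matching is greedy nearest
#' column, leftmost on ties, one-to-one.
#'
#' @param projections list of per-gene projection data.frames from
#'   [project_borders()], all against the same MSA.
#' @param slack column tolerance (default 0).
#' @return a `shared_border_report`: symmetric matrices `shared` and
#'   `shared_split`, plus `group_intersection` (count of borders shared by
#'   all genes) and `slack`.
#' @export
count_shared_borders <- function(projections, slack = 0L) {
  if (length(projections) < 2L) stop("need projections for >= 2 genes")
  ids <- vapply(projections, function(p) {
    if (nrow(p)) p$gene_id[1] else NA_character_
  }, "")
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  k <- length(projections)
  shared <- matrix(0L, k, k, dimnames = list(ids, ids))
  split <- shared
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pairs <- match_borders(projections[[i]], projections[[j]], slack)
      shared[i, j] <- shared[j, i] <- length(pairs)
      nsplit <- sum(vapply(pairs, function(p) {
        projections[[i]]$phase[p[1]] != 0L
      }, TRUE))
      split[i, j] <- split[j, i] <- nsplit
    }
  }
  # group intersection: borders of gene 1 matched in every other gene
  inter <- 0L
  p1 <- projections[[1]]
  for (i in seq_len(nrow(p1))) {
    hit_all <- all(vapply(projections[-1], function(q) {
      any(q$phase == p1$phase[i] & abs(q$column - p1$column[i]) <= slack)
    }, TRUE))
    if (hit_all) inter <- inter + 1L
  }
  structure(list(shared = shared, shared_split = split,
                 group_intersection = inter, slack = slack),
            class = "shared_border_report")
}

#' @export
print.shared_border_report <- function(x, ...) {
  cat("shared borders (slack", x$slack, "):\n")
  print(x$shared)
  cat("shared split codons:\n")
  print(x$shared_split)
  cat("borders shared by all:", x$group_intersection, "\n")
  invisible(x)
}

arch_shared_count <- function(a, b, slack_nt = 0L) {
  # architecture-level (CDS offset) border matching, used when no MSA is
  # available (e.g. undiverged simulated paralogs)
  pa <- a$borders; pb <- b$borders
  used <- rep(FALSE, nrow(pb))
  n <- 0L
  for (i in seq_len(nrow(pa))) {
    cand <- which(!used & pb$phase == pa$phase[i] &
                    abs(pb$offset - pa$offset[i]) <= slack_nt)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

#' Classify whether a gene's architecture indicates a retrotransposition origin
#'
#' A paralog that shares no exon borders or split codons with any family
#' member and carries fewer introns than the family median is a
#' retrotransposition candidate (the GNA12-type signature: an intron-free
#' reinsertion that may later regain introns at novel positions). A gene
#' sharing at least half of the family-consensus borders is classified
#' vertical; anything else is ambiguous.
#'
#' @param candidate an `exon_architecture`.
#' @param family list of `exon_architecture` of the reference family
#'   members (excluding the candidate).
#' @param min_shared borders-with-every-member threshold below which the
#'   candidate counts as border-sharing-free (default 1).
#' @param slack_nt CDS-offset tolerance in nt for border matching.
#' @return list with `class` in `c("vertical", "retro_candidate",
#'   "ambiguous")` and the supporting counts.
#' @export
classify_retro_origin <- function(candidate, family, min_shared = 1L,
                                  slack_nt = 0L) {
  if (length(family) == 0L) stop("empty family")
  shared <- vapply(family, function(f) {
    arch_shared_count(candidate, f, slack_nt)
  }, 0L)
  fam_introns <- vapply(family, function(f) nrow(f$borders), 0L)
  cand_introns <- nrow(candidate$borders)
  # family consensus: borders present in every family member
  consensus <- 0L
  f1 <- family[[1]]
  for (i in seq_len(nrow(f1$borders))) {
    if (all(vapply(family[-1], function(f) {
      any(f$borders$phase == f1$borders$phase[i] &
            abs(f$borders$offset - f1$borders$offset[i]) <= slack_nt)
    }, TRUE))) consensus <- consensus + 1L
  }
  cand_vs_consensus <- arch_shared_count(candidate, f1, slack_nt)
  cls <- if (all(shared < min_shared) &&
             cand_introns < stats::median(fam_introns)) {
    "retro_candidate"
  } else if (consensus > 0L && cand_vs_consensus >= consensus / 2) {
    "vertical"
  } else if (consensus == 0L && any(shared >= min_shared)) {
    "vertical"
  } else {
    "ambiguous"
  }
  list(class = cls, shared_per_member = shared,
       candidate_introns = cand_introns,
       family_median_introns = stats::median(fam_introns),
       consensus_borders = consensus)
}

#' Polarize presence/absence characters on a species tree by parsimony
#'
#' Sankoff parsimony with configurable gain:loss costs (default 1:1, which
#' on binary characters equals Fitch parsimony). Unknown states are
#' unconstrained. All co-optimal scenarios are enumerated and reported; a
#' character is flagged ambiguous when more than one distinct optimal
#' event scenario exists. A Dollo mode (single gain at the LCA of the
#' present taxa, losses below) is available.
#'
#' @param presence named character/integer vector per taxon: `"present"`
#'   (or 1), `"absent"` (or 0), `"unknown"` (or NA).
#' @param species_tree rooted `phylo` or Newick string.
#' @param gain_cost,loss_cost Sankoff step costs.
#' @param mode `"sankoff"` or `"dollo"`.
#' @return list with `cost` (minimum change count), `scenarios` (list of
#'   data.frames of edge events: `branch` = label of the child node of the
#'   edge, `event` = gain/loss), and `ambiguous`.
#' @export
polarize_border_characters <- function(presence, species_tree,
                                       gain_cost = 1, loss_cost = 1,
                                       mode = c("sankoff", "dollo")) {
  mode <- match.arg(mode)
  if (is.character(species_tree)) {
    species_tree <- ape::read.tree(text = species_tree)
  }
  tree <- species_tree
  ntip <- length(tree$tip.label)
  states <- normalize_states(presence)
  if (!all(names(states) %in% tree$tip.label)) {
    stop("taxa not in tree: ",
         paste(setdiff(names(states), tree$tip.label), collapse = ", "))
  }
  if (mode == "dollo") {
    return(polarize_dollo(states, tree))
  }
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nnode)))
  # Sankoff DP: cost[node, state+1], state in {0 absent, 1 present}
  cost <- matrix(Inf, nnode, 2)
  step <- function(from, to) {
    if (from == to) 0 else if (from == 0) gain_cost else loss_cost
  }
  for (tip in seq_len(ntip)) {
    s <- states[tree$tip.label[tip]]
    if (is.na(s)) {
      cost[tip, ] <- c(0, 0)
    } else {
      cost[tip, ] <- if (s == 1) c(Inf, 0) else c(0, Inf)
    }
  }
  for (nd in unique(tree$edge[ape::postorder(tree), 1])) {
    for (st in 0:1) {
      tot <- 0
      for (ch in kids[[nd]]) {
        tot <- tot + min(cost[ch, 1] + step(st, 0), cost[ch, 2] + step(st, 1))
      }
      cost[nd, st + 1] <- tot
    }
  }
  root <- ntip + 1L
  best <- min(cost[root, ])
  node_label <- function(n) {
    if (n <= ntip) tree$tip.label[n] else paste0("n", n)
  }
  # enumerate all optimal labelings by recursive backtracking over the DP
  enumerate_subtree <- function(nd, st) {
    ch_list <- kids[[nd]]
    if (length(ch_list) == 0L) return(list(empty_events()))
    per_child <- lapply(ch_list, function(ch) {
      v <- c(cost[ch, 1] + step(st, 0), cost[ch, 2] + step(st, 1))
      opt_states <- which(v == min(v)) - 1L
      out <- list()
      for (cst in opt_states) {
        edge_ev <- if (cst != st) {
          data.frame(branch = node_label(ch),
                     event = if (cst == 1) "gain" else "loss",
                     stringsAsFactors = FALSE)
        } else empty_events()
        subs <- if (ch <= ntip) list(empty_events()) else enumerate_subtree(ch, cst)
        for (s_ev in subs) out[[length(out) + 1L]] <- rbind(edge_ev, s_ev)
      }
      out
    })
    combos <- list(empty_events())
    for (pc in per_child) {
      combos <- unlist(lapply(combos, function(acc) {
        lapply(pc, function(ev) rbind(acc, ev))
      }), recursive = FALSE)
    }
    combos
  }
  root_states <- which(cost[root, ] == best) - 1L
  all_scen <- list()
  for (rs in root_states) {
    all_scen <- c(all_scen, enumerate_subtree(root, rs))
  }
  keys <- vapply(all_scen, function(ev) {
    if (nrow(ev) == 0L) return("")
    paste(sort(paste(ev$branch, ev$event)), collapse = ";")
  }, "")
  all_scen <- all_scen[!duplicated(keys)]
  list(cost = best, scenarios = all_scen, ambiguous = length(all_scen) > 1L,
       mode = "sankoff")
}

empty_events <- function() {
  data.frame(branch = character(0), event = character(0),
             stringsAsFactors = FALSE)
}

normalize_states <- function(presence) {
  if (is.numeric(presence)) {
    out <- ifelse(is.na(presence), NA_integer_, as.integer(presence > 0))
  } else {
    out <- ifelse(presence %in% c("present", "1"), 1L,
                  ifelse(presence %in% c("absent", "0"), 0L, NA_integer_))
  }
  stats::setNames(out, names(presence))
}

polarize_dollo <- function(states, tree) {
  ntip <- length(tree$tip.label)
  present <- names(states)[!is.na(states) & states == 1L]
  node_label <- function(n) {
    if (n <= ntip) tree$tip.label[n] else paste0("n", n)
  }
  if (length(present) == 0L) {
    return(list(cost = 0, scenarios = list(empty_events()),
                ambiguous = FALSE, mode = "dollo", gain_node = NA))
  }
  tips <- match(present, tree$tip.label)
  gain <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
  # minimal loss edges below the gain node
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1],
                                       levels = seq_len(ntip + tree$Nnode)))
  status <- function(nd) {
    if (nd <= ntip) {
      s <- states[tree$tip.label[nd]]
      if (is.na(s)) return("unknown")
      return(if (s == 1L) "present" else "absent")
    }
    st <- vapply(kids[[nd]], status, "")
    if (any(st == "present")) "present"
    else if (any(st == "absent")) "absent"
    else "unknown"
  }
  losses <- empty_events()
  walk <- function(nd) {
    if (nd <= ntip) return(invisible(NULL))
    for (ch in kids[[nd]]) {
      st <- status(ch)
      if (st == "absent") {
        losses <<- rbind(losses, data.frame(branch = node_label(ch),
                                            event = "loss",
                                            stringsAsFactors = FALSE))
      } else if (st == "present") {
        walk(ch)
      }
    }
  }
  walk(gain)
  events <- rbind(data.frame(branch = node_label(gain), event = "gain",
                             stringsAsFactors = FALSE), losses)
  list(cost = 1 + nrow(losses), scenarios = list(events), ambiguous = FALSE,
       mode = "dollo", gain_node = node_label(gain))
}
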