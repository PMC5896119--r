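# Gene-tree / species-tree reconciliation: LCA mapping with duplication
# and loss counting, support-based weak-edge collapse, minimum-cost
# polytomy resolution, and Dollo gain/loss mapping of presence/absence
# matrices.

species_index <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nnode <- ntip + species_tree$Nnode
  parent <- integer(nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  depth <- integer(nnode)
  root <- ntip + 1L
  for (n in seq_len(nnode)) {
    d <- 0L; cur <- n
    while (cur != root) { cur <- parent[cur]; d <- d + 1L }
    depth[n] <- d
  }
  list(ntip = ntip, parent = parent, depth = depth, root = root)
}

species_lca <- function(a, b, idx) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b]
    else if (idx$depth[b] < idx$depth[a]) a <- idx$parent[a]
    else { a <- idx$parent[a]; b <- idx$parent[b] }
  }
  a
}

#' Split a gene-tree leaf label into its species component
#' @param labels character vector of `species<sep>gene` labels.
#' @param sep separator (default `"|"`).
#' @return character vector of species ids.
#' @export
leaf_species <- function(labels, sep = "|") {
  vapply(strsplit(labels, sep, fixed = TRUE), `[[`, "", 1L)
}

#' Reconcile a gene tree with a species tree by LCA mapping
#'
#' Each gene-tree node is mapped to the lowest common ancestor of its
#' descendant species. A node is a duplication when it maps to the same
#' species node as at least one child. Losses on the edge above a node
#' equal the species-tree path length from the node's image to its
#' parent's image, minus one unless the parent is a duplication, floored
#' at zero.
#'
#' @param gene_tree rooted `phylo` (or Newick string); leaf labels
#'   `species<sep>gene`. Multifurcating nodes are accepted (used while
#'   scoring partial resolutions).
#' @param species_tree rooted `phylo` or Newick string.
#' @param sep species/gene separator in gene-tree leaf labels.
#' @return a `reconciliation` list: `duplications`, `losses`, `node_map`
#'   (species node image per gene-tree node), `is_duplication`,
#'   `edge_losses` (per gene-tree edge), `cost` (duplications + losses).
#' @export
lca_reconcile <- function(gene_tree, species_tree, sep = "|") {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  idx <- species_index(species_tree)
  gntip <- length(gene_tree$tip.label)
  if (gntip < 2L) {
    return(structure(list(duplications = 0L, losses = 0L, cost = 0L,
                          node_map = NULL, is_duplication = NULL,
                          edge_losses = NULL),
                     class = "reconciliation"))
  }
  if (!ape::is.rooted(gene_tree)) stop("gene tree must be rooted")
  sp <- leaf_species(gene_tree$tip.label, sep)
  sp_idx <- match(sp, species_tree$tip.label)
  if (anyNA(sp_idx)) {
    stop("species not in species tree: ",
         paste(unique(sp[is.na(sp_idx)]), collapse = ", "))
  }
  gnnode <- gntip + gene_tree$Nnode
  kids <- split(gene_tree$edge[, 2],
                factor(gene_tree$edge[, 1], levels = seq_len(gnnode)))
  map <- integer(gnnode)
  map[seq_len(gntip)] <- sp_idx
  for (nd in unique(gene_tree$edge[ape::postorder(gene_tree), 1])) {
    ch <- kids[[nd]]
    m <- map[ch[1]]
    for (c2 in ch[-1]) m <- species_lca(m, map[c2], idx)
    map[nd] <- m
  }
  isdup <- rep(FALSE, gnnode)
  for (nd in (gntip + 1L):gnnode) {
    isdup[nd] <- any(map[kids[[nd]]] == map[nd])
  }
  edge_losses <- integer(nrow(gene_tree$edge))
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]; v <- gene_tree$edge[i, 2]
    d <- idx$depth[map[v]] - idx$depth[map[u]]
    edge_losses[i] <- max(0L, d - (if (isdup[u]) 0L else 1L))
  }
  dups <- sum(isdup)
  losses <- sum(edge_losses)
  structure(list(duplications = as.integer(dups),
                 losses = as.integer(losses),
                 cost = as.integer(dups + losses),
                 node_map = map, is_duplication = isdup,
                 edge_losses = edge_losses, gene_tree = gene_tree,
                 species_tree = species_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", x$duplications, "duplication(s),",
      x$losses, "loss(es)\n")
  invisible(x)
}

# recursive list form of a rooted tree: either a leaf label (character) or
# list(children = list(...), support = numeric or NA)
phylo_to_rlist <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  kids <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(nnode)))
  supports <- phy$node.label
  build <- function(nd) {
    if (nd <= ntip) return(phy$tip.label[nd])
    sup <- NA_real_
    if (!is.null(supports)) {
      s <- supports[nd - ntip]
      if (!is.na(s) && nzchar(s)) sup <- suppressWarnings(as.numeric(s))
    }
    list(children = lapply(kids[[nd]], build), support = sup)
  }
  build(ntip + 1L)
}

rlist_to_newick <- function(node) {
  if (is.character(node)) return(node)
  inner <- paste(vapply(node$children, rlist_to_newick, ""), collapse = ",")
  sup <- if (!is.null(node$support) && !is.na(node$support)) node$support else ""
  paste0("(", inner, ")", sup)
}

rlist_to_phylo <- function(node) {
  ape::read.tree(text = paste0(rlist_to_newick(node), ";"))
}

#' Collapse weakly supported gene-tree edges
#'
#' Contracts every internal (non-root) edge whose child-node support is
#' below the threshold, producing a multifurcating tree. Supports are read
#' from the tree's internal node labels.
#'
#' @param gene_tree rooted `phylo` (or Newick) with numeric internal node
#'   labels as supports (0-100).
#' @param support_threshold collapse edges with support strictly below
#'   this (default 90); `NA` disables collapsing.
#' @return a `phylo`, possibly multifurcating.
#' @export
collapse_weak_edges <- function(gene_tree, support_threshold = 90) {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  if (is.na(support_threshold)) return(gene_tree)
  if (is.null(gene_tree$node.label)) {
    stop("gene tree carries no support values; pass support_threshold = NA ",
         "to disable collapsing")
  }
  r <- phylo_to_rlist(gene_tree)
  contract <- function(node, is_root) {
    if (is.character(node)) return(node)
    node$children <- lapply(node$children, contract, is_root = FALSE)
    newkids <- list()
    for (ch in node$children) {
      if (!is.character(ch) && !is.na(ch$support) &&
          ch$support < support_threshold) {
        newkids <- c(newkids, ch$children)
      } else {
        newkids <- c(newkids, list(ch))
      }
    }
    node$children <- newkids
    node
  }
  rlist_to_phylo(contract(r, TRUE))
}

# all rooted binary shapes over a list of items (each item is an rlist
# subtree, kept intact); returns list of rlist nodes. |shapes(k)| = (2k-3)!!
binary_shapes <- function(items) {
  k <- length(items)
  # enumerate shapes over atoms 1..k so insertion never descends into an
  # item's own internal structure
  insert_everywhere <- function(shape, x) {
    res <- list(list(idx_children = list(x, shape)))
    if (is.list(shape)) {
      for (i in seq_along(shape$idx_children)) {
        for (sub in insert_everywhere(shape$idx_children[[i]], x)) {
          s2 <- shape
          s2$idx_children[[i]] <- sub
          res <- c(res, list(s2))
        }
      }
    }
    res
  }
  shapes <- list(1L)
  for (x in seq_len(k)[-1]) {
    shapes <- unlist(lapply(shapes, insert_everywhere, x = x),
                     recursive = FALSE)
  }
  substitute_items <- function(shape) {
    if (!is.list(shape)) return(items[[shape]])
    list(children = lapply(shape$idx_children, substitute_items),
         support = NA_real_)
  }
  lapply(shapes, substitute_items)
}

#' Resolve gene-tree polytomies minimizing duplications + losses
#'
#' Polytomies are processed in postorder. A polytomy of degree at most
#' `max_exhaustive` is replaced by the best of all rooted binary
#' arrangements of its child subtrees (exhaustive search, first optimum in
#' a fixed enumeration order on ties); larger polytomies are resolved by
#' greedily cherry-joining the pair of children giving the smallest
#' reconciliation cost.
#'
#' @param gene_tree rooted `phylo` (or Newick), possibly multifurcating;
#'   leaf labels `species<sep>gene`.
#' @param species_tree rooted `phylo` or Newick.
#' @param sep leaf-label separator.
#' @param max_exhaustive largest polytomy degree solved exhaustively
#'   (default 6).
#' @return list with `tree` (binary `phylo`) and `reconciliation`.
#' @export
resolve_polytomies_min_cost <- function(gene_tree, species_tree, sep = "|",
                                        max_exhaustive = 6L) {
  if (is.character(gene_tree)) gene_tree <- ape::read.tree(text = gene_tree)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  r <- phylo_to_rlist(gene_tree)
  tree_cost <- function(root) {
    lca_reconcile(rlist_to_phylo(root), species_tree, sep)$cost
  }
  resolve <- function(node, get_root) {
    if (is.character(node)) return(node)
    node$children <- lapply(seq_along(node$children), function(i) {
      resolve(node$children[[i]], function(sub) {
        n2 <- node
        n2$children[[i]] <- sub
        get_root(n2)
      })
    })
    k <- length(node$children)
    if (k <= 2L) return(node)
    if (k <= max_exhaustive) {
      cands <- binary_shapes(node$children)
      costs <- vapply(cands, function(cand) {
        tree_cost(get_root(cand))
      }, 0)
      return(cands[[which.min(costs)]])
    }
    # greedy cherry joining for large polytomies
    while (length(node$children) > 2L) {
      kk <- length(node$children)
      best <- NULL; best_cost <- Inf
      for (i in seq_len(kk - 1L)) {
        for (j in (i + 1L):kk) {
          n2 <- node
          cherry <- list(children = list(node$children[[i]],
                                         node$children[[j]]),
                         support = NA_real_)
          n2$children <- c(n2$children[-c(i, j)], list(cherry))
          cst <- tree_cost(get_root(n2))
          if (cst < best_cost) { best_cost <- cst; best <- n2 }
        }
      }
      node <- best
    }
    node
  }
  resolved <- resolve(r, function(x) x)
  tr <- rlist_to_phylo(resolved)
  list(tree = tr, reconciliation = lca_reconcile(tr, species_tree, sep))
}

#' Dollo gain/loss mapping of a presence/absence matrix
#'
#' For each family, the gain is placed at the LCA of all species with at
#' least one copy; losses are the minimal set of species-tree edges
#' explaining the absences below the gain (Dollo parsimony). Unknown
#' entries (`NA`) are unconstrained.
#'
#' @param matrix numeric matrix, families x species; `NA` = unknown.
#' @param species_tree rooted `phylo` or Newick string.
#' @return named list per family: `gain` (node label, `NA` if the family
#'   is absent everywhere), `losses` (character vector of child-node
#'   labels of loss edges), `n_losses`.
#' @export
dollo_gainloss <- function(matrix, species_tree) {
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  if (!all(colnames(matrix) %in% species_tree$tip.label)) {
    stop("species not in tree: ",
         paste(setdiff(colnames(matrix), species_tree$tip.label),
               collapse = ", "))
  }
  out <- list()
  for (fam in rownames(matrix)) {
    counts <- matrix[fam, ]
    states <- ifelse(is.na(counts), NA_integer_, as.integer(counts >= 1))
    names(states) <- colnames(matrix)
    if (!any(states == 1L, na.rm = TRUE)) {
      warning("family ", fam, " absent everywhere; no events")
      out[[fam]] <- list(gain = NA_character_, losses = character(0),
                         n_losses = 0L)
      next
    }
    res <- polarize_dollo(states, species_tree)
    ev <- res$scenarios[[1]]
    out[[fam]] <- list(gain = res$gain_node,
                       losses = ev$branch[ev$event == "loss"],
                       n_losses = sum(ev$event == "loss"))
  }
  out
}
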