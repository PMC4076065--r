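# LCA gene-tree/species-tree reconciliation: duplication labelling and
# ancestral-gene counts at named species-tree nodes.

# per-node ancestor bookkeeping for a rooted tree
node_ancestry <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n + 1L
  depth <- integer(nn)
  anc <- vector("list", nn)
  # BFS from the root fills depths and ancestor lists
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) {
      depth[k] <- depth[v] + 1L
      anc[[k]] <- c(anc[[v]], v)
      queue <- c(queue, k)
    }
  }
  list(parent = parent, depth = depth, anc = anc, root = root, n_tip = n)
}

# lowest common ancestor of two nodes given ancestry bookkeeping
lca_nodes <- function(a, b, ancestry) {
  if (a == b) return(a)
  pa <- c(ancestry$anc[[a]], a)
  pb <- c(ancestry$anc[[b]], b)
  common <- intersect(pa, pb)
  common[which.max(ancestry$depth[common])]
}

#' Root an unrooted tree with an outgroup
#'
#' Places the root on the edge separating the outgroup leaves from the rest,
#' at the midpoint of that edge's length.
#'
#' @param tree An `ape::phylo` (rooted input is unrooted first).
#' @param outgroup Character vector of outgroup leaf labels.
#' @return A rooted `ape::phylo`.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  missing_tips <- setdiff(outgroup, tree$tip.label)
  if (length(missing_tips)) {
    abort(sprintf("outgroup leaves not in tree: %s", paste(missing_tips, collapse = ", ")))
  }
  if (length(outgroup) >= length(tree$tip.label)) abort("outgroup cannot cover all leaves")
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ok <- ape::is.monophyletic(un, outgroup) ||
    ape::is.monophyletic(un, setdiff(un$tip.label, outgroup))
  if (!ok) {
    abort(sprintf("outgroup is not monophyletic in the unrooted tree: %s",
                  paste(outgroup, collapse = ", ")))
  }
  rooted <- ape::root(un, outgroup = outgroup, resolve.root = TRUE)
  # split the stem edge length evenly across the two root children
  if (!is.null(rooted$edge.length)) {
    n <- length(rooted$tip.label)
    root_edges <- which(rooted$edge[, 1] == n + 1L)
    if (length(root_edges) == 2L) {
      tot <- sum(rooted$edge.length[root_edges])
      rooted$edge.length[root_edges] <- tot / 2
    }
  }
  rooted
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the most recent species-tree node that could
#' have contained it (the LCA mapping) and labels internal nodes as
#' `duplication` when the node maps to the same species node as one of its
#' children, `speciation` otherwise.
#'
#' @param gene_tree Rooted, binary `ape::phylo` of gene copies.
#' @param species_tree Rooted `ape::phylo`; internal nodes may carry labels
#'   (used to name MRCAs in reports).
#' @param species_map Tibble with columns `gene_id`, `species_id` assigning
#'   each gene-tree leaf to a species-tree leaf.
#' @return An object of class `reconciled_tree`: the trees plus per-node
#'   species mapping and event labels.
#' @examples
#' sp <- ape::read.tree(text = "(A:1,B:1)R;")
#' gt <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
#' map <- tibble::tibble(gene_id = c("a1", "b1", "a2", "b2"),
#'                       species_id = c("A", "B", "A", "B"))
#' rec <- lca_reconcile(gt, sp, map)
#' tidy(rec)
#' @export
lca_reconcile <- function(gene_tree, species_tree, species_map) {
  if (!ape::is.rooted(gene_tree)) abort("gene tree must be rooted; use root_by_outgroup() first")
  if (!ape::is.binary(gene_tree)) {
    abort("gene tree has polytomies; resolve them (e.g. use the uncollapsed tree) before reconciling")
  }
  if (!ape::is.rooted(species_tree)) abort("species tree must be rooted")
  sm <- as_tibble(species_map)
  if (!all(c("gene_id", "species_id") %in% names(sm))) {
    abort("species_map needs columns gene_id, species_id")
  }
  sp_of <- setNames(sm$species_id, sm$gene_id)
  missing_genes <- setdiff(gene_tree$tip.label, names(sp_of))
  if (length(missing_genes)) abort(sprintf("no species for gene(s): %s", paste(missing_genes, collapse = ", ")))
  unknown <- setdiff(unique(sp_of[gene_tree$tip.label]), species_tree$tip.label)
  if (length(unknown)) abort(sprintf("unknown species_id: %s", paste(unknown, collapse = ", ")))

  g_anc <- node_ancestry(gene_tree)
  s_anc <- node_ancestry(species_tree)
  n_g <- length(gene_tree$tip.label)
  nn_g <- n_g + gene_tree$Nnode
  M <- integer(nn_g)
  event <- character(nn_g)
  sp_tip_id <- setNames(seq_along(species_tree$tip.label), species_tree$tip.label)
  M[seq_len(n_g)] <- sp_tip_id[sp_of[gene_tree$tip.label]]
  event[seq_len(n_g)] <- "leaf"

  # deepest internal nodes first, so children are mapped before parents
  ord <- order(g_anc$depth[(n_g + 1L):nn_g], decreasing = TRUE) + n_g
  for (v in ord) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    mv <- Reduce(function(a, b) lca_nodes(a, b, s_anc), M[kids])
    M[v] <- mv
    event[v] <- if (any(M[kids] == mv)) "duplication" else "speciation"
  }

  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 species_map = sm, M = M, event = event,
                 species_ancestry = s_anc, gene_ancestry = g_anc),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat(sprintf("<reconciled_tree> %d gene copies on %d species; %d duplication node(s)\n",
              length(x$gene_tree$tip.label), length(x$species_tree$tip.label),
              sum(x$event == "duplication")))
  invisible(x)
}

#' Tidy a reconciled tree
#'
#' @param x A `reconciled_tree`.
#' @param ... Unused.
#' @return A tibble with one row per gene-tree node: node id, mapped species
#'   node (label where available) and event.
#' @export
tidy.reconciled_tree <- function(x, ...) {
  node_name <- species_node_names(x$species_tree)
  tibble(node = seq_along(x$M),
         label = c(x$gene_tree$tip.label, rep(NA_character_, x$gene_tree$Nnode)),
         species_node = node_name[x$M],
         event = x$event)
}

# display names for species-tree nodes: tip labels, then internal labels or
# "mrca_<k>" placeholders
species_node_names <- function(species_tree) {
  n <- length(species_tree$tip.label)
  internal <- species_tree$node.label
  if (is.null(internal) || !length(internal)) internal <- rep("", species_tree$Nnode)
  internal[!nzchar(internal)] <- paste0("mrca_", which(!nzchar(internal)))
  c(species_tree$tip.label, internal)
}

# resolve a species-tree node given a label or node number
resolve_species_node <- function(species_tree, node) {
  if (is.numeric(node)) return(as.integer(node))
  nm <- species_node_names(species_tree)
  hit <- which(nm == node)
  if (length(hit) != 1L) abort(sprintf("cannot resolve species-tree node '%s'", node))
  hit
}

#' Ancestral gene count at a species-tree node
#'
#' Number of distinct gene lineages present in the most recent common ancestor
#' represented by species-tree node `node`, inferred from the LCA
#' reconciliation: a gene-tree node is counted when its mapping lies at or
#' below `node`, it is not itself a duplication mapped exactly to `node`
#' (such a duplication splits one ancestral gene in place, so its children are
#' counted instead), and its parent lineage originates above `node` (or at
#' `node` via a duplication).
#'
#' @param rec A `reconciled_tree` from [lca_reconcile()].
#' @param node Species-tree internal node (label or node number).
#' @return Integer count of ancestral genes.
#' @export
ancestral_gene_count <- function(rec, node) {
  s <- resolve_species_node(rec$species_tree, node)
  n_sp_tip <- length(rec$species_tree$tip.label)
  if (s <= n_sp_tip) abort("ancestral gene counts are defined at internal species-tree nodes")
  s_anc <- rec$species_ancestry
  is_desc_or_equal <- function(x, y) x == y || y %in% s_anc$anc[[x]]
  is_proper_anc <- function(x, y) x %in% s_anc$anc[[y]]

  g <- rec$gene_tree
  n_g <- length(g$tip.label)
  parent <- integer(n_g + g$Nnode)
  parent[g$edge[, 2]] <- g$edge[, 1]
  root <- n_g + 1L

  count <- 0L
  for (v in seq_along(rec$M)) {
    mv <- rec$M[v]
    if (!is_desc_or_equal(mv, s)) next
    if (rec$event[v] == "duplication" && mv == s) next
    if (v == root) { count <- count + 1L; next }
    mp <- rec$M[parent[v]]
    if (is_proper_anc(mp, s) ||
        (mp == s && rec$event[parent[v]] == "duplication")) {
      count <- count + 1L
    }
  }
  count
}

#' Ancestral gene counts at every internal species-tree node
#'
#' @param rec A `reconciled_tree`.
#' @return A tibble: `species_node`, `ancestral_count`.
#' @export
ancestral_gene_counts <- function(rec) {
  st <- rec$species_tree
  n <- length(st$tip.label)
  nodes <- (n + 1L):(n + st$Nnode)
  nm <- species_node_names(st)
  tibble(species_node = nm[nodes],
         ancestral_count = vapply(nodes, function(s) ancestral_gene_count(rec, s), integer(1)))
}
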