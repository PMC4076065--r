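# Distance-based gene-family trees: Saitou-Nei neighbor joining on K2P
# distances, nonparametric bootstrap supports, and low-support collapsing.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q-matrix are broken by the lexicographically smallest label pair (a cluster
#' carries the smallest leaf label it contains), making the output fully
#' deterministic. Negative estimated branch lengths are set to zero. The
#' result is unrooted (stored with a basal trifurcation).
#'
#' @param d Symmetric distance matrix with row/column names (>= 3 labels).
#' @return An `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  labels <- rownames(d)
  if (is.null(labels)) abort("d must carry row names")
  n <- nrow(d)
  if (n < 3L) abort("neighbor joining needs at least 3 labels")
  if (max(abs(d - t(d))) > 1e-9) abort("d must be symmetric")
  if (any(diag(d) != 0)) abort("d must have a zero diagonal")
  if (any(d < 0)) abort("d must be non-negative")

  # active clusters: phylo node ids (tips 1..n, internals n+1..), tie-break
  # label = smallest leaf label in the cluster
  records <- vector("list", n - 2L)   # internal node children, filled as built
  next_internal <- 1L
  ids <- seq_len(n)
  labs <- labels
  D <- unname(d)

  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(labs[cand[, 1]], labs[cand[, 2]])
    key2 <- pmax(labs[cand[, 1]], labs[cand[, 2]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)

    records[[next_internal]] <- list(children = c(ids[i], ids[j]),
                                     lengths = c(li, lj))
    new_id <- n + next_internal
    next_internal <- next_internal + 1L

    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labs <- c(labs[keep], min(labs[c(i, j)]))
    ids <- c(ids[keep], new_id)
  }

  # terminal join: basal trifurcation
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  root_rec <- list(children = ids, lengths = c(l1, l2, l3))

  build_phylo(n, labels, records[seq_len(next_internal - 1L)], root_rec)
}

# assemble an ape::phylo from merge records; root_rec holds the basal node
build_phylo <- function(n_tips, tip_labels, records, root_rec) {
  # phylo numbering: tips 1..n, basal node n+1, other internals numbered in
  # preorder from the basal node (id 0 denotes the basal record here)
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  order_stack <- c(0L)
  preorder <- integer(0)
  while (length(order_stack)) {
    id <- order_stack[[length(order_stack)]]
    order_stack <- order_stack[-length(order_stack)]
    preorder <- c(preorder, id)
    rec <- if (id == 0L) root_rec else records[[id - n_tips]]
    kids <- rev(rec$children[rec$children > n_tips])
    order_stack <- c(order_stack, kids)
  }
  ids_map <- setNames(seq(n_tips + 1L, n_tips + length(preorder)), as.character(preorder))
  for (id in preorder) {
    rec <- if (id == 0L) root_rec else records[[id - n_tips]]
    par <- ids_map[[as.character(id)]]
    for (k in seq_along(rec$children)) {
      ch <- rec$children[k]
      ch_new <- if (ch <= n_tips) ch else ids_map[[as.character(ch)]]
      edges <- rbind(edges, c(par, ch_new))
      lens <- c(lens, rec$lengths[k])
    }
  }
  tree <- list(edge = edges, edge.length = lens, tip.label = tip_labels,
               Nnode = length(preorder))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# canonical split keys (tip-index sets, complemented away from tip 1 of
# `labels`) for every internal non-root node of an unrooted tree
tree_splits <- function(tree, labels) {
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, labels)
  pp <- ape::prop.part(tree)
  out <- character(0)
  nodes <- integer(0)
  for (k in seq_along(pp)) {
    node <- n + k
    if (node == n + 1L) next  # basal node: not an internal edge
    tips <- sort(idx[pp[[k]]])
    if (1L %in% tips) tips <- sort(setdiff(seq_len(length(labels)), tips))
    if (length(tips) < 2L || length(tips) > length(labels) - 2L) next
    out <- c(out, paste(tips, collapse = ","))
    nodes <- c(nodes, node)
  }
  list(keys = out, nodes = nodes)
}

#' Bootstrap neighbor-joining tree with K2P distances
#'
#' Builds the NJ tree of the full alignment, then resamples alignment columns
#' with replacement `reps` times; the support of each internal edge is the
#' percentage of replicates whose NJ tree contains the same bipartition.
#' Replicates in which a pairwise K2P distance is saturated (or has no
#' retained sites) are dropped and counted; support denominators use the
#' retained count. Deterministic for a given `seed`.
#'
#' @param seqs Aligned sequences (tibble with `id`, `seq`).
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return An `ape::phylo` with node labels carrying percent supports, plus
#'   attributes `splits` (tibble of bipartition supports), `n_retained`,
#'   `n_dropped`, and `degenerate` (TRUE when all distances are zero, i.e. the
#'   star-tree outcome).
#' @export
bootstrap_nj <- function(seqs, reps = 1000L, seed = 1L) {
  if (reps < 1L) abort("reps must be >= 1")
  m <- seq_matrix(seqs)
  labels <- rownames(m)
  n <- nrow(m)
  d_full <- k2p_matrix(seqs)
  main <- nj_tree(d_full)
  degenerate <- max(d_full) == 0
  if (degenerate) {
    warn("all pairwise distances are zero; bootstrap supports describe a star tree")
  }

  # per-pair column classes: 0 same, 1 transition, 2 transversion, 3 excluded
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  ncol_aln <- ncol(m)
  cls <- matrix(0L, np, ncol_aln)
  is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  for (p in seq_len(np)) {
    x <- m[pairs[1L, p], ]; y <- m[pairs[2L, p], ]
    excl <- x %in% c("-", "N") | y %in% c("-", "N")
    diff <- !excl & x != y
    ts <- diff & is_ts(x, y)
    cls[p, ] <- ifelse(excl, 3L, ifelse(ts, 1L, ifelse(diff, 2L, 0L)))
  }

  set.seed(seed)
  support_count <- new.env(parent = emptyenv())
  retained <- 0L
  dropped <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    counts <- count_pair_classes_cpp(cls, idx - 1L)
    ntot <- rowSums(counts[, 1:3, drop = FALSE])
    if (any(ntot == 0L)) { dropped <- dropped + 1L; next }
    P <- counts[, 2L] / ntot
    Q <- counts[, 3L] / ntot
    if (any(1 - 2 * P - Q <= 0 | 1 - 2 * Q <= 0)) { dropped <- dropped + 1L; next }
    k <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    dmat <- matrix(0, n, n, dimnames = list(labels, labels))
    dmat[t(pairs)] <- k
    dmat <- dmat + t(dmat)
    tr <- nj_tree(dmat)
    for (key in tree_splits(tr, labels)$keys) {
      support_count[[key]] <- (support_count[[key]] %||% 0L) + 1L
    }
    retained <- retained + 1L
  }
  if (retained == 0L) abort("all bootstrap replicates were dropped (saturated distances)")
  if (dropped > 0L) {
    warn(sprintf("%d of %d bootstrap replicates dropped (unestimable distances)", dropped, reps))
  }

  sp <- tree_splits(main, labels)
  supp <- vapply(sp$keys, function(k) 100 * (support_count[[k]] %||% 0L) / retained,
                 numeric(1))
  node_label <- rep("", main$Nnode)
  node_label[sp$nodes - n] <- sprintf("%g", round(supp, 1))
  main$node.label <- node_label
  attr(main, "splits") <- tibble(split = sp$keys, node = sp$nodes,
                                 support_pct = round(unname(supp), 1))
  attr(main, "n_retained") <- retained
  attr(main, "n_dropped") <- dropped
  attr(main, "degenerate") <- degenerate
  main
}

#' Collapse poorly supported edges into polytomies
#'
#' Every internal edge whose support is strictly below `threshold_pct` is
#' contracted (its length discarded); the leaf set is unchanged.
#'
#' @param tree An `ape::phylo` with numeric node labels holding percent
#'   supports (as produced by [bootstrap_nj()]).
#' @param threshold_pct Support threshold; edges with support `<` it collapse.
#' @return An `ape::phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold_pct = 50) {
  if (is.null(tree$node.label)) abort("tree has no support labels")
  n <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  root <- n + 1L
  low <- which(!is.na(supports) & supports < threshold_pct) + n
  low <- setdiff(low, root)
  if (!length(low)) return(tree)

  # splice children of each low-support node into its parent
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  final_parent <- function(v) {
    while (v %in% low) v <- parent_of[v]
    v
  }
  keep_edge <- !(tree$edge[, 2] %in% low)
  new_edges <- tree$edge[keep_edge, , drop = FALSE]
  new_lens <- tree$edge.length[keep_edge]
  new_edges[, 1] <- vapply(new_edges[, 1], final_parent, integer(1))

  # renumber: tips keep ids, surviving internals compacted
  surv_internal <- sort(unique(new_edges[, 1]))
  remap <- integer(max(tree$edge))
  remap[seq_len(n)] <- seq_len(n)
  remap[surv_internal] <- n + seq_along(surv_internal)
  out <- list(edge = cbind(remap[new_edges[, 1]], remap[new_edges[, 2]]),
              edge.length = new_lens,
              tip.label = tree$tip.label,
              Nnode = length(surv_internal),
              node.label = tree$node.label[surv_internal - n])
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}
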