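# Synthetic gene-family histories: WGD and tandem duplications on a dated
# species tree, gene loci with collinear flanking anchors, and GY94 codon
# simulation calibrated so a pair split T years apart accrues Ks ~ 2*lambda*T.

#' Default dated species scaffold
#'
#' Four-species tree with the divergence times used throughout the synthetic
#' data: legume split at 54 mya, dicot MRCA at 100 mya, dicot/monocot split at
#' 145 mya. Branch lengths are in million years; internal nodes are labelled.
#'
#' @return An `ape::phylo`.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = "(((Gmax:54,Mtruncatula:54)legumes:46,Athaliana:100)dicots:45,Osativa:145)dicot_monocot;")
}

# ultrametric node ages (mya) for a dated tree
node_ages <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  age <- rep(NA_real_, nn)
  age[seq_len(n)] <- 0
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    a <- age[ch] + tr$edge.length[e]
    if (!is.na(age[par]) && abs(age[par] - a) > 1e-6) abort("species tree is not ultrametric")
    age[par] <- a
  }
  age
}

# species-tree edge (child node id) active at `time` on the path to `species`
edge_at_time <- function(tree, ages, species, time) {
  tip <- which(tree$tip.label == species)
  if (!length(tip)) abort(sprintf("unknown species '%s'", species))
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  v <- tip
  while (v != length(tree$tip.label) + 1L) {
    if (time < ages[parent[v]] && time >= ages[v]) return(v)
    v <- parent[v]
  }
  abort(sprintf("event time %.1f mya is older than the tree root", time))
}

#' Simulate a gene-family duplication history
#'
#' A single gene lineage enters the species tree at `origin` and splits at
#' every speciation; WGD events duplicate every gene lineage present in the
#' affected lineage at the event time (the new copy is retained with
#' probability `retention_prob`), and tandem events duplicate one gene in
#' place. Deterministic given `seed`.
#'
#' @param species_tree Dated `ape::phylo` (branch lengths in mya) with
#'   labelled internal nodes; defaults to [default_species_tree()].
#' @param wgd_events Tibble with columns `time` (mya) and `species`: each row
#'   is a whole-genome duplication on the lineage leading to `species` at
#'   `time` (shared with sister species when older than their split).
#' @param tandem_events Tibble with columns `time`, `species`: deterministic
#'   single-gene tandem duplications.
#' @param tandem_rate Additional random tandem duplications per gene lineage
#'   per million years.
#' @param retention_prob Probability that a new WGD copy is retained.
#' @param origin Species-tree node (label) where the family originates;
#'   default the root.
#' @param family Family name used to build gene ids.
#' @param seed Integer seed.
#' @return An object of class `sim_history`: the dated gene tree (node labels
#'   record the event type, `attr(, "node_time")` the node ages in mya), the
#'   species tree, true lineage counts at every species node, per-tip segment
#'   assignments, the segment table, and the event log.
#' @export
simulate_history <- function(species_tree = default_species_tree(),
                             wgd_events = tibble(time = numeric(), species = character()),
                             tandem_events = tibble(time = numeric(), species = character()),
                             tandem_rate = 0, retention_prob = 1,
                             origin = NULL, family = "fam", seed = 1L) {
  ages <- node_ages(species_tree)
  n_sp <- length(species_tree$tip.label)
  root <- n_sp + 1L
  origin_node <- if (is.null(origin)) root else resolve_species_node(species_tree, origin)
  if (origin_node <= n_sp) abort("origin must be an internal species-tree node")
  for (t in wgd_events$time) {
    if (t > ages[origin_node]) abort(sprintf("WGD time %.1f mya is older than the family origin", t))
  }
  set.seed(seed)

  # growing gene-tree records
  st <- new.env(parent = emptyenv())
  st$parent <- integer(0); st$time <- numeric(0); st$type <- character(0)
  st$label <- character(0)
  st$seg_parent <- integer(0); st$seg_time <- numeric(0); st$seg_species <- character(0)
  st$n_seg <- 1L; st$seg_parent[1] <- NA_integer_; st$seg_time[1] <- NA_real_
  st$tandem_counter <- 0L
  st$tip_info <- list()
  st$counts <- list()
  st$events <- list()
  new_node <- function(parent, time, type, label = NA_character_) {
    st$parent <- c(st$parent, parent)
    st$time <- c(st$time, time)
    st$type <- c(st$type, type)
    st$label <- c(st$label, label)
    length(st$parent)
  }
  new_segment <- function(parent_seg, time) {
    st$n_seg <- st$n_seg + 1L
    st$seg_parent[st$n_seg] <- parent_seg
    st$seg_time[st$n_seg] <- time
    st$n_seg
  }

  wgd_events$edge_child <- vapply(seq_len(nrow(wgd_events)), function(i) {
    edge_at_time(species_tree, ages, wgd_events$species[i], wgd_events$time[i])
  }, integer(1))
  tandem_events$edge_child <- if (nrow(tandem_events)) {
    vapply(seq_len(nrow(tandem_events)), function(i) {
      edge_at_time(species_tree, ages, tandem_events$species[i], tandem_events$time[i])
    }, integer(1))
  } else integer(0)

  node_name <- species_node_names(species_tree)

  # process one species-tree edge (from t0 down to the age of sp_child), then
  # recurse into sp_child; lineages are lists (node, seg, pos)
  process_edge <- function(lineages, sp_child, t0) {
    t1 <- ages[sp_child]
    ev <- bind_rows(
      if (nrow(wgd_events)) wgd_events |> filter(.data$edge_child == sp_child) |>
        mutate(kind = "wgd") else NULL,
      if (nrow(tandem_events)) tandem_events |> filter(.data$edge_child == sp_child) |>
        mutate(kind = "tandem") else NULL
    )
    if (tandem_rate > 0) {
      # random tandem events: Poisson per lineage over the edge duration
      n_rand <- rpois(1L, tandem_rate * (t0 - t1) * length(lineages))
      if (n_rand > 0) {
        ev <- bind_rows(ev, tibble(time = runif(n_rand, t1, t0),
                                   species = NA_character_,
                                   edge_child = sp_child, kind = "tandem"))
      }
    }
    if (nrow(ev %||% tibble())) ev <- ev |> arrange(dplyr::desc(.data$time))
    for (i in seq_len(nrow(ev))) {
      tev <- ev$time[i]
      if (tev <= t1 || tev > t0) next
      if (ev$kind[i] == "wgd") {
        # the WGD copies whole segments: all lineages sharing a segment move
        # together onto one new segment
        seg_map <- new.env(parent = emptyenv())
        new_lineages <- list()
        for (ln in lineages) {
          if (runif(1) <= retention_prob) {
            d <- new_node(ln$node, tev, "wgd")
            key <- as.character(ln$seg)
            if (is.null(seg_map[[key]])) seg_map[[key]] <- new_segment(ln$seg, tev)
            new_lineages <- c(new_lineages,
                              list(list(node = d, seg = ln$seg, pos = ln$pos),
                                   list(node = d, seg = seg_map[[key]], pos = ln$pos)))
          } else {
            new_lineages <- c(new_lineages, list(ln))
          }
        }
        lineages <- new_lineages
        st$events <- c(st$events, list(tibble(type = "wgd", time = tev,
                                              species_edge = node_name[sp_child])))
      } else {
        k <- if (length(lineages) == 1L) 1L else sample.int(length(lineages), 1L)
        ln <- lineages[[k]]
        d <- new_node(ln$node, tev, "tandem")
        st$tandem_counter <- st$tandem_counter + 1L
        off <- 1e-3 * st$tandem_counter
        lineages[[k]] <- list(node = d, seg = ln$seg, pos = ln$pos)
        lineages <- c(lineages, list(list(node = d, seg = ln$seg, pos = ln$pos + off)))
        st$events <- c(st$events, list(tibble(type = "tandem", time = tev,
                                              species_edge = node_name[sp_child])))
      }
    }
    process_node(lineages, sp_child)
  }

  process_node <- function(lineages, sp_node) {
    st$counts[[node_name[sp_node]]] <- length(lineages)
    if (sp_node <= n_sp) {
      sp <- species_tree$tip.label[sp_node]
      for (i in seq_along(lineages)) {
        ln <- lineages[[i]]
        lab <- sprintf("%s_%s_%d", family, sp, i)
        new_node(ln$node, 0, "leaf", lab)
        st$tip_info <- c(st$tip_info,
                         list(tibble(gene_id = lab, species = sp,
                                     segment = ln$seg, pos = ln$pos)))
      }
      return(invisible(NULL))
    }
    kids <- species_tree$edge[species_tree$edge[, 1] == sp_node, 2]
    # each lineage speciates at this node
    spec_nodes <- vapply(lineages, function(ln) {
      new_node(ln$node, ages[sp_node], "speciation")
    }, integer(1))
    for (ch in kids) {
      child_lineages <- lapply(seq_along(lineages), function(i) {
        list(node = spec_nodes[i], seg = lineages[[i]]$seg, pos = lineages[[i]]$pos)
      })
      process_edge(child_lineages, ch, ages[sp_node])
    }
  }

  process_node(list(list(node = NA_integer_, seg = 1L, pos = 0)), origin_node)

  gt <- gene_tree_from_records(st$parent, st$time, st$type, st$label)
  tip_info <- bind_rows(st$tip_info)
  segs <- tibble(segment = seq_len(st$n_seg),
                 parent_segment = st$seg_parent[seq_len(st$n_seg)],
                 split_time = st$seg_time[seq_len(st$n_seg)])
  structure(list(gene_tree = gt$tree,
                 node_time = gt$node_time,
                 node_type = gt$node_type,
                 species_tree = species_tree,
                 origin = node_name[origin_node],
                 family = family,
                 lineage_counts = tibble(species_node = names(st$counts),
                                         count = unlist(st$counts, use.names = FALSE)),
                 tip_info = tip_info,
                 segments = segs,
                 events = bind_rows(st$events)),
            class = "sim_history")
}

#' @export
print.sim_history <- function(x, ...) {
  cat(sprintf("<sim_history> family '%s': %d gene copies, %d segments, %d event(s)\n",
              x$family, length(x$gene_tree$tip.label), nrow(x$segments),
              nrow(x$events)))
  invisible(x)
}

# assemble an ape::phylo from flat simulation records (parents may be NA only
# for the root); returns the tree plus per-node times/types in phylo numbering
gene_tree_from_records <- function(parent, time, type, label) {
  is_leaf <- type == "leaf"
  n <- sum(is_leaf)
  if (n < 2L) abort("simulated family has fewer than 2 surviving genes")
  rec_root <- which(is.na(parent))
  children <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
  # preorder numbering: tips 1..n in record order, internals from n+1
  new_id <- integer(length(parent))
  new_id[is_leaf] <- cumsum(is_leaf)[is_leaf]
  counter <- n
  stack <- rec_root
  order_internal <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    counter <- counter + 1L
    new_id[v] <- counter
    order_internal <- c(order_internal, v)
    kids <- children[[as.character(v)]]
    stack <- c(stack, rev(kids[!is_leaf[kids]]))
  }
  edges <- cbind(new_id[parent[!is.na(parent)]], new_id[which(!is.na(parent))])
  lens <- time[parent[!is.na(parent)]] - time[!is.na(parent)]
  tree <- list(edge = edges, edge.length = lens,
               tip.label = label[is_leaf][order(new_id[is_leaf])],
               Nnode = counter - n,
               node.label = type[order_internal])
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  node_time <- numeric(counter)
  node_time[new_id] <- time
  node_type <- character(counter)
  node_type[new_id] <- type
  list(tree = tree, node_time = node_time, node_type = node_type)
}

#' True duplicate pairs of a simulated history
#'
#' One row per gene pair whose most recent common ancestor in the simulated
#' gene tree is a duplication node, with the event type at the MRCA, the true
#' divergence time, and the clock-expected Ks (`2 * lambda * T`). For
#' same-species pairs the `mechanism` column gives the positional truth a
#' classifier should recover: `tandem` when the two copies lie on the same
#' segment and `segmental` when they lie on duplicated segments (a pair may
#' descend from a tandem duplication and still sit on parallel segments when
#' a later WGD separated the array; such pairs are physically segmental).
#' `mrca_event` preserves the raw gene-tree event.
#'
#' @param history A `sim_history`.
#' @param lambda_rate Synonymous substitution rate per site per year.
#' @return A tibble: `gene_a`, `gene_b`, `mechanism`, `mrca_event`,
#'   `time_mya`, `expected_ks`, `same_species`.
#' @export
truth_pairs <- function(history, lambda_rate = 6.1e-9) {
  gt <- history$gene_tree
  n <- length(gt$tip.label)
  mr <- ape::mrca(gt)
  sp_of <- setNames(history$tip_info$species, history$tip_info$gene_id)
  seg_of <- setNames(history$tip_info$segment, history$tip_info$gene_id)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- mr[i, j]
      tp <- history$node_type[v]
      if (!tp %in% c("wgd", "tandem")) next
      tmya <- history$node_time[v]
      ga <- gt$tip.label[i]; gb <- gt$tip.label[j]
      same_sp <- sp_of[[ga]] == sp_of[[gb]]
      mech <- if (same_sp) {
        if (seg_of[[ga]] == seg_of[[gb]]) "tandem" else "segmental"
      } else if (tp == "wgd") "segmental" else "tandem"
      out[[length(out) + 1L]] <- tibble(
        gene_a = ga, gene_b = gb,
        mechanism = mech,
        mrca_event = if (tp == "wgd") "segmental" else "tandem",
        time_mya = tmya,
        expected_ks = 2 * lambda_rate * tmya * 1e6,
        same_species = same_sp)
    }
  }
  bind_rows(out)
}

# ---- GY94 simulation -------------------------------------------------------

# single-difference codon pair list (cached): i, j (1-based), transition flag,
# nonsynonymous flag
codon_pair_list <- function() {
  if (!is.null(codon_env$pair_list)) return(codon_env$pair_list)
  tb <- codon_tables()
  n <- length(tb$codons)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(tb$nuc[i, ] != tb$nuc[j, ])
      if (length(diff) != 1L) next
      a <- tb$nuc[i, diff]; b <- tb$nuc[j, diff]
      res[[length(res) + 1L]] <- c(i, j, as.integer((a + b == 2) || (a + b == 4)),
                                   as.integer(tb$aa[i] != tb$aa[j]))
    }
  }
  m <- do.call(rbind, res)
  codon_env$pair_list <- list(i = m[, 1], j = m[, 2], ts = m[, 3] == 1L, nonsyn = m[, 4] == 1L)
  codon_env$pair_list
}

# codon frequencies from uniform-position nucleotide frequencies
codon_freqs_from_nuc <- function(nuc_freqs) {
  tb <- codon_tables()
  nuc_freqs <- nuc_freqs / sum(nuc_freqs)
  pi <- nuc_freqs[tb$nuc[, 1] + 1L] * nuc_freqs[tb$nuc[, 2] + 1L] * nuc_freqs[tb$nuc[, 3] + 1L]
  pi <- pi / sum(pi)
  names(pi) <- tb$codons
  pi
}

#' Simulate codon sequences along a dated gene tree
#'
#' Continuous-time GY94 simulation with site-wise omega. The generator is
#' calibrated so that the expected number of synonymous substitutions per
#' (NG86) synonymous site equals `lambda_rate` per year on every branch:
#' a pair of genes split `T` years ago accrues an expected Ks of
#' `2 * lambda_rate * T`, matching the molecular clock used for dating.
#'
#' @param tree Dated `ape::phylo`, branch lengths in million years.
#' @param n_codons Number of codon sites.
#' @param lambda_rate Synonymous substitution rate per site per year.
#' @param kappa Transition/transversion rate ratio.
#' @param site_omega Site-wise omega specification: `list(model = "M0",
#'   omega = )`, `list(model = "beta", p = , q = )`, or `list(model =
#'   "beta_point", p = , q = , p0 = , omega_s = )`.
#' @param nuc_freqs Nucleotide frequencies used to build codon frequencies.
#' @param seed Integer seed.
#' @return A tibble with `id`, `seq`; the per-site true omega values are
#'   attached as `attr(, "site_omega")`.
#' @export
evolve_codons <- function(tree, n_codons, lambda_rate = 6.1e-9, kappa = 2,
                          site_omega = list(model = "M0", omega = 0.2),
                          nuc_freqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                          seed = 1L) {
  if (n_codons < 1L) abort("n_codons must be >= 1")
  set.seed(seed)
  tb <- codon_tables()
  pi <- codon_freqs_from_nuc(nuc_freqs)

  omegas <- switch(site_omega$model,
                   M0 = rep(site_omega$omega, n_codons),
                   beta = rbeta(n_codons, site_omega$p, site_omega$q),
                   beta_point = {
                     sel <- runif(n_codons) > site_omega$p0
                     w <- rbeta(n_codons, site_omega$p, site_omega$q)
                     w[sel] <- site_omega$omega_s
                     w
                   },
                   abort(sprintf("unknown site_omega model '%s'", site_omega$model)))

  # calibration: synonymous flux per NG86 synonymous site = lambda per year
  pl <- codon_pair_list()
  syn_rate_unscaled <- sum(pi[pl$i] * pi[pl$j] * ifelse(pl$ts, kappa, 1) * !pl$nonsyn)
  s_bar <- sum(pi * tb$syn_sites)
  u <- lambda_rate * s_bar / syn_rate_unscaled   # per year

  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  n <- length(tr$tip.label)
  ct <- gy94_code_tables()
  states <- gy94_sim_cpp(tr$edge - 1L, tr$edge.length * 1e6 * u,
                         n, n + tr$Nnode, n, unname(pi), kappa, omegas,
                         ct$nuc, ct$aa)
  seqs <- tibble(id = tr$tip.label,
                 seq = vapply(seq_len(n), function(i) {
                   paste(tb$codons[states[i, ] + 1L], collapse = "")
                 }, character(1)))
  attr(seqs, "site_omega") <- omegas
  seqs
}
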