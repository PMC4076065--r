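# Collinearity: anchor chaining between chromosome segments, dating-window
# selection around focal genes, and cross-species synteny support.

# longest strictly increasing subsequence (by `y`) of points already sorted by
# `x`; returns indices of the chosen points. O(n^2) dynamic programme with
# earliest-predecessor tie-breaks, deterministic for a given input order.
lis_indices <- function(y) {
  n <- length(y)
  if (!n) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (y[j] < y[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(len[best])
  k <- len[best]
  while (best > 0L) { chain[k] <- best; k <- k - 1L; best <- prev[best] }
  chain
}

#' Chain homology hits into collinear blocks
#'
#' For every chromosome pair, keeps hits with `evalue <= evalue_max`, maps
#' them to gene rank coordinates, and extracts the maximum-cardinality chain
#' monotone in both rank coordinates (strictly increasing on the first
#' segment, strictly increasing or strictly decreasing on the second; both
#' orientations are tried and the larger chain kept). Blocks with fewer than
#' `min_anchors` anchors are discarded. Output is invariant to hit order.
#'
#' @param hits Tibble of homology hits (`query_id`, `subject_id`, `evalue`,
#'   optionally `identity_pct`).
#' @param loci Ranked loci tibble (see [rank_loci()]) covering all hit genes.
#' @param evalue_max Maximum E-value for a hit to enter chaining.
#' @param min_anchors Minimum chain size for a block to be reported.
#' @return A tibble with one row per block: `block_id`, `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b`, `n_anchors`, `orientation`, and a
#'   list-column `anchors` (tibbles of `gene_a`, `gene_b`, `rank_a`, `rank_b`).
#' @export
chain_collinear <- function(hits, loci, evalue_max = 1e-10, min_anchors = 4L) {
  empty <- tibble(block_id = character(), chrom_a = character(), start_a = numeric(),
                  end_a = numeric(), chrom_b = character(), start_b = numeric(),
                  end_b = numeric(), n_anchors = integer(), orientation = character(),
                  anchors = list())
  if (!nrow(hits)) return(empty)
  h <- hits |>
    filter(.data$evalue <= evalue_max, .data$query_id != .data$subject_id)
  if (!nrow(h)) return(empty)
  li <- loci |> select("gene_id", "chromosome", "start", "end", "rank")
  h <- h |>
    left_join(li, by = c(query_id = "gene_id")) |>
    rename(chrom_q = "chromosome", start_q = "start", end_q = "end", rank_q = "rank") |>
    left_join(li, by = c(subject_id = "gene_id")) |>
    rename(chrom_s = "chromosome", start_s = "start", end_s = "end", rank_s = "rank")
  if (anyNA(h$chrom_q) || anyNA(h$chrom_s)) abort("hits reference genes missing from the loci table")

  # canonical orientation of each hit so (a, b) is order-independent
  flip <- h$chrom_s < h$chrom_q | (h$chrom_s == h$chrom_q & h$rank_s < h$rank_q)
  a_id <- ifelse(flip, h$subject_id, h$query_id)
  b_id <- ifelse(flip, h$query_id, h$subject_id)
  pts <- tibble(
    gene_a = a_id, gene_b = b_id,
    chrom_a = ifelse(flip, h$chrom_s, h$chrom_q),
    chrom_b = ifelse(flip, h$chrom_q, h$chrom_s),
    rank_a = ifelse(flip, h$rank_s, h$rank_q),
    rank_b = ifelse(flip, h$rank_q, h$rank_s),
    start_a = ifelse(flip, h$start_s, h$start_q),
    end_a = ifelse(flip, h$end_s, h$end_q),
    start_b = ifelse(flip, h$start_q, h$start_s),
    end_b = ifelse(flip, h$end_q, h$end_s)
  ) |>
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)

  blocks <- pts |>
    group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::group_map(function(g, key) {
      up <- lis_indices(g$rank_b)
      down <- lis_indices(-g$rank_b)
      use_down <- length(down) > length(up)
      chain <- if (use_down) down else up
      if (length(chain) < min_anchors) return(NULL)
      gg <- g[chain, ]
      tibble(block_id = sprintf("%s|%s", key$chrom_a, key$chrom_b),
             chrom_a = key$chrom_a, start_a = min(gg$start_a), end_a = max(gg$end_a),
             chrom_b = key$chrom_b, start_b = min(gg$start_b), end_b = max(gg$end_b),
             n_anchors = nrow(gg),
             orientation = if (use_down) "inverted" else "collinear",
             anchors = list(gg |> select("gene_a", "gene_b", "rank_a", "rank_b")))
    }) |>
    purrr::compact() |>
    bind_rows()
  if (!nrow(blocks)) return(empty)
  arrange(blocks, .data$chrom_a, .data$chrom_b)
}

#' Select dating anchors around a focal pair
#'
#' Returns up to `max_per_side` anchors nearest the focal pair on each side
#' (by rank on the first segment), in rank order, excluding the focal pair
#' itself.
#'
#' @param block One block row from [chain_collinear()] (or its `anchors`
#'   tibble).
#' @param focal_gene_a,focal_gene_b Gene ids of the focal anchor pair.
#' @param max_per_side Maximum anchors kept on each side.
#' @return An anchors tibble (subset of the block's anchors).
#' @export
select_dating_anchors <- function(block, focal_gene_a, focal_gene_b, max_per_side = 6L) {
  anchors <- if (is.data.frame(block) && "anchors" %in% names(block)) block$anchors[[1L]] else block
  pos <- which(anchors$gene_a == focal_gene_a & anchors$gene_b == focal_gene_b)
  if (length(pos) != 1L) abort("focal pair is not an anchor of this block")
  below <- anchors[seq_len(pos - 1L), , drop = FALSE]
  above <- anchors[seq_len(nrow(anchors)) > pos, , drop = FALSE]
  below <- tail(below, max_per_side)
  above <- head(above, max_per_side)
  bind_rows(below, above)
}

#' Cross-species synteny support for a focal gene
#'
#' A focal gene's arrangement is supported in another genome when at least
#' `min_flank_hits` of its flanking genes (within `window_bp` on each side on
#' the same chromosome) have significant homology hits (`evalue <
#' evalue_sig`, strict) to a common chromosome of the other genome.
#'
#' @param focal_gene Gene id of the focal gene.
#' @param loci Ranked loci tibble for the focal genome.
#' @param hits Hits from focal-genome genes to the other genome (`query_id`,
#'   `subject_id`, `evalue`).
#' @param other_loci Ranked loci for the other genome (supplies subject
#'   chromosomes).
#' @param window_bp Flanking window in bp on each side of the focal gene.
#' @param evalue_sig Significance threshold (strict `<`).
#' @param min_flank_hits Minimum supporting flanking genes.
#' @return A one-row tibble: `focal_gene`, `supported`, `best_chromosome`,
#'   `n_support`, plus an `evidence` list-column of the supporting hits.
#' @export
cross_species_support <- function(focal_gene, loci, hits, other_loci,
                                  window_bp = 100000, evalue_sig = 1e-10,
                                  min_flank_hits = 3L) {
  if (window_bp <= 0) abort("window_bp must be positive")
  f <- loci |> filter(.data$gene_id == focal_gene)
  if (nrow(f) != 1L) abort(sprintf("focal gene '%s' not found in loci", focal_gene))
  flank <- loci |>
    filter(.data$chromosome == f$chromosome,
           .data$gene_id != focal_gene,
           .data$end > f$start - window_bp,
           .data$start < f$end + window_bp)
  ev <- hits |>
    filter(.data$query_id %in% flank$gene_id, .data$evalue < evalue_sig) |>
    left_join(other_loci |> select("gene_id", other_chrom = "chromosome"),
              by = c(subject_id = "gene_id"))
  if (!nrow(ev)) {
    return(tibble(focal_gene = focal_gene, supported = FALSE,
                  best_chromosome = NA_character_, n_support = 0L,
                  evidence = list(ev)))
  }
  per_chrom <- ev |>
    distinct(.data$query_id, .data$other_chrom) |>
    dplyr::count(.data$other_chrom, sort = TRUE)
  best <- per_chrom$other_chrom[1L]
  n_support <- per_chrom$n[1L]
  tibble(focal_gene = focal_gene,
         supported = n_support >= min_flank_hits,
         best_chromosome = best, n_support = as.integer(n_support),
         evidence = list(ev |> filter(.data$other_chrom == best)))
}
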