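# Fixture assembly: gene loci with collinear flanking anchors, homology-hit
# tables, anchor coding sequences, and complete simulated input bundles.

#' Lay out gene loci with collinear flanking anchors
#'
#' Every (species, segment) instance of a simulated history becomes a
#' chromosome carrying `(genes_per_segment - 1) / 2` anchor genes on each side
#' of the family's genes; tandem copies sit adjacent (zero intervening genes).
#' Segments descending from the same ancestral segment share anchor slots, so
#' corresponding anchors are homologous across segments and species. With
#' `noise > 0` each anchor's position is shuffled with that probability,
#' breaking collinearity.
#'
#' @param history A `sim_history`.
#' @param genes_per_segment Genes per segment (odd; at least 2*anchors+1).
#' @param noise Fraction of anchors repositioned at random.
#' @param seed Integer seed (used only when `noise > 0`).
#' @return A list: `loci` (ranked loci tibble for all species, with a
#'   `species` column), `anchor_slots` (anchor gene metadata), `focal`
#'   (family gene metadata with chromosome assignments).
#' @export
layout_loci <- function(history, genes_per_segment = 13L, noise = 0, seed = 1L) {
  k <- (genes_per_segment - 1L) %/% 2L
  if (genes_per_segment < 3L || genes_per_segment %% 2L == 0L) {
    abort("genes_per_segment must be odd and >= 3")
  }
  set.seed(seed)
  fam <- history$family
  if (!nrow(history$tip_info)) abort("history has no surviving genes")
  inst <- history$tip_info |>
    distinct(.data$species, .data$segment) |>
    arrange(.data$species, .data$segment) |>
    group_by(.data$species) |>
    mutate(chromosome = sprintf("%s_%s_chr%02d", .data$species, history$family, row_number())) |>
    ungroup()

  rows <- list()
  slots <- list()
  for (i in seq_len(nrow(inst))) {
    sp <- inst$species[i]; seg <- inst$segment[i]; chrom <- inst$chromosome[i]
    focal <- history$tip_info |>
      filter(.data$species == sp, .data$segment == seg) |>
      arrange(.data$pos)
    left <- sprintf("%s_anc%02d_%s_seg%03d", fam, seq_len(k), sp, seg)
    right <- sprintf("%s_anc%02d_%s_seg%03d", fam, k + seq_len(k), sp, seg)
    ids <- c(rev(left), focal$gene_id, right)
    pos_idx <- seq_along(ids)
    if (noise > 0) {
      anchor_at <- which(ids %in% c(left, right))
      for (a in anchor_at) {
        if (runif(1) < noise) {
          b <- sample(anchor_at, 1L)
          pos_idx[c(a, b)] <- pos_idx[c(b, a)]
        }
      }
    }
    rows[[i]] <- tibble(gene_id = ids, chromosome = chrom,
                        start = pos_idx * 10000, end = pos_idx * 10000 + 3000,
                        strand = "+", species = sp)
    slots[[i]] <- tibble(anchor_gene_id = c(left, right), slot = seq_len(2L * k),
                         species = sp, segment = seg)
  }
  loci <- bind_rows(rows)
  loci <- rank_loci(loci |> select(-"species")) |>
    left_join(loci |> select("gene_id", "species"), by = "gene_id")
  list(loci = loci,
       anchor_slots = bind_rows(slots),
       focal = history$tip_info |>
         left_join(inst, by = c("species", "segment")))
}

#' Homology hits between anchor and family genes
#'
#' Same-slot anchors on different segments hit each other, as do all family
#' gene copies; hits are emitted for the requested (query species, subject
#' species) direction.
#'
#' @param layout Result of [layout_loci()].
#' @param history The `sim_history` behind the layout.
#' @param query_species,subject_species Species of the query and subject
#'   genes (equal for within-genome hits).
#' @param evalue E-value recorded for the synthetic hits.
#' @return A hits tibble: `query_id`, `subject_id`, `identity_pct`, `evalue`.
#' @export
anchor_hits <- function(layout, history, query_species, subject_species,
                        evalue = 1e-60) {
  a <- layout$anchor_slots
  qa <- a |> filter(.data$species == query_species)
  sa <- a |> filter(.data$species == subject_species)
  anchors <- qa |>
    dplyr::inner_join(sa, by = "slot", suffix = c("_q", "_s"),
                      relationship = "many-to-many") |>
    filter(.data$anchor_gene_id_q != .data$anchor_gene_id_s) |>
    select(query_id = "anchor_gene_id_q", subject_id = "anchor_gene_id_s")
  qf <- history$tip_info |> filter(.data$species == query_species)
  sf <- history$tip_info |> filter(.data$species == subject_species)
  focal <- tidyr::expand_grid(query_id = qf$gene_id, subject_id = sf$gene_id) |>
    filter(.data$query_id != .data$subject_id)
  bind_rows(anchors, focal) |>
    mutate(identity_pct = 92, evalue = evalue)
}

#' Simulate anchor coding sequences
#'
#' Each anchor slot evolves on the family's segment-instance tree (the gene
#' tree pruned to one primary copy per species/segment), so anchors accrue
#' Ks proportional to the age of the segmental duplications that separate
#' them (expected `2 * lambda * T`).
#'
#' @param history A `sim_history`.
#' @param layout Result of [layout_loci()].
#' @param n_codons Codons per anchor gene.
#' @param lambda_rate,kappa Simulation parameters (see [evolve_codons()]).
#' @param omega Single purifying omega used for anchors.
#' @param seed Integer seed (per-slot substreams derived from it).
#' @return A tibble of anchor sequences (`id`, `seq`).
#' @export
anchor_sequences <- function(history, layout, n_codons = 400L,
                             lambda_rate = 6.1e-9, kappa = 2, omega = 0.1,
                             seed = 1L) {
  # primary copy per (species, segment) carries the segment's history
  prim <- history$tip_info |>
    group_by(.data$species, .data$segment) |>
    dplyr::slice_min(.data$pos, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(prim) < 2L) return(tibble(id = character(), seq = character()))
  seg_tree <- ape::keep.tip(history$gene_tree, prim$gene_id)
  slots <- sort(unique(layout$anchor_slots$slot))
  out <- purrr::map_dfr(slots, function(s) {
    ids <- layout$anchor_slots |> filter(.data$slot == s)
    map <- prim |>
      left_join(ids, by = c("species", "segment")) |>
      filter(!is.na(.data$anchor_gene_id))
    tr <- seg_tree
    seqs <- evolve_codons(tr, n_codons, lambda_rate, kappa,
                          site_omega = list(model = "M0", omega = omega),
                          seed = substream_seed(seed, s))
    seqs$id <- map$anchor_gene_id[match(seqs$id, map$gene_id)]
    seqs |> filter(!is.na(.data$id))
  })
  out
}

# star tree of population haplotypes, depth in mya
star_tree <- function(n, depth, prefix = "acc") {
  txt <- paste0("(", paste(sprintf("%s%02d:%g", prefix, seq_len(n), depth), collapse = ","), ");")
  ape::read.tree(text = txt)
}

paper_like_families <- function() {
  w <- function(...) tibble(time = c(...), species = "Gmax")
  t0 <- function() tibble(time = numeric(), species = character())
  # upstream families evolve under stronger purifying selection than
  # downstream ones, mirroring the pathway-position contrast
  up <- list(model = "beta", p = 0.3, q = 2.7)
  down <- list(model = "beta", p = 1, q = 1.5)
  list(
    PAL  = list(position = "upstream", pleiotropy = "n/a", origin = NULL,
                wgd = w(55, 12), tandem = t0(), site_omega = up),
    C4H  = list(position = "upstream", pleiotropy = "n/a", origin = NULL,
                wgd = w(12), tandem = t0(), site_omega = up),
    `4CL` = list(position = "branch_point", pleiotropy = "higher", origin = NULL,
                 wgd = w(12), tandem = tibble(time = 60, species = "Gmax")),
    CHS  = list(position = "branch_point", pleiotropy = "higher", origin = NULL,
                wgd = w(12), tandem = tibble(time = c(5, 4), species = "Gmax")),
    CHI  = list(position = "branch_point", pleiotropy = "higher", origin = NULL,
                wgd = w(12), tandem = tibble(time = 60, species = "Gmax")),
    CHR  = list(position = "branch_point", pleiotropy = "lower", origin = "legumes",
                wgd = w(12), tandem = t0()),
    IFS  = list(position = "branch_point", pleiotropy = "lower", origin = "legumes",
                wgd = w(12), tandem = t0()),
    IOMT = list(position = "downstream", pleiotropy = "n/a", origin = "legumes",
                wgd = w(12), tandem = tibble(time = 13, species = "Gmax"),
                site_omega = down),
    IFR  = list(position = "downstream", pleiotropy = "n/a", origin = "legumes",
                wgd = w(12), tandem = tibble(time = 60, species = "Gmax"),
                site_omega = list(model = "beta_point", p = 0.5, q = 1.5,
                                  p0 = 0.8, omega_s = 4))
  )
}

#' Build a complete synthetic input bundle
#'
#' `profile = "small"` emits one gene family with a single recent WGD, for
#' unit-scale work; `profile = "paper_like"` emits a nine-family pathway
#' (PAL-like through IFR-like) with WGDs at 55 and 12 mya, family-specific
#' tandem events (old tandems on the shared legume stem, recent ones in the
#' soybean-like lineage), and one downstream family (IFR-like) carrying a
#' positively selected site class. Byte-identical given the same seed.
#'
#' @param profile `"small"` or `"paper_like"`.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the bundle is also written out
#'   as FASTA/TSV/newick/JSON files via [write_fixture()].
#' @param n_accessions Haplotypes sampled per focal-species gene copy.
#' @param n_codons Codons per family coding region.
#' @param pop_depth_mya Depth of the within-species haplotype star tree.
#' @param lambda_rate,kappa Simulation parameters.
#' @return A fixture bundle (list); see Details in the package vignette.
#' @export
make_fixture <- function(profile = c("small", "paper_like"), seed = 1L, dir = NULL,
                         n_accessions = NULL, n_codons = NULL,
                         pop_depth_mya = 0.35, lambda_rate = 6.1e-9, kappa = 2) {
  profile <- match.arg(profile)
  fams <- if (profile == "small") {
    list(FAM = list(position = "upstream", pleiotropy = "n/a", origin = NULL,
                    wgd = tibble(time = 12, species = "Gmax"),
                    tandem = tibble(time = numeric(), species = character())))
  } else paper_like_families()
  n_accessions <- n_accessions %||% (if (profile == "small") 6L else 8L)
  n_codons <- n_codons %||% (if (profile == "small") 120L else 200L)
  sp_tree <- default_species_tree()

  families <- list()
  loci_all <- list(); slots_all <- list(); anchors_all <- list()
  hits_within <- list(); hits_cross <- list()
  genes_all <- list()
  fam_names <- names(fams)
  for (fi in seq_along(fams)) {
    fam <- fam_names[fi]
    fd <- fams[[fam]]
    fseed <- substream_seed(seed, fi * 10L)
    hist <- simulate_history(sp_tree, wgd_events = fd$wgd, tandem_events = fd$tandem,
                             retention_prob = 1, origin = fd$origin,
                             family = fam, seed = fseed)
    lay <- layout_loci(hist, genes_per_segment = 13L, noise = 0,
                       seed = substream_seed(seed, fi * 10L + 1L))
    so <- fd$site_omega %||% list(model = "beta", p = 0.5, q = 1.5)
    copy_seqs <- evolve_codons(hist$gene_tree, n_codons, lambda_rate, kappa,
                               site_omega = so, seed = substream_seed(seed, fi * 10L + 2L))
    anchors <- anchor_sequences(hist, lay, n_codons = 400L,
                                lambda_rate = lambda_rate, kappa = kappa,
                                seed = substream_seed(seed, fi * 10L + 3L))
    gmax_copies <- hist$tip_info |> filter(.data$species == "Gmax") |> pull("gene_id")
    pop_seqs <- setNames(lapply(seq_along(gmax_copies), function(ci) {
      evolve_codons(star_tree(n_accessions, pop_depth_mya,
                              prefix = paste0(gmax_copies[ci], "_acc")),
                    n_codons, lambda_rate, kappa, site_omega = so,
                    seed = substream_seed(seed, fi * 10L + 4L) + ci)
    }), gmax_copies)

    families[[fam]] <- list(history = hist, layout = lay, copy_seqs = copy_seqs,
                            pop_seqs = pop_seqs,
                            position = fd$position, pleiotropy = fd$pleiotropy)
    loci_all[[fam]] <- lay$loci
    slots_all[[fam]] <- lay$anchor_slots
    anchors_all[[fam]] <- anchors
    hits_within[[fam]] <- anchor_hits(lay, hist, "Gmax", "Gmax")
    if ("Mtruncatula" %in% hist$tip_info$species) {
      hits_cross[[fam]] <- anchor_hits(lay, hist, "Gmax", "Mtruncatula")
    }
    genes_all[[fam]] <- hist$tip_info |> mutate(family = fam)
  }

  annotation <- purrr::map_dfr(fam_names, function(fam) {
    tibble(family = fam, position = families[[fam]]$position,
           pleiotropy = families[[fam]]$pleiotropy)
  })

  structure(list(profile = profile, seed = as.integer(seed),
                 species_tree = sp_tree,
                 families = families,
                 genes = bind_rows(genes_all),
                 loci = bind_rows(loci_all),
                 anchor_slots = bind_rows(slots_all),
                 anchor_seqs = bind_rows(anchors_all),
                 hits_within = bind_rows(hits_within),
                 hits_cross = bind_rows(hits_cross),
                 annotation = annotation,
                 n_accessions = n_accessions, n_codons = n_codons,
                 lambda_rate = lambda_rate, kappa = kappa),
            class = "pathevo_fixture") -> bundle
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

#' @export
print.pathevo_fixture <- function(x, ...) {
  cat(sprintf("<pathevo_fixture> profile '%s', %d family/families, seed %d\n",
              x$profile, length(x$families), x$seed))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits the exact formats the readers consume: FASTA for sequences, TSV for
#' loci/hits/annotation, newick for the species tree, and a JSON truth file.
#'
#' @param bundle A fixture from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_newick(bundle$species_tree, p("species_tree.nwk"))
  readr::write_tsv(bundle$loci |> select("gene_id", "chromosome", "start", "end", "strand"),
                   p("loci.tsv"))
  readr::write_tsv(bundle$genes |>
                     select("gene_id", "family", "species", "segment"),
                   p("genes.tsv"))
  readr::write_tsv(bundle$anchor_slots, p("anchor_slots.tsv"))
  readr::write_tsv(bundle$hits_within, p("hits_within.tsv"))
  readr::write_tsv(bundle$hits_cross, p("hits_cross.tsv"))
  readr::write_tsv(bundle$annotation, p("annotation.tsv"))
  write_fasta(bundle$anchor_seqs, p("anchors.fasta"))
  for (fam in names(bundle$families)) {
    fd <- bundle$families[[fam]]
    write_fasta(fd$copy_seqs, p(sprintf("family_%s_copies.fasta", fam)))
    for (copy in names(fd$pop_seqs)) {
      write_fasta(fd$pop_seqs[[copy]], p(sprintf("pop_%s.fasta", copy)))
    }
    write_newick(fd$history$gene_tree, p(sprintf("family_%s_true_tree.nwk", fam)))
  }
  truth <- list(
    profile = bundle$profile, seed = bundle$seed,
    lineage_counts = lapply(bundle$families, function(f) {
      stats::setNames(as.list(f$history$lineage_counts$count),
                      f$history$lineage_counts$species_node)
    }),
    pairs = lapply(bundle$families, function(f) {
      tp <- truth_pairs(f$history, bundle$lambda_rate)
      lapply(seq_len(nrow(tp)), function(i) as.list(tp[i, ]))
    })
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
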