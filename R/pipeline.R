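# End-to-end orchestration: diversity/rates, trees, reconciliation, synteny,
# dating, classification, selection tests, and report assembly.

#' Read a fixture directory back into a pipeline input bundle
#'
#' Reconstructs the inputs [run_pipeline()] needs from the files written by
#' [write_fixture()].
#'
#' @param dir Fixture directory.
#' @return A list usable as the `bundle` argument of [run_pipeline()].
#' @export
read_fixture <- function(dir) {
  p <- function(...) file.path(dir, ...)
  need <- function(f, stage) {
    if (!file.exists(p(f))) abort(sprintf("missing input '%s' for stage %s", f, stage))
    p(f)
  }
  genes <- readr::read_tsv(need("genes.tsv", "core"), show_col_types = FALSE)
  loci <- read_loci_table(need("loci.tsv", "synteny"))
  fams <- unique(genes$family)
  families <- setNames(lapply(fams, function(fam) {
    copies <- read_fasta(need(sprintf("family_%s_copies.fasta", fam), "tree"))
    gmax <- genes |> filter(.data$family == fam, .data$species == "Gmax") |> pull("gene_id")
    pop <- setNames(lapply(gmax, function(g) {
      f <- p(sprintf("pop_%s.fasta", g))
      if (file.exists(f)) read_fasta(f) else NULL
    }), gmax)
    list(copy_seqs = copies, pop_seqs = purrr::compact(pop))
  }), fams)
  ann <- readr::read_tsv(need("annotation.tsv", "report"), show_col_types = FALSE)
  list(profile = "from_dir",
       species_tree = read_newick(need("species_tree.nwk", "reconcile")),
       families = purrr::imap(families, function(fd, fam) {
         c(fd, list(position = ann$position[ann$family == fam][1],
                    pleiotropy = ann$pleiotropy[ann$family == fam][1]))
       }),
       genes = genes,
       loci = loci,
       anchor_slots = readr::read_tsv(need("anchor_slots.tsv", "synteny"), show_col_types = FALSE),
       anchor_seqs = read_fasta(need("anchors.fasta", "date")),
       hits_within = read_hits_table(need("hits_within.tsv", "synteny")),
       hits_cross = read_hits_table(need("hits_cross.tsv", "synteny")),
       annotation = ann)
}

# outgroup species preference for rooting gene trees
pick_outgroup_species <- function(species_present) {
  for (sp in c("Osativa", "Athaliana", "Mtruncatula")) {
    if (sp %in% species_present && length(species_present) > 1L) return(sp)
  }
  species_present[length(species_present)]
}

#' Run the full pathway-evolution pipeline
#'
#' Executes every stage on a fixture bundle (from [make_fixture()] or
#' [read_fixture()]): per-copy diversity and NG86 rates, bootstrap NJ trees
#' with reconciliation-based ancestral-gene counts, collinearity chaining,
#' trimmed-mean Ks dating, duplication classification and event tabulation,
#' M7-vs-M8 selection tests, and the report tables. All stochastic stages
#' derive their seeds from `config$rng_seed`, so two runs with the same seed
#' write byte-identical reports.
#'
#' @param bundle A fixture bundle or fixture directory path.
#' @param config A [pathevo_config()].
#' @param out_dir Directory for report TSVs, trees and the JSON run log
#'   (created if needed). `NULL` skips writing.
#' @param selection Fit site models? (The slowest stage; representative Gmax
#'   copy per family is annotated with the family-level LRT.)
#' @return A list of report tibbles (`family_sizes`, `ancestral_counts`,
#'   `segment_dating`, `duplication_calls`, `duplication_events`,
#'   `rate_stats`, `updown`, `branchpoint`, `selection`, `log`), invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(bundle, config = pathevo_config(), out_dir = NULL,
                         selection = TRUE) {
  if (is.character(bundle)) bundle <- read_fixture(bundle)
  if (!length(bundle$families)) {
    res <- list(family_sizes = tibble(), ancestral_counts = tibble(),
                segment_dating = tibble(), duplication_calls = tibble(),
                duplication_events = tibble(), rate_stats = tibble(),
                updown = NULL, branchpoint = NULL, selection = tibble(),
                log = list(n_families = 0L))
    if (!is.null(out_dir)) write_report(res, out_dir)
    return(invisible(res))
  }
  for (nm in c("genes", "loci", "hits_within", "anchor_seqs", "annotation")) {
    if (is.null(bundle[[nm]])) abort(sprintf("missing input '%s' for stage %s", nm,
                                             c(genes = "core", loci = "synteny",
                                               hits_within = "synteny",
                                               anchor_seqs = "date",
                                               annotation = "report")[[nm]]))
  }
  log <- list(seed = config$rng_seed, warnings = character(0))
  note <- function(msg) log$warnings <<- c(log$warnings, msg)

  genes <- bundle$genes
  fams <- names(bundle$families)

  # stage 1: per-copy diversity and mean pairwise NG86 rates
  rate_stats <- purrr::map_dfr(fams, function(fam) {
    fd <- bundle$families[[fam]]
    purrr::map_dfr(names(fd$pop_seqs), function(copy) {
      seqs <- fd$pop_seqs[[copy]]
      div <- nucleotide_diversity(seqs)
      mr <- mean_pairwise_rates(seqs)
      tibble(family = fam, gene_id = copy, pi = div$pi,
             dn = mr$dn, ds = mr$ds, omega = mr$omega,
             n_haplotypes = div$n_sequences)
    })
  })

  # stage 2: trees, rooting, reconciliation, ancestral counts
  tree_seed <- substream_seed(config$rng_seed, 1L)
  trees <- list()
  anc_counts <- list()
  for (fam in fams) {
    fd <- bundle$families[[fam]]
    seqs <- fd$copy_seqs
    if (nrow(seqs) < 3L) { note(sprintf("family %s: <3 copies, tree skipped", fam)); next }
    bt <- suppressWarnings(bootstrap_nj(seqs, reps = config$bootstrap_reps,
                                        seed = substream_seed(tree_seed, match(fam, fams))))
    fam_genes <- genes |> filter(.data$family == fam)
    sp_map <- fam_genes |> select("gene_id", species_id = "species")
    og_sp <- pick_outgroup_species(unique(fam_genes$species))
    og <- fam_genes$gene_id[fam_genes$species == og_sp]
    rooted <- tryCatch(root_by_outgroup(bt, og), error = function(e) {
      note(sprintf("family %s: outgroup not monophyletic, rooted on first outgroup leaf", fam))
      ape::root(ape::unroot(bt), outgroup = og[1], resolve.root = TRUE)
    })
    rec <- lca_reconcile(rooted, bundle$species_tree, sp_map)
    trees[[fam]] <- list(bootstrap = bt, rooted = rooted, collapsed =
                           collapse_low_support(bt, config$support_collapse_pct))
    anc_counts[[fam]] <- ancestral_gene_counts(rec) |> mutate(family = fam)
  }
  ancestral_counts <- bind_rows(anc_counts)

  # stage 3: collinearity chaining
  blocks <- chain_collinear(bundle$hits_within, bundle$loci,
                            evalue_max = config$evalue_max,
                            min_anchors = config$min_anchors)

  # stage 4: Ks dating per block around the family's focal anchor pair
  anchor_seq_of <- setNames(bundle$anchor_seqs$seq, bundle$anchor_seqs$id)
  copy_seq_of <- do.call(c, lapply(fams, function(fam) {
    setNames(bundle$families[[fam]]$copy_seqs$seq, bundle$families[[fam]]$copy_seqs$id)
  }))
  ks_of_pair <- function(ga, gb) {
    sa <- if (ga %in% names(anchor_seq_of)) anchor_seq_of[[ga]] else copy_seq_of[ga][[1]]
    sb <- if (gb %in% names(anchor_seq_of)) anchor_seq_of[[gb]] else copy_seq_of[gb][[1]]
    if (is.null(sa) || is.null(sb) || is.na(sa) || is.na(sb) ||
        nchar(sa) != nchar(sb)) return(NA_real_)
    tryCatch(ng86_rates(sa, sb)$ds, error = function(e) NA_real_)
  }
  segment_dating <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    a <- blocks$anchors[[i]]
    isfam <- a$gene_a %in% genes$gene_id & a$gene_b %in% genes$gene_id
    if (!any(isfam)) return(NULL)
    fo <- which(isfam)[1L]
    fam <- genes$family[match(a$gene_a[fo], genes$gene_id)]
    sel <- select_dating_anchors(a, a$gene_a[fo], a$gene_b[fo],
                                 max_per_side = config$max_anchors_per_side)
    ks <- vapply(seq_len(nrow(sel)), function(j) ks_of_pair(sel$gene_a[j], sel$gene_b[j]),
                 numeric(1))
    ks <- ks[!is.na(ks)]
    if (!length(ks)) { note(sprintf("block %s: no anchor Ks available", blocks$block_id[i])); return(NULL) }
    dd <- suppressWarnings(date_from_anchors(ks, config$lambda_rate))
    tibble(family = fam, block_id = blocks$block_id[i],
           chrom_a = blocks$chrom_a[i], chrom_b = blocks$chrom_b[i],
           n_anchors = dd$n_anchors, ks_mean = dd$ks_mean, ks_sd = dd$ks_sd,
           age_mya = dd$age_mya, age_mya_reported = dd$age_mya_reported)
  })

  # stage 5: classify duplicate pairs and tabulate events
  mtr_tandem <- function(fam) {
    mg <- genes |> filter(.data$family == fam, .data$species == "Mtruncatula") |>
      left_join(bundle$loci, by = "gene_id")
    if (nrow(mg) < 2L) return(FALSE)
    for (i in seq_len(nrow(mg) - 1L)) {
      for (j in (i + 1L):nrow(mg)) {
        if (!is.na(mg$chromosome[i]) && !is.na(mg$chromosome[j]) &&
            mg$chromosome[i] == mg$chromosome[j] &&
            abs(mg$rank[i] - mg$rank[j]) - 1L <= config$tandem_max_intervening_genes) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  duplication_calls <- purrr::map_dfr(fams, function(fam) {
    gmax <- genes |> filter(.data$family == fam, .data$species == "Gmax") |> pull("gene_id")
    if (length(gmax) < 2L) return(NULL)
    outg <- mtr_tandem(fam)
    pairs <- combn(sort(gmax), 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      ga <- pairs[1L, k]; gb <- pairs[2L, k]
      call0 <- suppressWarnings(classify_pair(ga, gb, blocks, bundle$loci,
                                              dating = NULL, outgroup_presence = outg,
                                              config = config))
      if (call0$mechanism == "segmental" && !is.na(call0$block_id) &&
          nrow(segment_dating) && call0$block_id %in% segment_dating$block_id) {
        dd <- segment_dating |> filter(.data$block_id == call0$block_id)
        call0 <- classify_pair(ga, gb, blocks, bundle$loci,
                               dating = dd[1L, ], outgroup_presence = outg,
                               config = config)
      }
      call0 |> mutate(family = fam)
    })
  })
  duplication_events <- if (nrow(duplication_calls)) {
    tabulate_duplications(duplication_calls, families = fams)
  } else tibble()

  # stage 6: M7-vs-M8 selection test per family (on the cross-species copy
  # alignment with the NJ tree), annotated on the representative Gmax copy
  selection_tbl <- tibble(family = character(), gene_id = character(),
                          loglik_m7 = numeric(), loglik_m8 = numeric(),
                          lrt_stat = numeric(), lrt_p = numeric(),
                          stars = character())
  if (selection) {
    selection_tbl <- purrr::map_dfr(fams, function(fam) {
      if (is.null(trees[[fam]])) return(NULL)
      fd <- bundle$families[[fam]]
      fit <- tryCatch(
        site_model_lrt(fd$copy_seqs, trees[[fam]]$bootstrap, config, n_starts = 1L),
        error = function(e) { note(sprintf("family %s: selection fit failed (%s)", fam,
                                           conditionMessage(e))); NULL })
      if (is.null(fit)) return(NULL)
      rep_copy <- (genes |> filter(.data$family == fam, .data$species == "Gmax") |>
                     pull("gene_id"))[1L]
      tibble(family = fam, gene_id = rep_copy,
             loglik_m7 = fit$fit7$loglik, loglik_m8 = fit$fit8$loglik,
             lrt_stat = fit$lrt$stat, lrt_p = fit$lrt$p_value,
             stars = fit$lrt$stars)
    })
  }

  # stage 7: report assembly
  family_sizes <- genes |>
    dplyr::count(.data$family, .data$species, name = "n_genes") |>
    tidyr::complete(family = fams, species = bundle$species_tree$tip.label,
                    fill = list(n_genes = 0L)) |>
    family_size_summary()

  stats_full <- rate_stats |>
    left_join(selection_tbl |> select("gene_id", "lrt_stat", "lrt_p"), by = "gene_id") |>
    left_join(bundle$annotation, by = "family")
  ud <- stats_full |> filter(.data$position %in% c("upstream", "downstream"))
  updown <- if (nrow(ud) && length(unique(ud$position)) == 2L) {
    build_rate_table(ud, ud |> select("gene_id", "position") |> distinct(),
                     group = "position", config = config)
  } else NULL
  bp <- stats_full |> filter(.data$position == "branch_point")
  branchpoint <- if (nrow(bp) && length(unique(bp$pleiotropy)) == 2L) {
    build_rate_table(bp, bp |> select("gene_id", "pleiotropy") |> distinct(),
                     group = "pleiotropy", config = config)
  } else NULL

  log$n_families <- length(fams)
  log$n_blocks <- nrow(blocks)
  log$n_dated <- nrow(segment_dating)
  log$n_calls <- nrow(duplication_calls)
  log$bootstrap_reps <- config$bootstrap_reps

  res <- list(family_sizes = family_sizes,
              ancestral_counts = ancestral_counts,
              segment_dating = segment_dating,
              blocks = blocks |> select(-"anchors"),
              duplication_calls = duplication_calls,
              duplication_events = duplication_events,
              rate_stats = rate_stats,
              updown = updown,
              branchpoint = branchpoint,
              selection = selection_tbl,
              trees = trees,
              log = log)
  if (!is.null(out_dir)) {
    write_report(res, out_dir)
    return(invisible(res))
  }
  res
}

# write the report bundle: TSV tables, newick trees, JSON run log
write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  wt <- function(x, f) if (!is.null(x) && is.data.frame(x)) readr::write_tsv(x, p(f))
  wt(res$family_sizes, "family_sizes.tsv")
  wt(res$ancestral_counts, "ancestral_counts.tsv")
  wt(res$segment_dating, "segment_dating.tsv")
  wt(res$blocks, "collinear_blocks.tsv")
  wt(res$duplication_calls, "duplication_calls.tsv")
  wt(res$duplication_events, "duplication_events.tsv")
  wt(res$rate_stats, "rate_stats.tsv")
  if (!is.null(res$updown)) {
    wt(res$updown$rows, "updown_rates.tsv")
    wt(res$updown$groups, "updown_groups.tsv")
  }
  if (!is.null(res$branchpoint)) {
    wt(res$branchpoint$rows, "branchpoint_rates.tsv")
    wt(res$branchpoint$groups, "branchpoint_groups.tsv")
  }
  wt(res$selection, "selection_tests.tsv")
  for (fam in names(res$trees %||% list())) {
    write_newick(res$trees[[fam]]$bootstrap, p(sprintf("tree_%s.nwk", fam)))
    write_newick(res$trees[[fam]]$collapsed, p(sprintf("tree_%s_collapsed.nwk", fam)))
  }
  jsonlite::write_json(res$log, p("run_log.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
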