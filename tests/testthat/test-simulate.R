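test_that("event-free histories are single copy everywhere", {
  h <- simulate_history(seed = 1)
  expect_true(all(h$lineage_counts$count == 1))
  expect_equal(nrow(truth_pairs(h)), 0L)
})

test_that("WGD events double gene lineages in the affected lineage only", {
  h <- simulate_history(wgd_events = tibble::tibble(time = 12, species = "Gmax"),
                        seed = 2)
  counts <- setNames(h$lineage_counts$count, h$lineage_counts$species_node)
  expect_equal(counts[["Gmax"]], 2L)
  expect_equal(counts[["Mtruncatula"]], 1L)
  expect_equal(counts[["legumes"]], 1L)  # the parent node predates the WGD

  h2 <- simulate_history(wgd_events = tibble::tibble(time = c(55, 12), species = "Gmax"),
                         seed = 3)
  c2 <- setNames(h2$lineage_counts$count, h2$lineage_counts$species_node)
  expect_equal(c2[["Gmax"]], 4L)          # both WGDs compose
  expect_equal(c2[["Mtruncatula"]], 2L)   # the 55 mya WGD predates the split
  expect_error(simulate_history(wgd_events = tibble::tibble(time = 200, species = "Gmax")),
               "older than")
})

test_that("true pair times convert to the clock-expected Ks exactly", {
  h <- simulate_history(wgd_events = tibble::tibble(time = c(55, 12), species = "Gmax"),
                        tandem_events = tibble::tibble(time = 5, species = "Gmax"),
                        seed = 4)
  tp <- truth_pairs(h, lambda_rate = 6.1e-9)
  expect_true(all(abs(tp$expected_ks - 2 * 6.1e-9 * tp$time_mya * 1e6) < 1e-12))
  expect_true(any(tp$mechanism == "tandem"))
})

test_that("loci layout keeps tandem copies adjacent and anchors collinear", {
  h <- simulate_history(wgd_events = tibble::tibble(time = 12, species = "Gmax"),
                        tandem_events = tibble::tibble(time = 5, species = "Gmax"),
                        seed = 6)
  lay <- layout_loci(h, genes_per_segment = 13)
  gm <- lay$loci |> dplyr::filter(.data$species == "Gmax")
  fam <- h$tip_info |> dplyr::filter(species == "Gmax")
  # tandem pair: same chromosome, consecutive ranks
  tp <- truth_pairs(h) |> dplyr::filter(mechanism == "tandem", same_species)
  tp <- tp[tp$gene_a %in% gm$gene_id & tp$gene_b %in% gm$gene_id, ]
  expect_gte(nrow(tp), 1L)
  ra <- gm$rank[match(tp$gene_a[1], gm$gene_id)]
  rb <- gm$rank[match(tp$gene_b[1], gm$gene_id)]
  expect_equal(abs(ra - rb), 1L)

  hits <- anchor_hits(lay, h, "Gmax", "Gmax")
  bl <- chain_collinear(hits, lay$loci, 1e-10, 4)
  expect_gte(nrow(bl), 1L)
  expect_gte(max(bl$n_anchors), 12L)  # zero noise: full anchor recovery
})

test_that("rearrangement noise degrades anchor recovery monotonically", {
  h <- simulate_history(wgd_events = tibble::tibble(time = 12, species = "Gmax"),
                        seed = 7)
  rec <- vapply(c(0, 0.3, 0.8), function(noise) {
    lay <- layout_loci(h, genes_per_segment = 13, noise = noise, seed = 9)
    bl <- chain_collinear(anchor_hits(lay, h, "Gmax", "Gmax"), lay$loci, 1e-10, 1)
    if (!nrow(bl)) 0 else max(bl$n_anchors) / 13
  }, numeric(1))
  expect_equal(rec[1], 1)
  expect_lte(rec[2], rec[1])
  expect_lte(rec[3], rec[2])
  expect_lt(rec[3], 1)
})

test_that("codon simulation respects the clock calibration and omega limits", {
  pair <- ape::read.tree(text = "(a:10,b:10);")
  z <- evolve_codons(ape::read.tree(text = "(a:0,b:0);"), 50, seed = 1)
  expect_equal(z$seq[1], z$seq[2])

  s0 <- evolve_codons(pair, 300, site_omega = list(model = "M0", omega = 0), seed = 2)
  expect_equal(ng86_rates(s0$seq[1], s0$seq[2])$dn, 0)

  s <- evolve_codons(pair, 4000, site_omega = list(model = "M0", omega = 0.2), seed = 3)
  ks <- ng86_rates(s$seq[1], s$seq[2])$ds
  expect_lt(abs(ks - 0.122) / 0.122, 0.2)  # 2 * lambda * T at T = 10 mya
})

test_that("fixture bundles are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture("small", seed = 5, dir = d1)
  make_fixture("small", seed = 5, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
  }
})

test_that("fixture files parse with the package readers", {
  d <- withr::local_tempdir()
  make_fixture("small", seed = 5, dir = d)
  expect_s3_class(read_fasta(file.path(d, "anchors.fasta")), "tbl_df")
  expect_s3_class(read_loci_table(file.path(d, "loci.tsv")), "tbl_df")
  expect_s3_class(read_hits_table(file.path(d, "hits_within.tsv")), "tbl_df")
  expect_s3_class(read_newick(file.path(d, "species_tree.nwk")), "phylo")
  bundle <- read_fixture(d)
  expect_equal(names(bundle$families), "FAM")
})
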