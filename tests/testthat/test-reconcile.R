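two_sp <- ape::read.tree(text = "(A:1,B:1)R;")

test_that("congruent single-copy families reconcile to pure speciations", {
  gt <- ape::read.tree(text = "(a1:1,b1:1);")
  rec <- lca_reconcile(gt, two_sp,
                       tibble::tibble(gene_id = c("a1", "b1"), species_id = c("A", "B")))
  expect_true(all(rec$event[rec$event != "leaf"] == "speciation"))
  expect_equal(ancestral_gene_count(rec, "R"), 1L)
})

test_that("pre-split duplications are labelled and counted at the MRCA", {
  gt <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  map <- tibble::tibble(gene_id = c("a1", "b1", "a2", "b2"),
                        species_id = c("A", "B", "A", "B"))
  rec <- lca_reconcile(gt, two_sp, map)
  td <- tidy(rec)
  root_row <- td[td$node == length(gt$tip.label) + 1L, ]
  expect_equal(root_row$event, "duplication")
  expect_equal(ancestral_gene_count(rec, "R"), 2L)
})

test_that("post-split duplications do not inflate the ancestral count", {
  gt <- ape::read.tree(text = "((a1:1,a2:1):1,b1:2);")
  rec <- lca_reconcile(gt, two_sp,
                       tibble::tibble(gene_id = c("a1", "a2", "b1"),
                                      species_id = c("A", "A", "B")))
  td <- tidy(rec)
  expect_true("duplication" %in% td$event)
  expect_equal(td$species_node[td$event == "duplication"], "A")
  expect_equal(ancestral_gene_count(rec, "R"), 1L)
})

test_that("reconciliation preconditions are enforced", {
  gt <- ape::read.tree(text = "(a1:1,b1:1);")
  expect_error(lca_reconcile(gt, two_sp,
                             tibble::tibble(gene_id = c("a1", "b1"),
                                            species_id = c("A", "X"))),
               "unknown species")
  poly <- ape::read.tree(text = "((a1:1,a2:1,a3:1):1,b1:1);")
  expect_error(lca_reconcile(poly, two_sp,
                             tibble::tibble(gene_id = c("a1", "a2", "a3", "b1"),
                                            species_id = c("A", "A", "A", "B"))),
               "polytom")
  expect_error(ancestral_gene_count(
    lca_reconcile(gt, two_sp, tibble::tibble(gene_id = c("a1", "b1"),
                                             species_id = c("A", "B"))), "A"),
    "internal")
})

test_that("outgroup rooting places the root on the outgroup edge", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,rice:4):1);")
  rooted <- root_by_outgroup(tr, "rice")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1L, 2]
  expect_true(which(rooted$tip.label == "rice") %in% kids)
  # midpoint split of the stem edge
  lens <- rooted$edge.length[rooted$edge[, 1] == length(rooted$tip.label) + 1L]
  expect_equal(lens[1], lens[2])

  cherry <- ape::read.tree(text = "((a:1,b:1):1,(rice1:1,rice2:1):2);")
  r2 <- root_by_outgroup(cherry, c("rice1", "rice2"))
  expect_true(ape::is.monophyletic(r2, c("rice1", "rice2")))

  scattered <- ape::read.tree(text = "((rice1:1,b:1):1,(rice2:1,c:1):1);")
  expect_error(root_by_outgroup(scattered, c("rice1", "rice2")), "monophyletic")
})

test_that("ancestral counts recover simulated lineage counts exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    wgd <- tibble::tibble(time = runif(sample(0:2, 1), 5, 120), species = "Gmax")
    h <- simulate_history(wgd_events = wgd, tandem_rate = 0.005,
                          retention_prob = 1, seed = seed)
    rec <- lca_reconcile(h$gene_tree, h$species_tree,
                         h$tip_info |> dplyr::select(gene_id, species_id = species))
    got <- ancestral_gene_counts(rec)
    truth <- h$lineage_counts
    for (i in seq_len(nrow(got))) {
      expect_equal(got$ancestral_count[i],
                   truth$count[truth$species_node == got$species_node[i]],
                   info = sprintf("seed %d node %s", seed, got$species_node[i]))
    }
  }
})
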