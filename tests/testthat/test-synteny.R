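mk_loci <- function(ranks_a, ranks_b) {
  rank_loci(tibble::tibble(
    gene_id = c(paste0("a", ranks_a), paste0("b", ranks_b)),
    chromosome = rep(c("c1", "c2"), c(length(ranks_a), length(ranks_b))),
    start = c(ranks_a, ranks_b) * 1000,
    end = c(ranks_a, ranks_b) * 1000 + 500,
    strand = "+"))
}

test_that("perfectly collinear hits chain into one full block", {
  loci <- mk_loci(1:10, 1:10)
  hits <- tibble::tibble(query_id = paste0("a", 1:10), subject_id = paste0("b", 1:10),
                         identity_pct = 95, evalue = 1e-50)
  bl <- chain_collinear(hits, loci, 1e-10, 4)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$n_anchors, 10L)
  expect_equal(bl$orientation, "collinear")
})

test_that("the chain is the longest monotone subsequence", {
  loci <- mk_loci(1:3, 1:3)
  hits <- tibble::tibble(query_id = c("a1", "a2", "a3"),
                         subject_id = c("b1", "b3", "b2"),
                         identity_pct = 95, evalue = 1e-50)
  bl <- chain_collinear(hits, loci, 1e-10, min_anchors = 1)
  expect_equal(bl$n_anchors, 2L)
})

test_that("empty input and strict thresholds behave as contracted", {
  expect_equal(nrow(chain_collinear(tibble::tibble(query_id = character(),
                                                   subject_id = character(),
                                                   evalue = numeric()),
                                    mk_loci(1:2, 1:2))), 0L)
  loci <- mk_loci(1:10, 1:10)
  hits <- tibble::tibble(query_id = paste0("a", 1:10), subject_id = paste0("b", 1:10),
                         identity_pct = 95, evalue = 1e-9)
  expect_equal(nrow(chain_collinear(hits, loci, evalue_max = 1e-10)), 0L)
})

test_that("inverted blocks are detected and chaining ignores hit order", {
  loci <- mk_loci(1:8, 1:8)
  hits <- tibble::tibble(query_id = paste0("a", 1:8),
                         subject_id = paste0("b", 8:1),
                         identity_pct = 95, evalue = 1e-50)
  bl <- chain_collinear(hits, loci, 1e-10, 4)
  expect_equal(bl$orientation, "inverted")
  expect_equal(bl$n_anchors, 8L)
  set.seed(3)
  for (i in 1:5) {
    bl2 <- chain_collinear(hits[sample.int(8), ], loci, 1e-10, 4)
    expect_identical(bl2$anchors[[1]], bl$anchors[[1]])
  }
})

test_that("block anchors always satisfy the monotonicity invariant", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 12
    loci <- mk_loci(1:n, 1:n)
    hits <- tibble::tibble(query_id = paste0("a", sample.int(n)),
                           subject_id = paste0("b", sample.int(n)),
                           identity_pct = 90, evalue = 1e-40)
    bl <- chain_collinear(hits, loci, 1e-10, min_anchors = 1)
    for (i in seq_len(nrow(bl))) {
      a <- bl$anchors[[i]]
      expect_true(all(diff(a$rank_a) > 0))
      expect_true(all(diff(a$rank_b) > 0) || all(diff(a$rank_b) < 0))
    }
  }
})

test_that("dating anchors are the nearest on each side of the focal pair", {
  anchors <- tibble::tibble(gene_a = paste0("a", 1:17), gene_b = paste0("b", 1:17),
                            rank_a = 1:17, rank_b = 1:17)
  sel <- select_dating_anchors(anchors, "a9", "b9", max_per_side = 6)
  expect_equal(sel$gene_a, paste0("a", c(3:8, 10:15)))
  sel2 <- select_dating_anchors(anchors[c(6:9, 10:11), ], "a9", "b9", 6)
  expect_equal(nrow(sel2), 5L)
  edge <- select_dating_anchors(anchors, "a1", "b1", 6)
  expect_equal(edge$gene_a, paste0("a", 2:7))
  expect_error(select_dating_anchors(anchors, "zz", "b1", 6), "not an anchor")
})

test_that("cross-species support counts flanking hits under the strict cutoff", {
  loci <- rank_loci(tibble::tibble(
    gene_id = c("f", paste0("g", 1:6)),
    chromosome = "c1",
    start = c(400000, 1:6 * 10000 + 350000),
    end = c(403000, 1:6 * 10000 + 353000),
    strand = "+"))
  other <- rank_loci(tibble::tibble(
    gene_id = paste0("m", 1:6), chromosome = "mt1",
    start = 1:6 * 1000, end = 1:6 * 1000 + 500, strand = "+"))
  hits <- tibble::tibble(query_id = paste0("g", 1:5), subject_id = paste0("m", 1:5),
                         identity_pct = 90, evalue = 1e-30)
  res <- cross_species_support("f", loci, hits, other, 100000, 1e-10, 3)
  expect_true(res$supported)
  expect_equal(res$n_support, 5L)

  none <- cross_species_support("f", loci, hits[0, ], other, 100000, 1e-10, 3)
  expect_false(none$supported)

  at_cut <- dplyr::mutate(hits, evalue = 1e-10)  # exactly at the threshold
  res2 <- cross_species_support("f", loci, at_cut, other, 100000, 1e-10, 3)
  expect_false(res2$supported)
})
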