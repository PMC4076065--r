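test_that("NJ recovers the unique 3-taxon tree with closed-form lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  dd <- cophenetic(tr)
  expect_equal(dd[rownames(d), colnames(d)], d)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reconstructs the additive 4-taxon example exactly", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_true(same_topology(tr, ref))
  expect_equal(cophenetic(tr)[labs, labs], d)
})

test_that("tied Q-pairs are broken by the lexicographically smallest labels", {
  labs <- c("d", "c", "b", "a")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  tr1 <- nj_tree(d)
  tr2 <- nj_tree(d[rev(labs), rev(labs)])
  # fully tied distances: the first join must be the pair (a, b)
  expect_true(ape::is.monophyletic(tr1, c("a", "b")))
  expect_equal(ape::dist.topo(tr1, tr2), structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("NJ reconstructs random additive matrices exactly", {
  for (case in 1:8) {
    n <- sample(4:8, 1)
    oc <- random_additive_case(n, seed = 100 + case)
    tr <- nj_tree(oc$d)
    expect_true(same_topology(tr, oc$tree))
    expect_equal(cophenetic(tr)[rownames(oc$d), colnames(oc$d)], oc$d,
                 tolerance = 1e-9)
  }
})

test_that("bootstrap supports are high for well-separated clades and reproducible", {
  tr <- ape::read.tree(text = "((a:3,b:3):14,(c:3,d:3):14);")
  s <- evolve_codons(tr, 250, site_omega = list(model = "M0", omega = 0.3), seed = 5)
  bt1 <- bootstrap_nj(s, reps = 200, seed = 2)
  bt2 <- bootstrap_nj(s, reps = 200, seed = 2)
  expect_identical(bt1$node.label, bt2$node.label)
  sp <- attr(bt1, "splits")
  expect_gte(max(sp$support_pct), 95)
  expect_equal(attr(bt1, "n_dropped"), 0L)
})

test_that("degenerate alignments are flagged as star-tree outcomes", {
  s <- tibble::tibble(id = letters[1:4], seq = strrep("ACGT", 30))
  expect_warning(bt <- bootstrap_nj(s, reps = 20, seed = 1), "star tree")
  expect_true(attr(bt, "degenerate"))
  expect_equal(sort(bt$tip.label), letters[1:4])
})

test_that("collapsing is strict at the threshold and preserves leaves", {
  tr <- ape::read.tree(text = "((a:1,b:1)49:1,(c:1,d:1)50:1);")
  col <- collapse_low_support(tr, 50)
  expect_equal(sort(col$tip.label), sort(tr$tip.label))
  # the 49 edge collapses, the 50 edge stays (strict <)
  expect_equal(col$Nnode, tr$Nnode - 1L)
  expect_true(ape::is.monophyletic(col, c("c", "d")))

  all_high <- ape::read.tree(text = "((a:1,b:1)80:1,(c:1,d:1)90:1);")
  expect_equal(collapse_low_support(all_high, 50)$Nnode, all_high$Nnode)

  nested <- ape::read.tree(text = "(((a:1,b:1)30:1,c:1)80:1,(d:1,e:1)90:1);")
  col2 <- collapse_low_support(nested, 50)
  expect_equal(col2$Nnode, nested$Nnode - 1L)
  expect_false(ape::is.monophyletic(col2, c("a", "b")))
  expect_true(ape::is.monophyletic(col2, c("a", "b", "c")))
})

test_that("single low-support internal edge collapses to a star", {
  tr <- ape::read.tree(text = "((a:1,b:1)49:1,c:1,d:1);")
  col <- collapse_low_support(tr, 50)
  expect_equal(col$Nnode, 1L)
  expect_equal(length(col$tip.label), 4L)
})
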