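test_that("Jukes-Cantor correction matches the closed form", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.10732, tolerance = 1e-4)
  expect_equal(jc_distance(0.06), 0.06253, tolerance = 1e-4)
  expect_error(jc_distance(0.75), "saturation")
  expect_error(jc_distance(0.9), "saturation")
})

test_that("K2P distance matches the closed form and handles deletion", {
  a <- strrep("A", 100)
  expect_equal(k2p_distance(a, a), 0)
  # 10 transitions, 5 transversions over 100 sites
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(k2p_distance(a, b), 0.170181, tolerance = 1e-5)
  # gap/N columns excluded: distance computed over remaining 100 sites
  a2 <- paste0("N-", a); b2 <- paste0("AC", b)
  expect_equal(k2p_distance(a2, b2), k2p_distance(a, b))
  # saturation: P = 0.4, Q = 0.2
  c1 <- paste0(strrep("G", 40), strrep("C", 20), strrep("A", 40))
  expect_error(k2p_distance(a, c1), "saturation")
  expect_error(k2p_distance("---", "AAA"), "no complete columns")
})

test_that("nucleotide distances are symmetric and dominate the p-distance", {
  set.seed(42)
  for (i in 1:10) {
    n <- 60
    x <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    k1 <- try(k2p_distance(x, y), silent = TRUE)
    if (inherits(k1, "try-error")) next
    expect_equal(k1, k2p_distance(y, x))
    p <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    expect_gte(k1, p - 1e-12)
    expect_gte(jc_distance(min(p, 0.74)), min(p, 0.74) - 1e-12)
  }
})

test_that("nucleotide diversity is the mean JC distance over pairs", {
  s_same <- tibble::tibble(id = c("a", "b", "c"), seq = strrep("ACGT", 25))
  expect_equal(nucleotide_diversity(s_same)$pi, 0)

  # pairwise p-distances 0, 0.06, 0.06 over 100 sites
  base <- strrep("A", 100)
  mut <- paste0(strrep("C", 6), strrep("A", 94))
  s <- tibble::tibble(id = c("a", "b", "c"), seq = c(base, base, mut))
  expect_equal(nucleotide_diversity(s)$pi, 0.04169, tolerance = 1e-4)

  s2 <- s[c(1, 3), ]
  expect_equal(nucleotide_diversity(s2)$pi, jc_distance(0.06))
  expect_error(nucleotide_diversity(s[1, ]), "at least 2")
})

test_that("NG86 matches the hand-worked single-codon example", {
  r <- ng86_rates("TTT", "TTA")
  expect_equal(r$n_sites_S, 0.5)
  expect_equal(r$n_sites_N, 2.5)
  expect_equal(r$n_diff_N / r$n_sites_N, 0.4) # pN
  expect_equal(r$ds, 0)
  expect_true(is.na(r$omega))
})

test_that("NG86 is symmetric and zero for identical sequences", {
  r0 <- ng86_rates("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r0$dn, 0)
  expect_equal(r0$ds, 0)
  expect_true(is.na(r0$omega))
  set.seed(7)
  for (i in 1:5) {
    a <- rand_codon_seq(30); b <- rand_codon_seq(30)
    ra <- try(ng86_rates(a, b), silent = TRUE)
    if (inherits(ra, "try-error")) next
    expect_equal(ra, ng86_rates(b, a))
    expect_equal(ra$n_sites_N + ra$n_sites_S, 3 * ra$n_codons_used, tolerance = 1e-6)
  }
})

test_that("NG86 excludes codon columns with gaps or stops", {
  r <- ng86_rates("TTTTAAGGG", "TTATAGGGG")
  expect_equal(r$n_codons_used, 2L)  # middle codon is a stop in both
})

test_that("purely synonymous divergence gives dN exactly zero", {
  tr <- ape::read.tree(text = "(a:8,b:8);")
  s <- evolve_codons(tr, 400, site_omega = list(model = "M0", omega = 0), seed = 31)
  r <- ng86_rates(s$seq[1], s$seq[2])
  expect_equal(r$dn, 0)
  expect_gt(r$ds, 0)
})

test_that("NG86 length preconditions are enforced", {
  expect_error(ng86_rates("ATG", "ATGA"), "equal length")
  expect_error(ng86_rates("ATGA", "ATGA"), "multiple of 3")
})

test_that("omega formatting mirrors the report conventions", {
  expect_equal(format_omega(0.26, 0), "0.26e-2/0")
  expect_equal(format_omega(0, 0), "0/0")
  expect_equal(format_omega(0.2, 0.4), "0.50")
})
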