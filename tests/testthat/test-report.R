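test_that("family-size averages use the nonzero-species mean with half-up rounding", {
  counts <- tibble::tibble(
    family = rep(c("PAL", "CHR"), each = 7),
    species = rep(paste0("sp", 1:7), 2),
    n_genes = c(8, 6, 6, 5, 4, 11, 9,   2, 2, 4, 6, 0, 0, 0))
  fs <- family_size_summary(counts)
  expect_equal(fs$average[fs$family == "PAL"], 7)
  expect_equal(fs$average[fs$family == "CHR"], 4)  # mean over nonzero = 3.5

  single <- family_size_summary(c(spA = 5))
  expect_equal(single$average, 5)
  zero <- family_size_summary(c(spA = 0, spB = 0))
  expect_equal(zero$average, 0)
  expect_true(zero$all_zero)
})

test_that("group means are per-copy averages on the percent scale", {
  vals <- tibble::tibble(gene_id = paste0("g", 1:5),
                         value_pct = c(0.16, 0.03, 0.07, 0.09, 0.00))
  ann <- tibble::tibble(gene_id = paste0("g", 1:5), position = "upstream")
  gm <- group_means(vals, ann, "position")
  expect_equal(gm$mean_pct_2dp, 0.07)

  dn <- tibble::tibble(gene_id = paste0("d", 1:4),
                       value_pct = c(0.18, 0.37, 0.26, 0.35))
  gm2 <- group_means(dn, tibble::tibble(gene_id = paste0("d", 1:4),
                                        position = "downstream"), "position")
  expect_equal(gm2$mean_pct_2dp, 0.29)
  # order invariance
  gm3 <- group_means(dn[4:1, ], tibble::tibble(gene_id = paste0("d", 1:4),
                                               position = "downstream"), "position")
  expect_equal(gm3$mean_pct, gm2$mean_pct)
  expect_error(group_means(dn, tibble::tibble(gene_id = "d1", position = "x"),
                           "position"), "annotated")
})

test_that("the permutation test enumerates small problems exactly", {
  r <- permutation_test(c(0, 0), c(1, 1))
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$method, "exhaustive")
  same <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(permutation_test(numeric(0), 1), "non-empty")
})

test_that("Monte Carlo permutation P-values are seeded and corrected", {
  a <- rnorm(30, 0, 1); b <- rnorm(30, 1.5, 1)
  r1 <- permutation_test(a, b, n_permutations = 500, seed = 9, max_exhaustive = 10)
  r2 <- permutation_test(a, b, n_permutations = 500, seed = 9, max_exhaustive = 10)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$method, "monte_carlo")
  expect_gte(r1$p_value, 1 / 501)
})

test_that("permutation type-I error is close to nominal under the null", {
  set.seed(77)
  rejections <- 0L
  n_rep <- 500L
  for (i in seq_len(n_rep)) {
    x <- rnorm(5); y <- rnorm(5)
    if (permutation_test(x, y)$p_value <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("fold ratios follow the larger-over-smaller convention", {
  expect_equal(fold_ratio(0.28, 0.07), 4)
  expect_equal(fold_ratio(0.29, 0.01), 29)
  expect_equal(fold_ratio(0.2, 0.2), 1)
  expect_equal(fold_ratio(0.5, 0), Inf)
  expect_equal(fold_ratio(0, 0), 1)
})

test_that("rate tables render ratio cells and stars as printed", {
  stats <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          pi = c(0.0020, 0.0005, 0.0010),
                          dn = c(0.0026, 0, 0.0010),
                          ds = c(0, 0, 0.0040),
                          lrt_stat = c(1.13, NA, 25.15),
                          lrt_p = c(0.5, NA, 1e-5))
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        position = c("downstream", "downstream", "upstream"))
  rt <- build_rate_table(stats, ann, "position", pathevo_config(permutations = 200))
  expect_equal(rt$rows$dn_ds[rt$rows$gene_id == "g1"], "0.26e-2/0")
  expect_equal(rt$rows$dn_ds[rt$rows$gene_id == "g2"], "0/0")
  expect_equal(rt$rows$lrt[rt$rows$gene_id == "g3"], "25.15**")
  expect_true(is.na(rt$rows$lrt[rt$rows$gene_id == "g2"]))
  expect_equal(nrow(rt$groups), 3L)

  empty <- build_rate_table(stats[0, ], ann[0, ], "position")
  expect_equal(nrow(empty$rows), 0L)
})
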