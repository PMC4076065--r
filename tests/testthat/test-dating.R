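test_that("trimmed mean removes one minimum and one maximum", {
  expect_equal(trimmed_mean_ks(c(0.1, 0.2, 0.3))$ks_mean, 0.2)
  tm <- trimmed_mean_ks(c(0.1, 0.1, 0.5, 0.3))
  expect_equal(tm$ks_mean, 0.2)  # one 0.1 and the 0.5 removed
  expect_equal(tm$n_used, 2L)
  expect_warning(one <- trimmed_mean_ks(0.4), "without trimming")
  expect_equal(one$ks_mean, 0.4)
  expect_false(one$trimmed)
  expect_error(trimmed_mean_ks(numeric(0)), "empty")
  set.seed(5)
  for (i in 1:10) {
    v <- runif(sample(3:12, 1), 0, 2)
    m <- suppressWarnings(trimmed_mean_ks(v)$ks_mean)
    expect_gte(m, min(v)); expect_lte(m, max(v))
  }
})

test_that("the molecular clock maps Ks to the printed ages", {
  expect_equal(date_duplication(0.17), 13.93, tolerance = 1e-3)
  expect_equal(round_age(date_duplication(0.17)), 14L)
  expect_equal(date_duplication(0), 0)
  expect_equal(round_age(date_duplication(0.66)), 54L)
})

test_that("dating is linear in Ks and decreasing in the rate", {
  expect_equal(date_duplication(0.4), 2 * date_duplication(0.2))
  expect_lt(date_duplication(0.2, 1e-8), date_duplication(0.2, 6.1e-9))
})

blocks1 <- chain_collinear(
  tibble::tibble(query_id = paste0("a", 1:6), subject_id = paste0("b", 1:6),
                 identity_pct = 95, evalue = 1e-50),
  rank_loci(tibble::tibble(
    gene_id = c(paste0("a", 1:6), paste0("b", 1:6), paste0("x", 1:25)),
    chromosome = rep(c("c1", "c2", "c3"), c(6, 6, 25)),
    start = c(1:6 * 1000, 1:6 * 1000, 1:25 * 1000),
    end = c(1:6 * 1000 + 500, 1:6 * 1000 + 500, 1:25 * 1000 + 500),
    strand = "+")), 1e-10, 4)
loci1 <- rank_loci(tibble::tibble(
  gene_id = c(paste0("a", 1:6), paste0("b", 1:6), paste0("x", 1:25)),
  chromosome = rep(c("c1", "c2", "c3"), c(6, 6, 25)),
  start = c(1:6 * 1000, 1:6 * 1000, 1:25 * 1000),
  end = c(1:6 * 1000 + 500, 1:6 * 1000 + 500, 1:25 * 1000 + 500),
  strand = "+"))

test_that("pairs are classified segmental, tandem or dispersed", {
  cfg <- pathevo_config()
  dating <- date_from_anchors(c(0.12, 0.13, 0.14, 0.15))
  seg <- classify_pair("a3", "b3", blocks1, loci1, dating = dating, config = cfg)
  expect_equal(seg$mechanism, "segmental")
  expect_equal(seg$age_class, "recent")

  tand_old <- classify_pair("x1", "x2", blocks1, loci1,
                            outgroup_presence = TRUE, config = cfg)
  expect_equal(tand_old$mechanism, "tandem")
  expect_equal(tand_old$age_class, "old")
  tand_new <- classify_pair("x1", "x2", blocks1, loci1,
                            outgroup_presence = FALSE, config = cfg)
  expect_equal(tand_new$age_class, "recent")

  disp <- classify_pair("x1", "x22", blocks1, loci1, config = cfg)
  expect_equal(disp$mechanism, "dispersed")
})

test_that("a segmental pair without dating is flagged ambiguous", {
  expect_warning(call <- classify_pair("a3", "b3", blocks1, loci1, dating = NULL),
                 "ambiguous")
  expect_equal(call$mechanism, "segmental")
  expect_equal(call$age_class, "ambiguous")
})

test_that("duplication events merge pairs by the stated conventions", {
  calls <- dplyr::bind_rows(
    tibble::tibble(gene_a = "g1", gene_b = "g2", mechanism = "tandem",
                   age_class = "recent", age_mya = NA_real_,
                   block_id = NA_character_, shared_with_outgroup = FALSE,
                   family = "F1"),
    tibble::tibble(gene_a = "g2", gene_b = "g3", mechanism = "tandem",
                   age_class = "recent", age_mya = NA_real_,
                   block_id = NA_character_, shared_with_outgroup = FALSE,
                   family = "F1"),
    tibble::tibble(gene_a = "s1", gene_b = "s2", mechanism = "segmental",
                   age_class = "recent", age_mya = 11, block_id = "b1",
                   shared_with_outgroup = NA, family = "F1"))
  tab <- tabulate_duplications(calls, families = c("F1", "F2"))
  expect_equal(tab$tandem_recent[tab$family == "F1"], 2L)   # 3-gene array
  expect_equal(tab$segmental_recent[tab$family == "F1"], 1L) # one block
  expect_equal(unlist(tab[tab$family == "F2", -1]), rep(0L, 5), ignore_attr = TRUE)
})

test_that("every printed segment-pair age follows from its printed Ks", {
  tab <- readr::read_tsv(system.file("extdata", "segment_dating.tsv",
                                     package = "pathevo"),
                         show_col_types = FALSE)
  recomputed <- vapply(tab$ks_mean, function(k) round_age(date_duplication(k)), integer(1))
  expect_equal(recomputed, tab$reported_mya)
})
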