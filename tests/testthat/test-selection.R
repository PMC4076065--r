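eight_taxa <- ape::read.tree(
  text = "(((a:15,b:15):15,(c:15,d:15):15):15,((e:15,f:15):15,(g:15,h:15):15):15);")

test_that("beta discretization has the stated class structure", {
  u <- discretize_beta(1, 1, 10)
  expect_equal(u$omega, seq(0.05, 0.95, by = 0.1), tolerance = 1e-9)
  expect_equal(u$weight, rep(0.1, 10))
  for (pq in list(c(0.3, 2), c(2, 0.5), c(5, 5))) {
    d <- discretize_beta(pq[1], pq[2], 10)
    expect_true(all(diff(d$omega) > 0))
    expect_equal(sum(d$weight * d$omega), pq[1] / sum(pq), tolerance = 1e-3)
  }
  expect_error(discretize_beta(-1, 1, 10), "positive")
})

test_that("the no-evolution limit reduces to codon frequencies", {
  seqs <- tibble::tibble(id = c("a", "b", "c"), seq = rep("ATGGCTAAA", 3))
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  pi <- f3x4_frequencies(seqs)
  ll <- gy94_loglik(seqs, star, kappa = 2, class_weights = 1, class_omegas = 0.4)
  expect_equal(ll, log(pi[["ATG"]]) + log(pi[["GCT"]]) + log(pi[["AAA"]]))
})

test_that("a one-class mixture equals the M0 likelihood", {
  s <- evolve_codons(eight_taxa, 60, site_omega = list(model = "M0", omega = 0.3),
                     seed = 21)
  l1 <- gy94_loglik(s, eight_taxa, 2, 1, 0.3)
  l2 <- gy94_loglik(s, eight_taxa, 2, c(0.5, 0.5), c(0.3, 0.3))
  expect_equal(l1, l2, tolerance = 1e-9)
  expect_error(gy94_loglik(s, eight_taxa, 2, c(0.5, 0.4), c(0.3, 0.3)), "sum to 1")
})

test_that("pruning matches a direct pairwise matrix-exponential oracle", {
  pair <- ape::read.tree(text = "(a:0.25,b:0.4);")
  s <- evolve_codons(ape::read.tree(text = "(a:10,b:10);"), 60,
                     site_omega = list(model = "M0", omega = 0.5), seed = 9)
  pi <- f3x4_frequencies(s)
  kap <- 1.8; w <- c(0.7, 0.3); oms <- c(0.15, 1.1)
  ll <- gy94_loglik(s, pair, kap, w, oms)

  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  nuc <- do.call(rbind, strsplit(codons, ""))
  Qof <- function(om) {
    Q <- matrix(0, 61, 61)
    for (i in 1:61) for (j in 1:61) {
      if (i == j) next
      d <- which(nuc[i, ] != nuc[j, ]); if (length(d) != 1) next
      ts <- paste0(sort(c(nuc[i, d], nuc[j, d])), collapse = "") %in% c("AG", "CT")
      Q[i, j] <- pi[j] * (if (ts) kap else 1) *
        (if (code[codons[i]] != code[codons[j]]) om else 1)
    }
    diag(Q) <- -rowSums(Q); Q
  }
  rate <- -sum(vapply(1:2, function(k) w[k] * sum(pi * diag(Qof(oms[k]))), 0))
  m <- do.call(rbind, strsplit(s$seq, ""))
  i1 <- match(vapply(seq(1, ncol(m), 3), function(p) paste(m[1, p:(p + 2)], collapse = ""), ""), codons)
  i2 <- match(vapply(seq(1, ncol(m), 3), function(p) paste(m[2, p:(p + 2)], collapse = ""), ""), codons)
  site <- 0
  for (k in 1:2) {
    P <- as.matrix(Matrix::expm(Qof(oms[k]) / rate * 0.65))
    site <- site + w[k] * pi[i1] * P[cbind(i1, i2)]
  }
  expect_equal(ll, sum(log(site)), tolerance = 1e-8)
})

test_that("likelihood is invariant to permuting sequences with their leaves", {
  s <- evolve_codons(eight_taxa, 50, site_omega = list(model = "M0", omega = 0.3),
                     seed = 3)
  ll1 <- gy94_loglik(s, eight_taxa, 2, 1, 0.3)
  perm <- s[sample(nrow(s)), ]
  ll2 <- gy94_loglik(perm, eight_taxa, 2, 1, 0.3, codon_freqs = f3x4_frequencies(s))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("transition matrices are stochastic and preserve the stationary law", {
  ct <- pathevo:::gy94_code_tables()
  pi <- pathevo:::codon_freqs_from_nuc(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  for (t in c(0.05, 0.5, 2)) {
    P <- pathevo:::gy94_pmat_cpp(unname(pi), 2, 0.4, t, 1, 0.4, ct$nuc, ct$aa)
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-9)
    expect_equal(as.numeric(unname(pi) %*% P), unname(pi), tolerance = 1e-9)
  }
})

test_that("M0 recovers the simulated omega", {
  s <- evolve_codons(eight_taxa, 300, site_omega = list(model = "M0", omega = 0.2),
                     seed = 11)
  f0 <- fit_site_model(s, eight_taxa, "M0", n_starts = 1)
  expect_lt(abs(f0$omega_params$omega - 0.2), 0.1)
  expect_lt(abs(f0$kappa - 2), 1)
})

test_that("identical sequences give equal M7 and M8 likelihoods", {
  seqs <- tibble::tibble(id = letters[1:4], seq = rep(strrep("ATGGCTTCA", 8), 4))
  star <- ape::read.tree(text = "(a:0.01,b:0.01,c:0.01,d:0.01);")
  res <- site_model_lrt(seqs, star, n_starts = 1)
  expect_lt(res$lrt$stat, 0.02)
  expect_gte(res$fit8$loglik, res$fit7$loglik - 1e-4)
})

test_that("M8 never reports a lower likelihood than its nested M7 start", {
  s <- evolve_codons(eight_taxa, 120, site_omega = list(model = "beta", p = 1, q = 2),
                     seed = 17)
  res <- site_model_lrt(s, eight_taxa, n_starts = 1)
  expect_gte(res$fit8$loglik, res$fit7$loglik - 1e-4)
  expect_gte(res$lrt$stat, 0)
})

test_that("the LRT uses a chi-square with 2 degrees of freedom", {
  f7 <- structure(list(model = "M7", loglik = -100, data_key = "k"),
                  class = "site_model_fit")
  f8 <- structure(list(model = "M8", loglik = -100, data_key = "k"),
                  class = "site_model_fit")
  r <- lrt_m7_m8(f7, f8)
  expect_equal(r$stat, 0)
  expect_equal(r$p_value, 1)
  f8$loglik <- -100 + 5.99 / 2
  r2 <- lrt_m7_m8(f7, f8)
  expect_equal(r2$p_value, 0.0500, tolerance = 1e-3)
  f8$loglik <- -100 + 9.3 / 2
  expect_equal(lrt_m7_m8(f7, f8)$significant_at, "0.01")
  f8$data_key <- "other"
  expect_error(lrt_m7_m8(f7, f8), "same alignment")
})

test_that("tidy and glance summarise fits", {
  s <- evolve_codons(eight_taxa, 60, site_omega = list(model = "M0", omega = 0.3),
                     seed = 2)
  f <- fit_site_model(s, eight_taxa, "M0", n_starts = 1)
  td <- tidy(f)
  expect_true(all(c("kappa", "omega", "branch_scale") %in% td$term))
  g <- glance(f)
  expect_equal(g$model, "M0")
  expect_equal(g$n_codons, 60L)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})

test_that("site posteriors are proper distributions over classes", {
  s <- evolve_codons(eight_taxa, 40, site_omega = list(model = "beta", p = 1, q = 2),
                     seed = 4)
  f <- fit_site_model(s, eight_taxa, "M7", n_starts = 1)
  sp <- site_posteriors(f, s, eight_taxa)
  sums <- sp |> dplyr::group_by(codon) |> dplyr::summarise(tot = sum(posterior))
  expect_equal(sums$tot, rep(1, nrow(sums)), tolerance = 1e-8)
})
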