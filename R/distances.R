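# Pairwise evolutionary distances: Jukes-Cantor, Kimura 2-parameter,
# nucleotide diversity, and Nei-Gojobori (1986) dN/dS.

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) log(1 - 4p/3)`, defined for `0 <= p < 0.75`.
#'
#' @param p Observed proportion of differing sites.
#' @return Substitutions per site.
#' @examples
#' jc_distance(0.1)
#' @export
jc_distance <- function(p) {
  stopifnot_scalar_number(p, "p")
  if (p < 0) abort("p must be >= 0")
  if (p >= 0.75) abort(sprintf("Jukes-Cantor saturation: p = %.4f >= 0.75", p))
  -0.75 * log(1 - 4 * p / 3)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns where either sequence carries a gap or `N` are excluded (complete
#' deletion). With `P` and `Q` the transition and transversion proportions over
#' the retained sites, `K = -(1/2) log(1-2P-Q) - (1/4) log(1-2Q)`.
#'
#' @param a,b Aligned sequences (character strings of equal length).
#' @return Substitutions per site.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")
#' @export
k2p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) abort("sequences must be aligned (equal length)")
  keep <- !(x %in% c("-", "N") | y %in% c("-", "N"))
  n <- sum(keep)
  if (n == 0L) abort("no complete columns retained for K2P distance")
  x <- x[keep]; y <- y[keep]
  diff <- x != y
  ts <- diff & ((x == "A" & y == "G") | (x == "G" & y == "A") |
                  (x == "C" & y == "T") | (x == "T" & y == "C"))
  P <- sum(ts) / n
  Q <- (sum(diff) - sum(ts)) / n
  k2p_from_props(P, Q)
}

k2p_from_props <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf("K2P saturation: P = %.4f, Q = %.4f", P, Q))
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs Aligned sequences (tibble with `id`, `seq`).
#' @return A symmetric matrix of substitutions/site, labelled by sequence id.
#' @export
k2p_matrix <- function(seqs) {
  m <- seq_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ss <- apply(m, 1L, paste, collapse = "")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(ss[i], ss[j])
    }
  }
  d
}

#' Nucleotide diversity (pi) with Jukes-Cantor correction
#'
#' Columns with a gap or `N` in any sequence are excluded (complete deletion);
#' pi is the mean over all unordered sequence pairs of the Jukes-Cantor
#' corrected pairwise p-distance.
#'
#' @param seqs Aligned sequences (tibble with `id`, `seq`), at least two.
#' @return A one-row tibble: `pi` (substitutions/site), `n_sequences`,
#'   `n_sites_used`.
#' @export
nucleotide_diversity <- function(seqs) {
  m <- seq_matrix(seqs)
  if (nrow(m) < 2L) abort("nucleotide diversity needs at least 2 sequences")
  drop <- incomplete_columns(m)
  if (length(drop)) m <- m[, -drop, drop = FALSE]
  n_sites <- ncol(m)
  if (n_sites == 0L) abort("no complete columns retained")
  n <- nrow(m)
  dists <- combn(n, 2L, function(ij) {
    p <- mean(m[ij[1L], ] != m[ij[2L], ])
    jc_distance(p)
  })
  tibble(pi = mean(dists), n_sequences = n, n_sites_used = n_sites)
}

# ---- Nei-Gojobori (1986) ---------------------------------------------------

# memoised codon bookkeeping: the 61 sense codons, their nucleotide triplets,
# amino acids, per-codon synonymous site fractions (changes to stop codons are
# excluded from both numerator and denominator), and per-pair substitution
# counts averaged over mutational pathways (pathways through stops discarded).
codon_env <- new.env(parent = emptyenv())

#' @noRd
codon_tables <- function() {
  if (!is.null(codon_env$tables)) return(codon_env$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  aa <- unname(code[codons])
  nucs <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  nuc <- t(vapply(strsplit(codons, "", fixed = TRUE),
                  function(x) nucs[x], integer(3L)))
  dimnames(nuc) <- NULL
  idx <- setNames(seq_along(codons), codons)

  # synonymous site count per codon
  syn_sites <- vapply(codons, function(cod) {
    chars <- strsplit(cod, "", fixed = TRUE)[[1]]
    s <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(c("A", "C", "G", "T"), chars[p]), function(nt) {
        alt <- chars; alt[p] <- nt; paste(alt, collapse = "")
      }, character(1))
      valid <- alts[code[alts] != "*"]
      if (length(valid)) s <- s + sum(code[valid] == code[cod]) / length(valid)
    }
    s
  }, numeric(1))

  codon_env$tables <- list(codons = codons, aa = aa, nuc = nuc, idx = idx,
                           syn_sites = unname(syn_sites), code = code)
  codon_env$tables
}

# average (synonymous, nonsynonymous) substitution counts between two codons
# over all valid mutational pathways
codon_pair_counts <- function(c1, c2, code) {
  if (c1 == c2) return(c(0, 0))
  x <- strsplit(c1, "", fixed = TRUE)[[1]]
  y <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(x != y)
  paths <- if (length(pos) == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    perms(pos)
  }
  tally <- function(order) {
    cur <- x
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- y[p]
      to <- paste(nxt, collapse = "")
      if (code[to] == "*") return(NULL)  # path through a stop (endpoints are sense)
      from <- paste(cur, collapse = "")
      if (code[from] == code[to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, tally))
  if (!length(res)) {
    # all pathways blocked by stops (only possible for 3-difference pairs);
    # fall back to averaging over all orders, ignoring the stop rule
    tally_all <- function(order) {
      cur <- x; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- y[p]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        same <- !is.na(code[from]) && !is.na(code[to]) && code[from] == code[to] &&
          code[from] != "*"
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(paths, tally_all)
  }
  colMeans(do.call(rbind, res))
}

pair_count_tables <- function() {
  if (!is.null(codon_env$pair_counts)) return(codon_env$pair_counts)
  tb <- codon_tables()
  n <- length(tb$codons)
  sd <- matrix(0, n, n)
  nd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- codon_pair_counts(tb$codons[i], tb$codons[j], tb$code)
      sd[i, j] <- sd[j, i] <- cnt[1]
      nd[i, j] <- nd[j, i] <- cnt[2]
    }
  }
  codon_env$pair_counts <- list(sd = sd, nd = nd)
  codon_env$pair_counts
}

#' Nei-Gojobori (1986) pairwise substitution rates
#'
#' Computes synonymous (`ds`) and nonsynonymous (`dn`) substitutions per site
#' between two aligned coding sequences under the universal genetic code.
#' Codon columns containing a gap, `N`, or a stop codon in either member are
#' excluded. Site counts use per-position synonymous fractions with mutations
#' to stop codons removed from both numerator and denominator, averaged over
#' the two sequences; codons differing at several positions average their
#' substitution counts over all mutational pathways that avoid stop codons.
#' The proportions are Jukes-Cantor corrected. `omega = dn/ds` is `NA`
#' ("undefined") when `ds = 0`.
#'
#' @param a,b Aligned coding sequences (strings, equal length, multiple of 3).
#' @return A one-row tibble: `dn`, `ds`, `omega`, `n_sites_N`, `n_sites_S`,
#'   `n_diff_N`, `n_diff_S`, `n_codons_used`.
#' @examples
#' ng86_rates("TTT", "TTA")
#' @export
ng86_rates <- function(a, b) {
  cnt <- ng86_counts(a, b)
  S <- cnt$n_sites_S; N <- cnt$n_sites_N
  Sd <- cnt$n_diff_S; Nd <- cnt$n_diff_N
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75) abort(sprintf("NG86 saturation: pS = %.4f >= 0.75", pS))
  if (pN >= 0.75) abort(sprintf("NG86 saturation: pN = %.4f >= 0.75", pN))
  ds <- jc_distance(pS)
  dn <- jc_distance(pN)
  tibble(dn = dn, ds = ds,
         omega = if (ds == 0) NA_real_ else dn / ds,
         n_sites_N = N, n_sites_S = S,
         n_diff_N = Nd, n_diff_S = Sd,
         n_codons_used = cnt$n_codons_used)
}

#' NG86 site and difference counts (no distance correction)
#'
#' The counting half of [ng86_rates()]: averaged synonymous/nonsynonymous
#' site counts and pathway-averaged substitution counts, without the
#' Jukes-Cantor step (so it is defined even where the correction saturates).
#'
#' @inheritParams ng86_rates
#' @return A one-row tibble: `n_sites_N`, `n_sites_S`, `n_diff_N`,
#'   `n_diff_S`, `n_codons_used`.
#' @export
ng86_counts <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) abort("sequences must be aligned (equal length)")
  if (nchar(a) %% 3L != 0L) abort("sequence length is not a multiple of 3")
  m <- seq_matrix(c(a = a, b = b))
  drop <- incomplete_codon_columns(m)
  nc <- ncol(m) %/% 3L
  keep <- setdiff(seq_len(nc), drop)
  if (!length(keep)) abort("no complete codon columns retained")
  tb <- codon_tables()
  pc <- pair_count_tables()
  codon_at <- function(row, k) paste(m[row, (3L * k - 2L):(3L * k)], collapse = "")
  ia <- tb$idx[vapply(keep, function(k) codon_at(1L, k), character(1))]
  ib <- tb$idx[vapply(keep, function(k) codon_at(2L, k), character(1))]
  S <- sum((tb$syn_sites[ia] + tb$syn_sites[ib]) / 2)
  tibble(n_sites_N = 3 * length(keep) - S, n_sites_S = S,
         n_diff_N = sum(pc$nd[cbind(ia, ib)]),
         n_diff_S = sum(pc$sd[cbind(ia, ib)]),
         n_codons_used = length(keep))
}

#' Pairwise distance and rate table for a set of aligned coding sequences
#'
#' One row per unordered sequence pair with the K2P nucleotide distance and
#' NG86 `dn`, `ds`, `omega`.
#'
#' @param seqs Aligned coding sequences (tibble with `id`, `seq`).
#' @return A tibble: `gene_a`, `gene_b`, `k2p`, `dn`, `ds`, `omega`.
#' @export
pairwise_rates <- function(seqs) {
  m <- seq_matrix(seqs)
  ids <- rownames(m)
  ss <- apply(m, 1L, paste, collapse = "")
  pairs <- combn(length(ids), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1L, c0]; j <- pairs[2L, c0]
    r <- ng86_rates(ss[i], ss[j])
    tibble(gene_a = ids[i], gene_b = ids[j],
           k2p = k2p_distance(ss[i], ss[j]),
           dn = r$dn, ds = r$ds, omega = r$omega)
  })
}

#' Average NG86 rates over all sequence pairs of a population alignment
#'
#' Returns copy-level summary rates: all-pairs average `dn`, `ds` and their
#' ratio (undefined when the mean `ds` is 0).
#'
#' @param seqs Aligned coding sequences (tibble with `id`, `seq`).
#' @return A one-row tibble: `dn`, `ds`, `omega`, `n_pairs`.
#' @export
mean_pairwise_rates <- function(seqs) {
  pr <- pairwise_rates(seqs)
  dn <- mean(pr$dn); ds <- mean(pr$ds)
  tibble(dn = dn, ds = ds,
         omega = if (ds == 0) NA_real_ else dn / ds,
         n_pairs = nrow(pr))
}

#' Format a dN/dS ratio as printed in rate tables
#'
#' When `ds` is zero the ratio is undefined and rendered `"<dn>e-2/0"` (or
#' `"0/0"` when both are zero), with `dn` on the percent scale; otherwise the
#' numeric ratio with two decimals.
#'
#' @param dn_pct,ds_pct Rates on the percent scale.
#' @return A character scalar.
#' @examples
#' format_omega(0.26, 0) # "0.26e-2/0"
#' @export
format_omega <- function(dn_pct, ds_pct) {
  if (ds_pct == 0) {
    if (dn_pct == 0) return("0/0")
    return(sprintf("%.2fe-2/0", dn_pct))
  }
  sprintf("%.2f", dn_pct / ds_pct)
}
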