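# Independent oracles used across tests. These deliberately re-derive results
# with different code paths (plain recursion, path-length sums, dense matrix
# exponentials) so they cannot share bugs with the package implementation.

# --- Nei-Gojobori brute force ----------------------------------------------

ng86_oracle_code <- Biostrings::GENETIC_CODE
ng86_oracle_codons <- names(ng86_oracle_code)[ng86_oracle_code != "*"]

# synonymous site count of one codon, stop mutations dropped from numerator
# and denominator
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == chars[pos]) next
      mut <- chars; mut[pos] <- nt
      mut <- paste(mut, collapse = "")
      if (ng86_oracle_code[[mut]] == "*") next
      valid <- valid + 1
      if (ng86_oracle_code[[mut]] == ng86_oracle_code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# enumerate substitution pathways between two codons; returns average
# (synonymous, nonsynonymous) counts over pathways avoiding stops
oracle_pathways <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(cur, remaining, allow_stops) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (ri in seq_along(remaining)) {
      p <- remaining[ri]
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      if (!allow_stops && ng86_oracle_code[[nxt]] == "*") next
      step <- if (ng86_oracle_code[[cur]] != "*" && ng86_oracle_code[[nxt]] != "*" &&
                  ng86_oracle_code[[cur]] == ng86_oracle_code[[nxt]]) c(1, 0) else c(0, 1)
      for (rest in walk(nxt, remaining[-ri], allow_stops)) {
        out[[length(out) + 1]] <- step + rest
      }
    }
    out
  }
  res <- walk(c1, pos, allow_stops = FALSE)
  if (!length(res)) res <- walk(c1, pos, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

# full NG86 computation for two codon strings via the oracle pieces
oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- sum((vapply(ca, oracle_syn_sites, 0) + vapply(cb, oracle_syn_sites, 0)) / 2)
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    cnt <- oracle_pathways(ca[i], cb[i])
    sd <- sd + cnt[1]; nd <- nd + cnt[2]
  }
  list(S = S, N = N, Sd = sd, Nd = nd)
}

# --- additive distance matrices --------------------------------------------

# random tree plus its exact path-length distance matrix
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  d <- cophenetic(tr)
  list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
}

# --- misc -------------------------------------------------------------------

rand_codon_seq <- function(n_codons) {
  paste(sample(ng86_oracle_codons, n_codons, replace = TRUE), collapse = "")
}

# unrooted topology comparison
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
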