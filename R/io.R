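#' Read a FASTA file of nucleotide sequences
#'
#' Records are returned in file order with residues upper-cased and `U`
#' mapped to `T`; the alphabet is restricted to `A,C,G,T,N,-`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "acga"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    abort(sprintf("malformed FASTA: line %d of %s does not start a record", nonblank[1], path))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) abort(sprintf("malformed FASTA header (empty id) in %s", path))
  if (anyDuplicated(ids)) abort(sprintf("duplicate FASTA ids in %s", path))
  ss <- chartr("u", "t", toupper(as.character(set)))
  ss <- chartr("U", "T", ss)
  if (any(!nzchar(ss))) abort(sprintf("empty sequence record in %s", path))
  validate_residues(ss, where = path)
  tibble(id = ids, seq = unname(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-position table
#'
#' Expects a TSV with columns `gene_id`, `chromosome`, `start`, `end`,
#' `strand`, BED-style 0-based half-open coordinates. A `rank` column (ordinal
#' position along each chromosome by ascending start) is added.
#'
#' @param path Path to the TSV file.
#' @return A tibble of gene loci with a per-chromosome `rank` column.
#' @export
read_loci_table <- function(path) {
  loci <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            gene_id = readr::col_character(),
                            chromosome = readr::col_character(),
                            start = readr::col_double(),
                            end = readr::col_double(),
                            strand = readr::col_character()))
  rank_loci(loci)
}

#' Assign per-chromosome gene ranks
#'
#' Validates loci (start < end, unique gene ids, strand in `+`/`-`) and
#' assigns `rank`, the 0-based ordinal position along each chromosome by
#' ascending start.
#'
#' @param loci Tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @return The loci tibble ordered by chromosome and start, with `rank`.
#' @export
rank_loci <- function(loci) {
  req <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(req, names(loci))
  if (length(missing_cols)) abort(sprintf("loci table missing columns: %s", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(loci$gene_id)) {
    abort(sprintf("duplicate gene_id in loci table: %s",
                  paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", ")))
  }
  bad <- loci$start >= loci$end
  if (any(bad)) abort(sprintf("start >= end for gene(s): %s", paste(loci$gene_id[bad], collapse = ", ")))
  if (!all(loci$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  loci |>
    arrange(.data$chromosome, .data$start) |>
    group_by(.data$chromosome) |>
    mutate(rank = row_number() - 1L) |>
    ungroup()
}

#' Write a loci table
#' @param loci Loci tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_table <- function(loci, path) {
  readr::write_tsv(loci, path)
  invisible(path)
}

#' Read a pairwise homology-hit table
#'
#' TSV with columns `query_id`, `subject_id`, `identity_pct`, `evalue`
#' (BLAST outfmt6-like subset).
#'
#' @param path Path to the TSV file.
#' @return A tibble of hits.
#' @export
read_hits_table <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            query_id = readr::col_character(),
                            subject_id = readr::col_character(),
                            identity_pct = readr::col_double(),
                            evalue = readr::col_double()))
  if (any(hits$evalue < 0)) abort("negative E-value in hits table")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100)) abort("identity_pct outside [0,100]")
  hits
}

#' Read a newick tree
#'
#' Numeric internal node labels are interpreted as bootstrap support
#' percentages. Reading and writing round-trip topology, branch lengths and
#' supports.
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) abort(sprintf("empty newick file: %s", path))
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) abort(sprintf("unbalanced parentheses in %s", path))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) abort(sprintf("newick parse error in %s: %s", path, conditionMessage(e))))
  if (is.null(tree)) abort(sprintf("newick parse error in %s", path))
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) abort("negative branch length")
  tree
}

#' Write a newick tree
#'
#' Bootstrap supports (node labels) are preserved.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a codon alignment
#'
#' Checks that all members have equal length, that the length is a multiple
#' of three, and that residues are in `A,C,G,T,N,-`.
#'
#' @param seqs Tibble with `id`, `seq` columns (aligned coding sequences).
#' @return `seqs` invisibly (errors on violation).
#' @export
validate_codon_alignment <- function(seqs) {
  m <- seq_matrix(seqs)
  validate_residues(apply(m, 1L, paste, collapse = ""))
  if (ncol(m) %% 3L != 0L) abort("alignment length is not a multiple of 3")
  if (nrow(m) < 1L) abort("alignment has no sequences")
  invisible(seqs)
}

# columns (nt) with a gap or N in any sequence; "complete deletion" removes
# these before distance computation
incomplete_columns <- function(mat) {
  which(apply(mat, 2L, function(col) any(col %in% c("-", "N"))))
}

# codon columns (index of codon, 1-based) containing a gap/N or a stop codon
# in any member
incomplete_codon_columns <- function(mat) {
  nc <- ncol(mat) %/% 3L
  stops <- c("TAA", "TAG", "TGA")
  drop <- logical(nc)
  for (k in seq_len(nc)) {
    block <- mat[, (3L * k - 2L):(3L * k), drop = FALSE]
    if (any(block %in% c("-", "N"))) { drop[k] <- TRUE; next }
    cods <- apply(block, 1L, paste, collapse = "")
    if (any(cods %in% stops)) drop[k] <- TRUE
  }
  which(drop)
}
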