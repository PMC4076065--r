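# shared internal helpers

# round half away from zero; report tables and printed averages use this, not
# base round(), so that e.g. 2.5 -> 3 and 3.5 -> 4
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a reproducible substream seed from the master seed; offsets are fixed
# per stage so all stochastic stages are independent but replayable
substream_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% .Machine$integer.max
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}

# convert an id/seq tibble (or named character vector) to a character matrix of
# single residues, rows named by sequence id
seq_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    ss <- seqs$seq
  } else {
    ids <- names(seqs)
    ss <- unname(seqs)
  }
  if (is.null(ids) || anyNA(ids) || any(ids == "")) abort("sequences must carry non-empty ids")
  if (anyDuplicated(ids)) abort("duplicate sequence ids")
  lens <- nchar(ss)
  if (length(unique(lens)) != 1L) abort("sequences must be aligned (equal lengths)")
  m <- matrix(unlist(strsplit(ss, "", fixed = TRUE), use.names = FALSE),
              nrow = length(ss), byrow = TRUE)
  rownames(m) <- ids
  m
}

seqs_tibble <- function(mat) {
  tibble(id = rownames(mat), seq = apply(mat, 1L, paste, collapse = ""))
}

validate_residues <- function(x, where = "sequence") {
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)),
                 c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N,-}: %s",
                  where, paste(bad, collapse = ", ")))
  }
  invisible(x)
}
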