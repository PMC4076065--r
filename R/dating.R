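# Molecular-clock dating of segmental duplications from anchor Ks values and
# classification of duplicate pairs by mechanism and age.

#' Trimmed mean of anchor Ks values
#'
#' For three or more values, exactly one instance of the minimum and one of
#' the maximum are removed before taking the arithmetic mean and standard
#' deviation; for one or two values the plain mean is returned with
#' `trimmed = FALSE` (and a warning).
#'
#' @param ks_values Non-negative numeric vector of per-anchor Ks values.
#' @return A one-row tibble: `ks_mean`, `ks_sd`, `n_used`, `trimmed`.
#' @examples
#' trimmed_mean_ks(c(0.1, 0.1, 0.5, 0.3))
#' @export
trimmed_mean_ks <- function(ks_values) {
  if (!length(ks_values)) abort("ks_values is empty")
  if (any(!is.finite(ks_values)) || any(ks_values < 0)) abort("ks_values must be finite and >= 0")
  if (length(ks_values) <= 2L) {
    warn("fewer than 3 Ks values: mean taken without trimming")
    return(tibble(ks_mean = mean(ks_values),
                  ks_sd = if (length(ks_values) > 1L) sd(ks_values) else NA_real_,
                  n_used = length(ks_values), trimmed = FALSE))
  }
  v <- sort(ks_values)
  v <- v[-c(1L, length(v))]
  tibble(ks_mean = mean(v), ks_sd = if (length(v) > 1L) sd(v) else NA_real_,
         n_used = length(v), trimmed = TRUE)
}

#' Date a duplication from its mean Ks
#'
#' Molecular clock `T = Ks / (2 * lambda)`, reported in million years.
#'
#' @param ks_mean Mean synonymous substitutions per synonymous site.
#' @param lambda_rate Synonymous substitution rate per site per year
#'   (default the Fabaceae rate `6.1e-9`).
#' @return Age in million years (exact float; round with
#'   [round_age()] for report tables).
#' @examples
#' date_duplication(0.17)         # ~13.9 mya
#' round_age(date_duplication(0.17))  # 14
#' @export
date_duplication <- function(ks_mean, lambda_rate = 6.1e-9) {
  stopifnot_scalar_number(ks_mean, "ks_mean")
  stopifnot_scalar_number(lambda_rate, "lambda_rate")
  if (ks_mean < 0) abort("ks_mean must be >= 0")
  if (lambda_rate <= 0) abort("lambda_rate must be positive")
  ks_mean / (2 * lambda_rate) / 1e6
}

#' Round an age to the nearest integer million years
#'
#' Report tables print integer ages; rounding is half away from zero.
#'
#' @param age_mya Age in million years.
#' @return Integer mya.
#' @export
round_age <- function(age_mya) {
  as.integer(round_half_up(age_mya))
}

#' Date a collinear block from anchor Ks values
#'
#' Convenience wrapper: trimmed-mean Ks, then the molecular clock.
#'
#' @param ks_values Per-anchor Ks values.
#' @param lambda_rate Synonymous substitution rate per site per year.
#' @return A one-row tibble: `n_anchors`, `ks_mean`, `ks_sd`, `age_mya`,
#'   `age_mya_reported`.
#' @export
date_from_anchors <- function(ks_values, lambda_rate = 6.1e-9) {
  tm <- trimmed_mean_ks(ks_values)
  age <- date_duplication(tm$ks_mean, lambda_rate)
  tibble(n_anchors = length(ks_values), ks_mean = tm$ks_mean, ks_sd = tm$ks_sd,
         age_mya = age, age_mya_reported = round_age(age))
}

# age class from the configured windows: recent / old / ambiguous
age_class_of <- function(age_mya, config) {
  r <- config$recent_age_window
  o <- config$old_age_window
  if (age_mya >= r[1] && age_mya < r[2]) return("recent")
  if (age_mya >= o[1] && age_mya <= o[2]) return("old")
  "ambiguous"
}

#' Classify a duplicate gene pair by mechanism and age
#'
#' A pair is `segmental` when it is an anchor of (or both genes fall within
#' the segments of) a collinear block linking two different segments;
#' `tandem` when the genes share a chromosome with at most
#' `tandem_max_intervening_genes` genes between them and are not part of a
#' block; otherwise `dispersed`. Segmental pairs are aged from their block's
#' Ks dating (`recent` / `old` / `ambiguous` by the configured windows);
#' tandem pairs are `old` when the tandem arrangement is shared with the
#' outgroup species and `recent` otherwise.
#'
#' @param gene_a,gene_b The duplicate pair.
#' @param blocks Blocks tibble from [chain_collinear()].
#' @param loci Ranked loci tibble.
#' @param dating Optional one-row tibble from [date_from_anchors()] for the
#'   pair's block.
#' @param outgroup_presence For tandem candidates: is the tandem arrangement
#'   present in the outgroup species? (`NA` when unknown.)
#' @param config A [pathevo_config()].
#' @return A one-row tibble: `gene_a`, `gene_b`, `mechanism`, `age_class`,
#'   `age_mya`, `block_id`, `shared_with_outgroup`.
#' @export
classify_pair <- function(gene_a, gene_b, blocks, loci, dating = NULL,
                          outgroup_presence = NA, config = pathevo_config()) {
  la <- loci |> filter(.data$gene_id == gene_a)
  lb <- loci |> filter(.data$gene_id == gene_b)
  if (nrow(la) != 1L || nrow(lb) != 1L) abort("both genes must be present in the loci table")

  in_block <- NA_character_
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      a <- blocks$anchors[[i]]
      hit <- any((a$gene_a == gene_a & a$gene_b == gene_b) |
                   (a$gene_a == gene_b & a$gene_b == gene_a))
      if (!hit) {
        # flanked within the two segments of the block (either assignment)
        within <- function(l, chrom, s, e) l$chromosome == chrom && l$start >= s && l$end <= e
        hit <- (within(la, blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i]) &&
                  within(lb, blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i])) ||
          (within(lb, blocks$chrom_a[i], blocks$start_a[i], blocks$end_a[i]) &&
             within(la, blocks$chrom_b[i], blocks$start_b[i], blocks$end_b[i]))
      }
      if (hit) {
        # require genuinely different segments
        same_segment <- blocks$chrom_a[i] == blocks$chrom_b[i] &&
          blocks$start_a[i] < blocks$end_b[i] && blocks$start_b[i] < blocks$end_a[i]
        if (!same_segment) { in_block <- blocks$block_id[i]; break }
      }
    }
  }

  if (!is.na(in_block)) {
    if (is.null(dating)) {
      warn(sprintf("segmental pair %s/%s has no Ks dating; age class set to ambiguous", gene_a, gene_b))
      return(tibble(gene_a = gene_a, gene_b = gene_b, mechanism = "segmental",
                    age_class = "ambiguous", age_mya = NA_real_, block_id = in_block,
                    shared_with_outgroup = NA))
    }
    return(tibble(gene_a = gene_a, gene_b = gene_b, mechanism = "segmental",
                  age_class = age_class_of(dating$age_mya, config),
                  age_mya = dating$age_mya, block_id = in_block,
                  shared_with_outgroup = NA))
  }

  if (la$chromosome == lb$chromosome &&
      abs(la$rank - lb$rank) - 1L <= config$tandem_max_intervening_genes) {
    return(tibble(gene_a = gene_a, gene_b = gene_b, mechanism = "tandem",
                  age_class = if (isTRUE(outgroup_presence)) "old"
                  else if (isFALSE(outgroup_presence)) "recent"
                  else "ambiguous",
                  age_mya = NA_real_, block_id = NA_character_,
                  shared_with_outgroup = outgroup_presence))
  }

  tibble(gene_a = gene_a, gene_b = gene_b, mechanism = "dispersed",
         age_class = "ambiguous", age_mya = NA_real_, block_id = NA_character_,
         shared_with_outgroup = NA)
}

# union-find over gene ids, used to merge duplicate pairs into events
uf_components <- function(a, b) {
  ids <- unique(c(a, b))
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(a)) {
    ra <- find(match(a[k], ids)); rb <- find(match(b[k], ids))
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  split(ids, roots)
}

#' Tabulate duplication events per family
#'
#' Counts duplication events in each family x {segmental, tandem} x
#' {old, recent} cell. Pairs of the same family, mechanism and age class are
#' merged into events by connected components; a component of `k` genes
#' contributes `k - 1` events (so a tandem array of three consecutive genes
#' counts two events).
#'
#' @param calls Tibble of classified pairs (rows from [classify_pair()]) with
#'   an added `family` column.
#' @param families Optional character vector fixing the families (and order)
#'   of the output; families without calls get all-zero rows.
#' @return A tibble: `family`, `segmental_old`, `segmental_recent`,
#'   `tandem_old`, `tandem_recent`, `ambiguous`.
#' @export
tabulate_duplications <- function(calls, families = NULL) {
  families <- families %||% unique(calls$family)
  cells <- list(segmental_old = c("segmental", "old"),
                segmental_recent = c("segmental", "recent"),
                tandem_old = c("tandem", "old"),
                tandem_recent = c("tandem", "recent"))
  rows <- lapply(families, function(fam) {
    fc <- calls |> filter(.data$family == fam)
    counts <- vapply(cells, function(cell) {
      sub <- fc |> filter(.data$mechanism == cell[1], .data$age_class == cell[2])
      if (!nrow(sub)) return(0L)
      if (cell[1] == "segmental" && !all(is.na(sub$block_id))) {
        # segmental events are counted per collinear block
        return(length(unique(sub$block_id[!is.na(sub$block_id)])))
      }
      comps <- uf_components(sub$gene_a, sub$gene_b)
      sum(vapply(comps, function(g) length(g) - 1L, integer(1)))
    }, integer(1))
    amb <- sum(fc$mechanism != "dispersed" & fc$age_class == "ambiguous")
    tibble(family = fam, !!!as.list(counts), ambiguous = as.integer(amb))
  })
  bind_rows(rows)
}
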