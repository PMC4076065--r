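# Pathway-level summaries: family copy-number tables, per-copy rate tables,
# and upstream/downstream group comparisons with permutation P-values.

#' Family-size summary across species
#'
#' The reported family average is the arithmetic mean over species carrying
#' at least one copy, rounded half-up to the nearest integer (legume-specific
#' families are averaged over legumes only).
#'
#' @param counts Tibble with columns `family`, `species`, `n_genes` (or a
#'   named numeric vector of per-species counts for a single family).
#' @return A tibble: `family`, one column per species, `average`, and
#'   `all_zero` flag.
#' @export
family_size_summary <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble(family = "family", species = names(counts),
                     n_genes = as.numeric(counts))
  }
  counts |>
    group_by(.data$family) |>
    summarise(average = {
      nz <- .data$n_genes[.data$n_genes > 0]
      if (!length(nz)) 0 else round_half_up(mean(nz))
    },
    all_zero = all(.data$n_genes == 0),
    .groups = "drop") |>
    left_join(counts |> tidyr::pivot_wider(names_from = "species", values_from = "n_genes"),
              by = "family") |>
    select("family", dplyr::everything())
}

#' Per-group means of a per-copy statistic
#'
#' Arithmetic means over gene copies (not family means), reported on the
#' percent scale with two half-up decimals alongside the exact value.
#'
#' @param values Tibble with a `gene_id` column and the statistic in `value`
#'   (fraction scale) or `value_pct` (percent scale).
#' @param annotation Tibble mapping `gene_id` to the grouping column.
#' @param group Name of the grouping column in `annotation`.
#' @return A tibble: group, `n`, `mean_pct`, `mean_pct_2dp`.
#' @export
group_means <- function(values, annotation, group) {
  v <- values
  if (!"value_pct" %in% names(v)) {
    if (!"value" %in% names(v)) abort("values needs a `value` or `value_pct` column")
    v$value_pct <- v$value * 100
  }
  joined <- v |> left_join(annotation, by = intersect(names(v), names(annotation)))
  if (anyNA(joined[[group]])) abort("every gene copy must be annotated")
  joined |>
    group_by(.data[[group]]) |>
    summarise(n = dplyr::n(), mean_pct = mean(.data$value_pct), .groups = "drop") |>
    mutate(mean_pct_2dp = round_half_up(.data$mean_pct, 2))
}

#' Two-sided permutation test for a difference of group means
#'
#' Statistic `|mean(a) - mean(b)|`. When the number of distinct label
#' assignments (`choose(na + nb, na)`) is at most `max_exhaustive`, the exact
#' permutation distribution is enumerated and `P = #extreme / #assignments`;
#' otherwise a seeded Monte Carlo with the add-one correction
#' `P = (k + 1) / (n_permutations + 1)`.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param n_permutations Monte Carlo permutations.
#' @param seed Integer seed (Monte Carlo only).
#' @param max_exhaustive Enumeration threshold on the number of assignments.
#' @return An object of class `group_comparison` (one-row tibble):
#'   `mean_a`, `mean_b`, `statistic`, `fold_ratio`, `p_value`, `method`,
#'   `n_permutations`, `seed`.
#' @examples
#' permutation_test(c(0, 0), c(1, 1))
#' @export
permutation_test <- function(values_a, values_b, n_permutations = 10000L, seed = 1L,
                             max_exhaustive = 20000) {
  if (!length(values_a) || !length(values_b)) abort("both groups must be non-empty")
  na <- length(values_a); nb <- length(values_b)
  pooled <- c(values_a, values_b)
  obs <- abs(mean(values_a) - mean(values_b))
  n_assign <- choose(na + nb, na)
  if (n_assign <= max_exhaustive) {
    idx <- combn(na + nb, na)
    stats <- apply(idx, 2L, function(ii) abs(mean(pooled[ii]) - mean(pooled[-ii])))
    p <- sum(stats >= obs - 1e-12) / ncol(idx)
    method <- "exhaustive"
    nperm <- ncol(idx)
  } else {
    set.seed(seed)
    k <- 0L
    for (r in seq_len(n_permutations)) {
      ii <- sample.int(na + nb, na)
      if (abs(mean(pooled[ii]) - mean(pooled[-ii])) >= obs - 1e-12) k <- k + 1L
    }
    p <- (k + 1) / (n_permutations + 1)
    method <- "monte_carlo"
    nperm <- n_permutations
  }
  out <- tibble(mean_a = mean(values_a), mean_b = mean(values_b),
                statistic = obs,
                fold_ratio = if (mean(values_a) >= 0 && mean(values_b) >= 0) {
                  fold_ratio(mean(values_a), mean(values_b))
                } else NA_real_,
                p_value = p, method = method,
                n_permutations = as.integer(nperm), seed = as.integer(seed))
  class(out) <- c("group_comparison", class(out))
  out
}

#' Fold ratio of two group means
#'
#' Larger mean over smaller mean; `Inf` (flagged) when the smaller mean is 0
#' and the larger is not; 1 for equal means.
#'
#' @param mean_a,mean_b Non-negative group means.
#' @return The dimensionless ratio.
#' @examples
#' fold_ratio(0.28, 0.07) # 4
#' @export
fold_ratio <- function(mean_a, mean_b) {
  if (mean_a < 0 || mean_b < 0) abort("means must be >= 0")
  lo <- min(mean_a, mean_b); hi <- max(mean_a, mean_b)
  if (lo == 0) {
    if (hi == 0) return(1)
    return(Inf)
  }
  hi / lo
}

#' Assemble a per-copy rate table with group blocks
#'
#' One row per gene copy: diversity and substitution rates on the percent
#' scale (two half-up decimals), the dN/dS cell (rendered `"x/0"`-style when
#' `ds` is zero), and the M7-vs-M8 LRT statistic with significance stars.
#' Group averages and permutation P-values are attached per grouping level.
#'
#' @param stats Tibble with one row per gene copy: `gene_id`, `pi`, `dn`,
#'   `ds` (fraction scale) and optionally `lrt_stat`, `lrt_p`.
#' @param annotation Tibble: `gene_id`, grouping column(s) such as `position`.
#' @param group Grouping column name.
#' @param config A [pathevo_config()] (permutations, seed).
#' @return A list: `rows` (per-copy table), `groups` (per-group means and
#'   P-values for pi, dn, ds).
#' @export
build_rate_table <- function(stats, annotation, group = "position",
                             config = pathevo_config()) {
  rows <- stats |>
    select(-dplyr::any_of(setdiff(names(annotation), "gene_id"))) |>
    left_join(annotation, by = "gene_id") |>
    mutate(pi_pct = round_half_up(.data$pi * 100, 2),
           dn_pct = round_half_up(.data$dn * 100, 2),
           ds_pct = round_half_up(.data$ds * 100, 2))
  rows$dn_ds <- vapply(seq_len(nrow(rows)), function(i) {
    if (is.na(rows$dn_pct[i]) || is.na(rows$ds_pct[i])) return(NA_character_)
    format_omega(rows$dn_pct[i], rows$ds_pct[i])
  }, character(1))
  if ("lrt_stat" %in% names(rows)) {
    rows$lrt <- vapply(seq_len(nrow(rows)), function(i) {
      if (is.na(rows$lrt_stat[i])) return(NA_character_)
      stars <- if (is.na(rows$lrt_p[i])) "" else if (rows$lrt_p[i] < 0.01) "**"
      else if (rows$lrt_p[i] < 0.05) "*" else ""
      sprintf("%.2f%s", rows$lrt_stat[i], stars)
    }, character(1))
  }

  lv <- unique(rows[[group]])
  groups <- NULL
  if (length(lv) == 2L) {
    groups <- purrr::map_dfr(c("pi", "dn", "ds"), function(metric) {
      a <- rows[[metric]][rows[[group]] == lv[1]] * 100
      b <- rows[[metric]][rows[[group]] == lv[2]] * 100
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (!length(a) || !length(b)) {
        return(tibble(metric = metric, group_a = lv[1], group_b = lv[2],
                      mean_a_pct = NA_real_, mean_b_pct = NA_real_,
                      fold_ratio = NA_real_, p_value = NA_real_))
      }
      pt <- permutation_test(a, b, config$permutations,
                             seed = substream_seed(config$rng_seed, 7L))
      tibble(metric = metric, group_a = lv[1], group_b = lv[2],
             mean_a_pct = round_half_up(pt$mean_a, 2),
             mean_b_pct = round_half_up(pt$mean_b, 2),
             fold_ratio = fold_ratio(round_half_up(pt$mean_a, 2),
                                     round_half_up(pt$mean_b, 2)),
             p_value = pt$p_value)
    })
  }
  list(rows = rows, groups = groups)
}

#' Plot per-copy rates by pathway position
#'
#' @param rows The `rows` tibble from [build_rate_table()].
#' @param metric One of `"pi_pct"`, `"dn_pct"`, `"ds_pct"`.
#' @param group Grouping column.
#' @return A ggplot object.
#' @export
plot_rate_groups <- function(rows, metric = "pi_pct", group = "position") {
  ggplot2::ggplot(rows, ggplot2::aes(x = .data[[group]], y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, colour = "steelblue") +
    ggplot2::labs(x = NULL, y = paste0(sub("_pct$", "", metric), " (%)")) +
    ggplot2::theme_minimal()
}
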