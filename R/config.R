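#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its default. The
#' defaults encode the study conditions: a Fabaceae synonymous substitution
#' rate of `6.1e-9` substitutions/site/year, 1000 bootstrap replicates with
#' branches below 50% support collapsed, at most six dating anchors on each
#' side of a focal gene, and recent/old age windows bracketing the two
#' whole-genome duplication epochs (roughly 5-15 and 50-60 million years ago).
#'
#' @param lambda_rate Synonymous substitution rate, substitutions per
#'   synonymous site per year.
#' @param bootstrap_reps Bootstrap replicates for neighbor-joining trees.
#' @param support_collapse_pct Internal edges with bootstrap support strictly
#'   below this percentage are collapsed.
#' @param max_anchors_per_side Maximum consecutive anchors kept on each side of
#'   a focal gene when dating a segmental duplication.
#' @param recent_age_window,old_age_window Age intervals (mya) assigned to the
#'   recent and old duplication classes; they must not overlap. Ages falling
#'   between the windows are classified `ambiguous`.
#' @param tandem_max_intervening_genes Maximum number of genes allowed between
#'   two same-chromosome copies for the pair to count as tandem.
#' @param permutations Monte Carlo permutations for group comparisons (used
#'   when exhaustive enumeration is infeasible).
#' @param rng_seed Master seed; every stochastic stage derives its own
#'   substream from it.
#' @param beta_categories Number of equal-weight discretisation classes for the
#'   beta distribution of the M7/M8 site models.
#' @param evalue_max E-value threshold for homology hits entering collinearity
#'   chaining.
#' @param min_anchors Minimum anchors for a collinear block to be reported.
#' @param window_bp Flanking window (bp) for cross-species synteny support.
#' @param min_flank_hits Minimum flanking genes with significant hits to a
#'   common chromosome for cross-species synteny support.
#'
#' @return A list of class `pathevo_config`.
#' @examples
#' cfg <- pathevo_config(rng_seed = 42)
#' cfg$lambda_rate
#' @export
pathevo_config <- function(lambda_rate = 6.1e-9,
                           bootstrap_reps = 1000L,
                           support_collapse_pct = 50,
                           max_anchors_per_side = 6L,
                           recent_age_window = c(0, 25),
                           old_age_window = c(40, 80),
                           tandem_max_intervening_genes = 5L,
                           permutations = 10000L,
                           rng_seed = 1L,
                           beta_categories = 10L,
                           evalue_max = 1e-10,
                           min_anchors = 4L,
                           window_bp = 100000,
                           min_flank_hits = 3L) {
  counts <- c(bootstrap_reps = bootstrap_reps, max_anchors_per_side = max_anchors_per_side,
              permutations = permutations, beta_categories = beta_categories,
              min_anchors = min_anchors, min_flank_hits = min_flank_hits,
              window_bp = window_bp)
  if (any(counts <= 0)) {
    abort(sprintf("configuration counts must be positive (%s)",
                  paste(names(counts)[counts <= 0], collapse = ", ")))
  }
  if (lambda_rate <= 0) abort("lambda_rate must be positive")
  for (w in list(recent_age_window, old_age_window)) {
    if (length(w) != 2L || w[1] >= w[2]) abort("age windows must be increasing length-2 intervals")
  }
  if (recent_age_window[2] > old_age_window[1] && old_age_window[2] > recent_age_window[1]) {
    abort("recent and old age windows must not overlap")
  }
  if (tandem_max_intervening_genes < 0) abort("tandem_max_intervening_genes must be >= 0")
  structure(list(
    lambda_rate = lambda_rate,
    bootstrap_reps = as.integer(bootstrap_reps),
    support_collapse_pct = support_collapse_pct,
    max_anchors_per_side = as.integer(max_anchors_per_side),
    recent_age_window = as.numeric(recent_age_window),
    old_age_window = as.numeric(old_age_window),
    tandem_max_intervening_genes = as.integer(tandem_max_intervening_genes),
    permutations = as.integer(permutations),
    rng_seed = as.integer(rng_seed),
    beta_categories = as.integer(beta_categories),
    evalue_max = evalue_max,
    min_anchors = as.integer(min_anchors),
    window_bp = window_bp,
    min_flank_hits = as.integer(min_flank_hits)
  ), class = "pathevo_config")
}

#' @export
print.pathevo_config <- function(x, ...) {
  cat("<pathevo_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are an error. Vector-valued fields (the age windows) are
#' comma-separated.
#'
#' @param path Path to the configuration file.
#' @return A `pathevo_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  defaults <- pathevo_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  args <- lapply(seq_along(keys), function(i) {
    as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1]])
  })
  names(args) <- keys
  do.call(pathevo_config, args)
}
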