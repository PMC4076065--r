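# Goldman-Yang (1994) codon site models on a fixed tree: M0 (one-ratio),
# M7 (beta-distributed omega) and M8 (beta plus a point mass with omega >= 1),
# with the M7-vs-M8 likelihood-ratio test for positive selection.

# integer codon bookkeeping shared with the C++ core
gy94_code_tables <- function() {
  tb <- codon_tables()
  list(nuc = tb$nuc, aa = as.integer(factor(tb$aa)), idx = tb$idx, codons = tb$codons)
}

# codon site patterns of an alignment: 0-based codon states per tip (rows) and
# unique pattern (columns), with pattern multiplicities
codon_patterns <- function(seqs) {
  m <- seq_matrix(seqs)
  if (ncol(m) %% 3L != 0L) abort("alignment length is not a multiple of 3")
  drop <- incomplete_codon_columns(m)
  nc <- ncol(m) %/% 3L
  keep <- setdiff(seq_len(nc), drop)
  if (!length(keep)) abort("no usable codon columns (all contain gaps, N or stops)")
  tb <- codon_tables()
  states <- matrix(0L, nrow(m), length(keep))
  for (ki in seq_along(keep)) {
    k <- keep[ki]
    cods <- apply(m[, (3L * k - 2L):(3L * k), drop = FALSE], 1L, paste, collapse = "")
    states[, ki] <- unname(tb$idx[cods]) - 1L
  }
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- states[, first, drop = FALSE]
  wt <- as.numeric(table(factor(key, levels = key[first])))
  rownames(pat) <- rownames(m)
  list(patterns = pat, weights = wt, n_codons = length(keep), kept_codons = keep,
       site_pattern = match(key, key[first]))
}

#' F3x4 codon frequencies of an alignment
#'
#' Position-specific nucleotide frequencies across the analyzed codon columns
#' multiplied per codon and renormalized over the 61 sense codons.
#' Zero-frequency codons are floored at `1e-6` and the vector renormalized.
#'
#' @param seqs Aligned coding sequences (tibble with `id`, `seq`).
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(seqs) {
  m <- seq_matrix(seqs)
  drop <- incomplete_codon_columns(m)
  nc <- ncol(m) %/% 3L
  keep <- setdiff(seq_len(nc), drop)
  if (!length(keep)) abort("no usable codon columns")
  nts <- c("A", "C", "G", "T")
  posfreq <- matrix(0, 3L, 4L, dimnames = list(NULL, nts))
  for (p in 1:3) {
    cols <- 3L * (keep - 1L) + p
    tab <- table(factor(m[, cols], levels = nts))
    posfreq[p, ] <- as.numeric(tab) / sum(tab)
  }
  tb <- codon_tables()
  pi <- posfreq[1L, tb$nuc[, 1L] + 1L] * posfreq[2L, tb$nuc[, 2L] + 1L] *
    posfreq[3L, tb$nuc[, 3L] + 1L]
  pi <- pi / sum(pi)
  pi[pi < 1e-6] <- 1e-6
  pi <- pi / sum(pi)
  names(pi) <- tb$codons
  pi
}

# postorder edge list and root for the pruning core
tree_for_pruning <- function(tree, tip_order) {
  if (is.null(tree$edge.length)) abort("tree must carry branch lengths")
  perm <- match(tree$tip.label, tip_order)
  if (anyNA(perm)) abort("tree leaves do not match alignment sequence ids")
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  edge <- tr$edge
  # renumber tips to alignment order, 0-based; internals keep ape numbering
  map <- integer(n + tr$Nnode)
  map[seq_len(n)] <- perm
  map[(n + 1L):(n + tr$Nnode)] <- (n + 1L):(n + tr$Nnode)
  list(edge = cbind(map[edge[, 1]], map[edge[, 2]]) - 1L,
       lengths = tr$edge.length,
       n_tip = n, n_node = n + tr$Nnode, root = n + 1L - 1L)
}

#' GY94 mixture log-likelihood of a codon alignment on a tree
#'
#' Evaluates the log-likelihood under the Goldman-Yang codon substitution
#' model with site-wise omega drawn from the given discrete classes. Rates
#' allow single-nucleotide codon changes only, with `kappa` scaling
#' transitions and the class omega scaling nonsynonymous changes; the
#' generator is normalized to one expected substitution per codon per unit
#' branch length under the class mixture. Codon columns containing gaps, `N`
#' or stop codons are excluded.
#'
#' @param seqs Aligned coding sequences (tibble with `id`, `seq`).
#' @param tree `ape::phylo` whose leaves match the sequence ids, with branch
#'   lengths in expected substitutions per codon.
#' @param kappa Transition/transversion rate ratio.
#' @param class_weights,class_omegas Site-class mixture (weights must sum
#'   to 1).
#' @param codon_freqs Codon frequencies (default: F3x4 from the alignment).
#' @return The total log-likelihood (natural log).
#' @export
gy94_loglik <- function(seqs, tree, kappa, class_weights, class_omegas,
                        codon_freqs = NULL) {
  if (abs(sum(class_weights) - 1) > 1e-8) abort("class weights must sum to 1")
  if (length(class_weights) != length(class_omegas)) abort("weights/omegas length mismatch")
  if (kappa <= 0 || any(class_omegas < 0)) abort("kappa must be > 0 and omegas >= 0")
  cp <- codon_patterns(seqs)
  pi <- codon_freqs %||% f3x4_frequencies(seqs)
  tp <- tree_for_pruning(tree, rownames(cp$patterns))
  ct <- gy94_code_tables()
  res <- gy94_loglik_cpp(cp$patterns, cp$weights, tp$edge, tp$lengths,
                         tp$n_tip, tp$n_node, tp$root,
                         unname(pi), kappa, class_weights, class_omegas,
                         ct$nuc, ct$aa, FALSE)
  res$loglik
}

#' Discretize a beta distribution into equal-weight omega classes
#'
#' Class `k` carries weight `1/K` and omega equal to the mean of the
#' Beta(p, q) distribution within its k-th probability decile (computed by
#' quantile integration).
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of classes (>= 2).
#' @return A tibble: `weight`, `omega`.
#' @examples
#' discretize_beta(1, 1, 10)
#' @export
discretize_beta <- function(p, q, K = 10L) {
  if (p <= 0 || q <= 0) abort("beta shapes must be positive")
  if (K < 2L) abort("K must be >= 2")
  # extreme shapes make qbeta noisy; values are sanitised below
  edges <- suppressWarnings(qbeta(seq(0, 1, length.out = K + 1L), p, q))
  edges <- cummax(pmin(pmax(edges, 0), 1))
  mu <- p / (p + q)
  # mean within each quantile band via the incomplete-beta identity
  Fp1 <- pbeta(edges, p + 1, q)
  omega <- mu * diff(Fp1) * K
  bad <- !is.finite(omega) | omega < 0 | omega > 1
  if (any(bad)) omega[bad] <- (edges[-1][bad] + edges[-(K + 1)][bad]) / 2
  tibble(weight = rep(1 / K, K), omega = omega)
}

# mixture classes per model
model_classes <- function(model, pars, K) {
  switch(model,
         M0 = tibble(weight = 1, omega = pars$omega),
         M7 = discretize_beta(pars$p, pars$q, K),
         M8 = {
           b <- discretize_beta(pars$p, pars$q, K)
           tibble(weight = c(b$weight * pars$p0, 1 - pars$p0),
                  omega = c(b$omega, pars$omega_s))
         },
         abort(sprintf("unknown model '%s'", model)))
}

# parameter transforms: optimizer works on an unconstrained scale
pack_pars <- function(model, pars) {
  switch(model,
         M0 = c(lk = log(pars$kappa), lo = log(pars$omega), ls = log(pars$scale)),
         M7 = c(lk = log(pars$kappa), lp = log(pars$p), lq = log(pars$q), ls = log(pars$scale)),
         M8 = c(lk = log(pars$kappa), lp = log(pars$p), lq = log(pars$q),
                z0 = stats::qlogis(pars$p0), zs = log(pars$omega_s - 1 + 1e-8),
                ls = log(pars$scale)))
}

unpack_pars <- function(model, x) {
  switch(model,
         M0 = list(kappa = exp(x[["lk"]]), omega = exp(x[["lo"]]), scale = exp(x[["ls"]])),
         M7 = list(kappa = exp(x[["lk"]]), p = exp(x[["lp"]]), q = exp(x[["lq"]]),
                   scale = exp(x[["ls"]])),
         M8 = list(kappa = exp(x[["lk"]]), p = exp(x[["lp"]]), q = exp(x[["lq"]]),
                   p0 = stats::plogis(x[["z0"]]), omega_s = 1 + exp(x[["zs"]]),
                   scale = exp(x[["ls"]])))
}

par_bounds <- function(model) {
  lims <- list(lk = log(c(0.05, 100)), lo = log(c(1e-6, 20)),
               lp = log(c(5e-3, 50)), lq = log(c(5e-3, 50)),
               z0 = stats::qlogis(c(1e-4, 1 - 1e-4)), zs = log(c(1e-6, 49)),
               ls = log(c(1e-4, 1e3)))
  nm <- names(pack_pars(model, list(kappa = 2, omega = 0.5, p = 1, q = 1,
                                    p0 = 0.9, omega_s = 1.5, scale = 1)))
  list(lower = vapply(nm, function(k) lims[[k]][1], numeric(1)),
       upper = vapply(nm, function(k) lims[[k]][2], numeric(1)))
}

default_starts <- function(model) {
  switch(model,
         M0 = list(list(kappa = 2, omega = 0.2, scale = 1),
                   list(kappa = 2, omega = 1.0, scale = 1),
                   list(kappa = 4, omega = 0.05, scale = 0.5)),
         M7 = list(list(kappa = 2, p = 0.5, q = 1.5, scale = 1),
                   list(kappa = 2, p = 2, q = 2, scale = 1),
                   list(kappa = 4, p = 0.2, q = 0.8, scale = 0.5)),
         M8 = list(list(kappa = 2, p = 0.5, q = 1.5, p0 = 0.99, omega_s = 1.5, scale = 1),
                   list(kappa = 2, p = 2, q = 2, p0 = 0.9, omega_s = 2.5, scale = 1),
                   list(kappa = 4, p = 0.2, q = 0.8, p0 = 0.99, omega_s = 1.5, scale = 0.5)))
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the GY94 likelihood over `kappa`, the model-specific omega
#' parameters (M0: a single omega; M7: beta shapes `p`, `q`; M8: `p`, `q`,
#' the beta proportion `p0` and the selection class `omega_s >= 1`) and a
#' global branch-length scale. Branch lengths are taken from the input tree
#' as a fixed shape; only the scale is re-estimated per model. Optimization
#' is bounded quasi-Newton (L-BFGS-B on log/logit-transformed parameters)
#' from `n_starts` fixed start points (or the supplied `init`), with
#' convergence tolerance 1e-6 in log-likelihood.
#'
#' @param seqs Aligned coding sequences (tibble with `id`, `seq`).
#' @param tree `ape::phylo` with branch lengths matching the sequence ids.
#' @param model One of `"M0"`, `"M7"`, `"M8"`.
#' @param config A [pathevo_config()] (supplies `beta_categories`).
#' @param n_starts Number of fixed start points to use (1-3).
#' @param init Optional named list of start values overriding the first start
#'   point (e.g. the M7 optimum when warm-starting M8).
#' @return An object of class `site_model_fit`.
#' @export
fit_site_model <- function(seqs, tree, model = c("M0", "M7", "M8"),
                           config = pathevo_config(), n_starts = 3L, init = NULL) {
  model <- match.arg(model)
  K <- config$beta_categories
  cp <- codon_patterns(seqs)
  pi <- f3x4_frequencies(seqs)
  tp <- tree_for_pruning(tree, rownames(cp$patterns))
  ct <- gy94_code_tables()

  # initial global scale: observed divergence per unit of tree path length,
  # so branch lengths in arbitrary units (e.g. million years) start close
  m <- seq_matrix(seqs)
  n_seq <- nrow(m)
  pd <- 0; np <- 0
  for (i in seq_len(n_seq - 1L)) {
    for (j in (i + 1L):n_seq) {
      keep <- !(m[i, ] %in% c("-", "N") | m[j, ] %in% c("-", "N"))
      if (any(keep)) { pd <- pd + mean(m[i, keep] != m[j, keep]); np <- np + 1 }
    }
  }
  coph <- cophenetic(tree)[rownames(m), rownames(m)]
  path_bar <- mean(coph[upper.tri(coph)])
  scale0 <- if (np > 0 && pd > 0 && path_bar > 0) {
    max(1e-3, min(1e3, 3 * (pd / np) / path_bar))
  } else 1

  negll <- function(x) {
    pars <- unpack_pars(model, x)
    cls <- model_classes(model, pars, K)
    res <- gy94_loglik_cpp(cp$patterns, cp$weights, tp$edge, tp$lengths * pars$scale,
                           tp$n_tip, tp$n_node, tp$root,
                           unname(pi), pars$kappa, cls$weight, cls$omega,
                           ct$nuc, ct$aa, FALSE)
    ll <- res$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # forward-difference gradient reusing the objective value at the current
  # point (optim evaluates fn then gr at the same x)
  memo <- new.env(parent = emptyenv())
  fn <- function(x) {
    v <- negll(x)
    memo$x <- x; memo$v <- v
    v
  }
  gr <- function(x) {
    f0 <- if (!is.null(memo$x) && isTRUE(all.equal(memo$x, x, tolerance = 0))) memo$v else negll(x)
    h <- 1e-5
    vapply(seq_along(x), function(i) {
      xi <- x; xi[i] <- xi[i] + h
      (negll(xi) - f0) / h
    }, numeric(1))
  }

  starts <- default_starts(model)[seq_len(max(1L, min(3L, n_starts)))]
  starts <- lapply(starts, function(st) { st$scale <- st$scale * scale0; st })
  if (!is.null(init)) starts[[1L]] <- utils::modifyList(starts[[1L]], init)
  bounds <- par_bounds(model)
  run_opt <- function(x0, free, coarse = FALSE) {
    # optimize a subset of coordinates with the others clamped; warm-up
    # stages run at a coarser tolerance, the final polish at ~1e-6 loglik
    sub_fn <- function(xf) { x <- x0; x[free] <- xf; fn(x) }
    sub_gr <- function(xf) { x <- x0; x[free] <- xf; gr(x)[free] }
    ctrl <- if (coarse) list(factr = 1e9, maxit = 60L, pgtol = 1e-4)
    else list(factr = 1e7, maxit = 500L, pgtol = 1e-4)
    fit <- optim(x0[free], sub_fn, sub_gr, method = "L-BFGS-B",
                 lower = bounds$lower[free], upper = bounds$upper[free],
                 control = ctrl)
    x <- x0; x[free] <- fit$par
    list(par = x, value = fit$value,
         convergence = if (coarse) 0L else fit$convergence)
  }
  best <- NULL
  for (st in starts) {
    x0 <- pack_pars(model, st)
    if (model == "M8" && !is.null(init)) {
      # warm-started M8: first move only the selection class (p0, omega_s)
      # away from the M7 optimum, then polish everything
      stage1 <- run_opt(x0, which(names(x0) %in% c("z0", "zs")), coarse = TRUE)
      x0 <- stage1$par
    }
    fit <- run_opt(x0, seq_along(x0))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (model == "M8" && !is.null(init)) {
    # the warm start is nested: never report an M8 optimum below the
    # quasi-M7 point (p0 -> 1, omega_s -> 1)
    near7 <- utils::modifyList(init, list(p0 = 1 - 1e-4, omega_s = 1 + 1e-8))
    x7 <- pack_pars("M8", near7)
    v7 <- negll(x7)
    if (v7 < best$value) best <- list(par = x7, value = v7, convergence = 0L)
  }
  if (best$convergence != 0 && best$convergence != 52) {
    abort(sprintf("site-model optimization did not converge (code %d); best loglik %.4f",
                  best$convergence, -best$value))
  }
  pars <- unpack_pars(model, best$par)
  cls <- model_classes(model, pars, K)
  structure(list(model = model,
                 kappa = pars$kappa,
                 omega_params = pars[setdiff(names(pars), c("kappa", "scale"))],
                 branch_scale = pars$scale,
                 loglik = -best$value,
                 codon_freqs = pi,
                 classes = cls,
                 tree = tree,
                 branch_lengths = tree$edge.length * pars$scale,
                 n_codons = cp$n_codons,
                 n_patterns = ncol(cp$patterns),
                 n_sequences = nrow(cp$patterns),
                 data_key = paste(nrow(cp$patterns), cp$n_codons,
                                  paste(sort(rownames(cp$patterns)), collapse = ";")),
                 convergence = best$convergence,
                 beta_categories = K),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("<site_model_fit> %s: loglik %.3f, kappa %.3f\n", x$model, x$loglik, x$kappa))
  op <- vapply(x$omega_params, function(v) sprintf("%.4g", v), character(1))
  cat("  ", paste(names(op), op, sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a site-model fit
#' @param x A `site_model_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter.
#' @export
tidy.site_model_fit <- function(x, ...) {
  pars <- c(list(kappa = x$kappa), x$omega_params, list(branch_scale = x$branch_scale))
  tibble(term = names(pars), estimate = unlist(pars), model = x$model)
}

#' One-row summary of a site-model fit
#' @param x A `site_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, loglik, parameter count, data sizes.
#' @export
glance.site_model_fit <- function(x, ...) {
  tibble(model = x$model, loglik = x$loglik,
         n_par = length(x$omega_params) + 2L,
         n_codons = x$n_codons, n_sequences = x$n_sequences,
         kappa = x$kappa, convergence = x$convergence)
}

#' Plot the fitted omega site-class distribution
#' @param object A `site_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_model_fit <- function(object, ...) {
  ggplot2::ggplot(object$classes, ggplot2::aes(x = .data$omega, y = .data$weight)) +
    ggplot2::geom_col(width = 0.02, fill = "steelblue") +
    ggplot2::labs(x = expression(omega), y = "class weight",
                  title = sprintf("%s site classes", object$model)) +
    ggplot2::theme_minimal()
}

#' Likelihood-ratio test of M8 against M7
#'
#' `stat = 2 * (loglik_M8 - loglik_M7)` (clamped at zero), compared to a
#' chi-square with 2 degrees of freedom. Because `omega_s = 1, p0` free makes
#' the models touch on a boundary, the df-2 chi-square is conservative.
#'
#' @param fit7,fit8 `site_model_fit` objects for M7 and M8 on the same data.
#' @return An object of class `lrt_result` (also a one-row tibble): `stat`,
#'   `df`, `p_value`, `significant_at`, `stars`.
#' @export
lrt_m7_m8 <- function(fit7, fit8) {
  if (fit7$model != "M7" || fit8$model != "M8") abort("pass an M7 fit and an M8 fit")
  if (!identical(fit7$data_key, fit8$data_key)) abort("fits are not from the same alignment/tree")
  stat <- max(0, 2 * (fit8$loglik - fit7$loglik))
  p <- pchisq(stat, df = 2, lower.tail = FALSE)
  out <- tibble(stat = stat, df = 2L, p_value = p,
                significant_at = if (p < 0.01) "0.01" else if (p < 0.05) "0.05" else "none",
                stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  class(out) <- c("lrt_result", class(out))
  out
}

#' Fit M7 and M8 and run the likelihood-ratio test
#'
#' M7 is fitted from the standard start points; M8 is warm-started from the
#' M7 optimum with `p0 = 0.99`, `omega_s = 1.5` (plus any extra start points
#' requested).
#'
#' @inheritParams fit_site_model
#' @return A list: `fit7`, `fit8`, `lrt`.
#' @export
site_model_lrt <- function(seqs, tree, config = pathevo_config(), n_starts = 1L) {
  fit7 <- fit_site_model(seqs, tree, "M7", config, n_starts = n_starts)
  init8 <- c(fit7$omega_params[c("p", "q")],
             list(kappa = fit7$kappa, scale = fit7$branch_scale,
                  p0 = 0.99, omega_s = 1.5))
  fit8 <- fit_site_model(seqs, tree, "M8", config, n_starts = n_starts, init = init8)
  list(fit7 = fit7, fit8 = fit8, lrt = lrt_m7_m8(fit7, fit8))
}

#' Naive empirical-Bayes site posteriors over omega classes
#'
#' Descriptive per-site posterior weight of each omega class under a fitted
#' site model (no uncertainty in the estimated parameters is propagated).
#'
#' @param fit A `site_model_fit`.
#' @param seqs,tree The data the model was fitted to.
#' @return A tibble: `codon` (position in the analyzed alignment), `class`,
#'   `omega`, `posterior`.
#' @export
site_posteriors <- function(fit, seqs, tree) {
  cp <- codon_patterns(seqs)
  tp <- tree_for_pruning(tree, rownames(cp$patterns))
  ct <- gy94_code_tables()
  res <- gy94_loglik_cpp(cp$patterns, cp$weights, tp$edge,
                         tp$lengths * fit$branch_scale,
                         tp$n_tip, tp$n_node, tp$root,
                         unname(fit$codon_freqs), fit$kappa,
                         fit$classes$weight, fit$classes$omega,
                         ct$nuc, ct$aa, TRUE)
  post <- res$posterior  # K x npat
  purrr::map_dfr(seq_along(cp$kept_codons), function(i) {
    tibble(codon = cp$kept_codons[i],
           class = seq_len(nrow(post)),
           omega = fit$classes$omega,
           posterior = post[, cp$site_pattern[i]])
  })
}
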