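---
title: "Dating duplications and detecting selection in multi-copy pathway gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating duplications and detecting selection in multi-copy pathway gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathevo)
```

## The problem

Plant metabolic pathways are typically encoded by multi-copy gene families,
and paleopolyploid genomes such as soybean carry duplicates from successive
whole-genome duplications (WGDs, roughly 50-60 and 5-15 million years ago in
the soybean lineage) alongside tandem arrays. Asking how a gene's position in
a pathway (upstream entry points, central branch points, terminal steps)
shapes its duplicate retention, polymorphism, substitution rates and exposure
to positive selection requires a chain of analyses: classifying each
duplicate pair by mechanism, dating segmental duplications, counting
ancestral genes at named divergences, and fitting codon site models per gene.
`pathevo` implements that chain end to end, together with a synthetic-data
generator that produces fully specified inputs with known truth, so every
stage is testable without any genome downloads.

## Models and procedures

### Pairwise distances

* **K2P** (Kimura two-parameter) distances drive gene-family trees:
  `K = -1/2 log(1-2P-Q) - 1/4 log(1-2Q)` with `P`, `Q` the transition and
  transversion proportions over the retained sites. Columns carrying a gap or
  `N` in either sequence are excluded (complete deletion). Saturated inputs
  (`1-2P-Q <= 0` or `1-2Q <= 0`) raise an error rather than returning a
  clamped value, so downstream code must handle them explicitly — the
  bootstrap drops such replicates and reports the count.
* **Nucleotide diversity** `pi` is the mean Jukes-Cantor-corrected pairwise
  p-distance over all haplotype pairs, computed over all sites of the
  region (not silent sites only). Whether the original DnaSP-style estimates
  used total or silent sites is not stated in our sources; all-site values
  are used and labelled as such.
* **NG86** (Nei-Gojobori 1986) gives `dN`, `dS` and `Ks`. Synonymous site
  fractions are counted per codon position with mutations to stop codons
  removed from both numerator and denominator; sites are averaged over the
  two sequences; codons differing at more than one position average their
  substitution counts over all mutational pathways that avoid stop codons
  (if every pathway is blocked — possible only for triple differences — all
  pathways are used). Proportions are Jukes-Cantor corrected, and
  `omega = dN/dS` is reported as undefined (`"x/0"`-style in tables) when
  `dS = 0`, which is common in shallow population samples.

### Trees and reconciliation

Gene-family trees are neighbor-joining (Saitou-Nei Q-criterion) on K2P
distances, with 1000 column-bootstrap replicates by default; supports are the
percentage of retained replicates containing each bipartition, and edges
below 50% support (strict `<`) can be collapsed. Q-ties are broken by the
lexicographically smallest label pair so results are exactly reproducible.
Negative estimated branch lengths are set to zero. NJ reconstructs additive
matrices exactly, which the tests verify against path-length oracles.

Ancestral gene counts use standard LCA reconciliation of a rooted binary
gene tree against the dated species tree: each gene-tree node maps to the
LCA of its children's mappings and is a duplication exactly when it maps to
the same species node as one of its children. The count at a species node is
the number of gene lineages entering that ancestor; no losses are modelled,
matching the minimal counting procedure. Because LCA duplication labels are
ill-defined on polytomies, reconciliation requires the uncollapsed (binary)
tree; the pipeline reconciles the full bootstrap NJ tree and uses the
collapsed tree only for display.

### Synteny and dating

Collinear blocks are maximum-cardinality chains of homology hits that are
strictly monotone in gene-rank coordinates on both segments (longest
increasing subsequence, run in both orientations; inverted blocks are
accepted). Ranks, not base pairs, make chaining robust to gene-length
variation. Blocks need at least 4 anchors — the smallest anchor count
observed in the segment pairs the defaults are modelled on. Strand is
recorded but ignored.

Dating selects up to six consecutive anchors on each side of the focal gene
pair, computes NG86 Ks per anchor, removes exactly one minimum and one
maximum, and converts the trimmed mean through the molecular clock
`T = Ks / (2 lambda)` with the Fabaceae synonymous rate
`lambda = 6.1e-9` substitutions/site/year. Reported ages are rounded half
away from zero to integer million years (half-up rounding is what reproduces
every printed age and family average; R's default banker's rounding does
not). Cross-species synteny support asks whether at least `min_flank_hits`
(default 3, a package knob — no published threshold exists) flanking genes
within 100 kb hit a common chromosome of the other genome at E-value
strictly below 1e-10.

### Duplication classification

A pair is *segmental* if it is an anchor of (or falls within) a collinear
block linking two different segments; *tandem* if the genes share a
chromosome with at most 5 intervening genes (configurable; "tandem" has no
canonical definition) and are not in a block; otherwise *dispersed*.
Segmental ages are classed *recent* in [0, 25) mya and *old* in [40, 80]
mya; ages between the windows are *ambiguous* rather than force-assigned,
since the two WGD epochs (5-15 and 50-60 mya) leave a gap. Tandem pairs are
*old* when the tandem arrangement also exists in the outgroup legume and
*recent* when lineage-specific. Event counts merge pairs: a tandem array of
`k` genes counts `k - 1` events, and segmental events are counted per
collinear block.

### Codon site models

Positive selection is tested with Goldman-Yang (GY94) codon models on a
fixed tree: single-nucleotide codon changes only, `kappa` scaling
transitions, `omega` scaling nonsynonymous changes, F3x4 codon frequencies
estimated from the analyzed alignment (zero frequencies floored at 1e-6 and
renormalized), and the generator normalized to one expected substitution per
codon per unit branch length under the site-class mixture. M7 draws
site-wise `omega` from Beta(p, q) discretized into 10 equal-weight classes
(class omega = the mean within each probability decile, via the
incomplete-beta identity); M8 adds a point mass with `omega_s >= 1` and
weight `1 - p0`. The M7-vs-M8 LRT uses `2 * delta loglik` against a
chi-square with 2 df — conservative, because the null sits on a boundary of
the alternative.

Numerical choices: branch lengths are taken from the input tree as a fixed
shape with a single global scale re-estimated per model (an order-of-
magnitude speed-up over joint per-branch estimation; a deliberate deviation
from full codeml-style optimization). The initial scale is set from the
observed mean pairwise p-distance divided by the mean tree path length, so
trees expressed in any units (million years, K2P substitutions) start near
the optimum. Optimization is bounded L-BFGS-B on log/logit-transformed
parameters with a memoized forward-difference gradient, convergence
tolerance about 1e-6 in log-likelihood, and up to three fixed start points.
M8 warm-starts from the M7 optimum with `p0 = 0.99`, `omega_s = 1.5`, moving
only the selection class coarsely before polishing all parameters, and never
reports an M8 optimum below the quasi-M7 point (which enforces the nesting
inequality).
Replicate studies use a single warm start: with the staged warm starts the
extra start points changed nothing except tripling the cost. Per-site
class posteriors are reported as naive empirical Bayes, descriptively only.

A caveat the pipeline makes visible: with deeply diverged families and
distance-derived tree shapes, the single global scale cannot absorb
per-branch misfit, and the M8 class can soak it up — occasional significant
LRTs on null families of the synthetic pathway are expected for this reason.
The calibration and power claims in the tests therefore use the true
simulated trees, as a simulation study should.

### Group comparisons

Upstream/downstream and pleiotropy contrasts compare per-copy means (means
over gene copies, not family means — this is the convention that reproduces
the published group averages), reported on the percent scale with two
half-up decimals, with fold ratios computed from the rounded means. The
significance test is a two-sided permutation test on the difference of
means: exhaustive enumeration when the number of assignments is at most
20000, otherwise seeded Monte Carlo with the add-one correction
`(k+1)/(B+1)`. The original publication's test behind its P-values is
unnamed, so the permutation P-values here are the package's own and are not
reproduction targets.

## The synthetic-data generator

`simulate_history()` places a single gene lineage on a dated species
scaffold (legume split 54 mya, dicot MRCA 100 mya, dicot/monocot split
145 mya) and applies WGD events — duplicating every lineage present, moving
whole segments together — and tandem events that duplicate one gene in
place. `layout_loci()` turns each (species, segment) into a chromosome with
six collinear flanking anchors per side; `anchor_sequences()` evolves each
anchor slot along the segment tree; `evolve_codons()` simulates GY94 codon
evolution with site-wise omega, calibrated so the synonymous flux per NG86
synonymous site equals `lambda` per year — a pair split `T` years ago has
expected `Ks = 2 * lambda * T`, the exact inverse of the dating clock.

The `paper_like` fixture is a nine-family pathway with WGDs at 55 and
12 mya, old tandem events on the shared legume stem (60 mya) and recent
soybean-specific ones, legume-specific downstream families originating at
the legume MRCA, stronger purifying selection upstream than downstream, and
one downstream family carrying a positively selected class (20% of sites at
`omega = 4`). Scale choices, made once as realistic desk-scale sizes: 200
codons per family region (partial CDS), 400 codons per anchor gene (typical
plant CDS), 8 haplotypes per sampled copy, haplotype star-tree depth
0.35 mya (giving diversities around 0.1-0.3%), kappa 2, nucleotide
frequencies A/T 0.3, C/G 0.2, WGD copy retention 1 in fixtures used for
exact-recovery checks and 0.5 available for uneven-family experiments.
Replicate studies use 8 taxa and 300 codons on a symmetric tree whose
pairwise divergences span the same Ks range (about 0.18-0.55) as the dated
segment pairs.

What the generator does **not** emulate: indels (alignments are gap-free, so
alignment construction stays out of scope), rate variation across anchor
genes beyond sampling noise, gene conversion, fractionation biases,
recombination within population samples (star genealogies only), and real
chromosome-scale gene order. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artefact of real genomes.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `lambda_rate` | 6.1e-9 | syn subs/site/year | Fabaceae synonymous clock |
| `bootstrap_reps` | 1000 | replicates | standard support resolution |
| `support_collapse_pct` | 50 | % | collapse threshold, strict `<` |
| `max_anchors_per_side` | 6 | anchors | dating window around focal genes |
| `recent_age_window` | [0, 25) | mya | brackets the 5-15 mya WGD |
| `old_age_window` | [40, 80] | mya | brackets the 50-60 mya WGD |
| `tandem_max_intervening_genes` | 5 | genes | tandem adjacency bound |
| `permutations` | 10000 | draws | Monte Carlo P resolution |
| `beta_categories` | 10 | classes | M7/M8 discretization |
| `evalue_max` | 1e-10 | — | hit filter for chaining |
| `min_anchors` | 4 | anchors | smallest reportable block |
| `window_bp` | 100000 | bp | cross-species flanking window |

A single `rng_seed` governs every stochastic stage through fixed per-stage
substreams, so a pipeline run is byte-reproducible.

## Degenerate inputs and tie-breaks

Identical sequences give zero distances; the bootstrap flags the star-tree
outcome instead of fabricating support. Fewer than three Ks values are
averaged without trimming, with a warning. Ties in NJ are broken
lexicographically; chaining ties resolve to the earliest predecessor, making
block output invariant to hit order. A segmental candidate without an
available dating is emitted with an ambiguous age and a warning rather than
dropped. Saturated distances are errors at the estimator level and dropped
replicates at the bootstrap level.

## Known limitations

* LCA reconciliation without loss modelling undercounts ancestors when
  entire descendant clades are missing; counts are exact only under the
  no-loss regime the recovery tests use.
* Branch-shape misfit can inflate the M7-vs-M8 LRT on distance-derived
  trees (see above); per-branch re-estimation is out of scope.
* The per-site positive-selection output is naive empirical Bayes — no
  parameter uncertainty is propagated.
* Dating inherits all molecular-clock caveats; only a single calibration
  rate is supported, with no rate-heterogeneity correction or whole-paranome
  Ks mixture deconvolution.

## Problem sizes used by the test suite

The suite's replicate studies run at desk scale, chosen once: 200 null and
50 selection replicates for LRT calibration and power (8 taxa, 300 codons),
30 random additive matrices for NJ recovery, 100 seeded histories for
reconciliation recovery, 10 000 codons for the clock-calibration check, and
two full pipeline runs on the nine-family fixture for byte-level
determinism. `scripts/acceptance.R` recomputes the same quantities with
smaller replicate counts (reported in its JSON `n` fields) plus the
printed-table recomputations, from a user-supplied seed.
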