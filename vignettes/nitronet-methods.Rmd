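---
title: "nitronet: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nitronet: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitronet)
```

# The problem

Plants reorganize their transcriptome and metabolome when nitrogen becomes
scarce, and the response to a *sudden drop* in nitrate (sufficient → limiting,
"reduction") differs from the *adapted* low-nitrogen state. nitronet
implements the analysis chain used to dissect such data: cluster genes by
co-expression across nitrogen condition × tissue combinations, summarize each
cluster by an eigengene, ask which clusters track which conditions, which
transcription factors sit at cluster centres, which functional terms are
over-represented, and which metabolites respond proportionally versus
non-proportionally to the nitrate level.

# The co-expression model

## Adjacency

For gene profiles $x_i$ over the collapsed samples, the weighted adjacency is

$$a_{ij} = \lvert \mathrm{cor}(x_i, x_j) \rvert^{\beta},$$

the soft-thresholded absolute Pearson correlation. We default to the unsigned
form: a power transform of a signed quantity could not stay in $[0,1]$, which
the topological overlap formula requires, so descriptions of a "signed matrix
from −1 to 1" can only refer to the correlation matrix itself. A
signed-magnitude alternative $((1+\mathrm{cor})/2)^{\beta}$ is available via
`mode = "signed"` for users who want anti-correlated genes pushed apart.

$\beta$ is chosen from a scan (integers 1–20 by default — the grid is a
convention, not a sensitivity point) using the scale-free fit index: bin the
connectivities $k_i = \sum_{u \ne i} a_{iu}$ into 10 equal-width bins, regress
$\log_{10}$ frequency on $\log_{10}$ mean-$k$, and sign the $R^2$ by
$-\mathrm{slope}$ so that positive-slope fits can never look scale-free. The
selection rule is deliberately *not* "first power to reach the target": it is
the last power **before** the curve reaches $R^2 = 0.90$, which retains more
mean connectivity. When the first candidate already exceeds the target it is
returned itself; when nothing reaches the target the argmax is returned with a
warning.

## Topological overlap

$$\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

with $\omega_{ii} = 1$. Connectivity excludes the diagonal — this is what
makes the isolated-pair identity $\omega_{12} = a_{12}$ hold exactly, which we
use as a closed-form test. The vectorized implementation (one matrix product)
is checked against a triple-loop oracle to $10^{-12}$ on random instances.
Genes are clustered on the dissimilarity $d_{ij} = 1 - \omega_{ij}$ with
complete linkage; an opt-in mode computes Euclidean distances between TOM rows
instead, preserving an alternative literal reading of "Euclidean distance on
the TOM dissimilarity" that is otherwise internally inconsistent.

## Module detection and merging

The dendrogram is cut tree-style: a static cut at 99 % of the tallest merge
defines major branches, and inside a branch a child subtree is detached when
it hangs below its parent merge by more than a fraction (`gap_fraction`,
default 0.25 — fixed once; larger values undersplit chained noise, smaller
values shatter real blocks) of the branch's height range *and* contains at
least `min_size` leaves (default 30, the field's conventional minimum).
Undersized leaf sets get label 0 (unassigned). The per-child detachment rule
matters: testing only the top gap fails the canonical case of several tight
blocks whose pairwise joins all sit near the top of the tree. No PAM-style
reassignment stage is implemented. Labels are renumbered by decreasing size
with ties broken by smallest leaf index, so the cut is deterministic;
`stability_check()` verifies invariance under gene-order permutation.

Each module's eigengene is the first principal component of its standardized
member profiles (per-gene standardization, otherwise bright genes dominate),
scaled to unit norm, signed so the mean member correlation is non-negative.
Modules merge while any eigengene pair correlates above 0.65: average-linkage
clustering of eigengenes on $1 - \mathrm{cor}$, cut at 0.35, relabel,
recompute, repeat to convergence (≤ 10 passes; module count is non-increasing
by construction). Iterating rather than one-pass merging is a choice — the
per-pass counts are recorded so either behaviour is auditable.

# Association statistics

Module–trait association is the Pearson correlation between an eigengene and
a binary condition/tissue indicator, with the Student-$t$ transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Both combination traits
("reduced.leaf") and condition-pooled traits ("LN") are emitted, because
published module–trait heatmaps mix the two granularities. With the default
design collapsed to $n = 8$ columns, $r = 0.91$ gives $p \approx 0.0017$ —
consistent with a printed "< 0.002" bound, which is also the internal
consistency check for using 8 median-collapsed columns rather than 24
replicate columns in the network.

Module membership is $\mathrm{MM}_i = \mathrm{cor}(x_i, E^{(q)})$ for the
gene's own module; ranks are MM-descending with ties broken by gene id. For
the top-ranked transcription factor at observed rank $r_{obs}$ among $n$
module genes of which $m$ are TFs, the primary significance measure is the
tail probability of the best TF rank under uniform random ranking:
Monte-Carlo over `n_perm` random orderings with the
$(\#\{R^* \le r_{obs}\}+1)/(n_{perm}+1)$ estimator, plus the closed form
$1 - \binom{n-r_{obs}}{m}\big/\binom{n}{m}$. A one-sample Wilcoxon
signed-rank test of the null ranks against $r_{obs}$ is reported alongside
because rank-centrality analyses sometimes quote it, but it is a location
test of the null distribution, not a tail probability, and the two can
disagree; we deliberately do not privilege it. No multiple-testing correction
is applied across modules (raw p-values are the convention here).

# Enrichment

Flat-annotation singular enrichment: one-sided hypergeometric tail per term
with $k \ge 1$ module genes, Benjamini–Hochberg within each module, flag at
$q \le 0.05$. The universe defaults to *annotated genes in the network* — not
the genome — because the background choice materially changes p-values; it is
an explicit argument. No GO DAG propagation: annotations are used as given,
so term counts are not comparable to DAG-aware web tools.

# Metabolite response patterns

Missing values are left-censored detection dropouts, imputed with the
per-compound observed minimum *before* the natural-log transform (that order
is the stated convention). Welch's unequal-variance $t$ (Welch–Satterthwaite
df) runs on the log scale; fold changes are reported as ratios of arithmetic
group means on the original scale, because that is what printed comparison
tables contain (a means-of-ratios alternative was considered and rejected as
the non-default — the ratio-of-means is reproducible from group summaries).
Significance uses the dual cut-off $p \le 0.05$ and BH $q \le 0.10$ per
contrast. The three contrasts are adaptation HN/LN, induction (LN→HN)/LN and
reduction (HN→LN)/HN.

Patterns per compound: **proportional-HN** (higher under sufficient N, not
further elevated by reduction), **LN-accumulating** (HN/LN significantly
below 1), **non-proportional-reduction** (not above 1 under adapted HN — or
not significantly — yet significantly elevated after the HN→LN shift; the
remobilization signature), **unchanged**, **other**. The classifier is a
total function and also accepts printed ratio + significance-star input
(`classify_from_ratios()`), which is how published table rows are checked
without raw data.

# The synthetic world

`generate_expression()` plants block-correlated modules: one latent signal
per module, drawn at the (condition, tissue) level and shared by replicates —
expression is condition-driven, which is also what makes median collapse
preserve the planted structure exactly. Trait-linked signals are
$r\,z(\mathrm{indicator}) + \sqrt{1-r^2}\,z(\text{orthogonalized noise})$, so
the planted eigengene–trait correlation is exact, making trait-recovery tests
sharp rather than approximate. Member genes are
$w\,s + \sqrt{1-w^2}\,\sigma\,\varepsilon$ with $w$ = `within_module_cor`
(default 0.9) and `noise_sd` $\sigma$ (default 1, at which the expected
gene–signal correlation equals $w$ exactly; 0 gives noiseless rank-1 blocks).
The default design is the study layout: 2 tissues × 4 conditions × 3
replicates = 24 samples, collapsing to 8. Defaults are calibration choices
for a recoverable-but-not-trivial world, not estimates of any real dataset.

What the generator does **not** emulate: probe-level artefacts, distribution
heavy-tails of real arrays, correlated background genes, GO-term biology
(annotation fixtures are arbitrary labelled sets), and — importantly —
minimum separation between module signals. Independent latent signals on 8
samples collide by chance: about a fifth of seeds produce a signal pair
correlated above the 0.65 merge threshold, and the pipeline then (correctly)
merges the two planted modules. Over 100 seeds the full-chain adjusted Rand
index against the raw planted labels has mean ≈ 0.92 and median ≈ 1.0 with a
heavy lower tail. A green recovery test therefore establishes that the chain
recovers identifiable structure; it does not establish that every random
world is identifiable, and we chose not to "repair" the truth labels
post hoc. `generate_metabolites()` plants log-normal abundances whose
*arithmetic-mean* group ratios equal the planted ratios exactly (the log-mean
offset is CV-corrected), with binomial left-censoring of the lowest values
per compound to match minimum imputation.

# Numerical and degenerate-input choices

* Zero-variance genes cannot be correlated: dropped with a warning before
  adjacency; MM undefined (flagged) in membership.
* Constant trait indicators are unusable and skipped with a warning.
* Welch test with zero variance in both groups and equal means returns
  $t = 0, p = 1$ rather than erroring.
* $m = 1$ permutation draws are vectorized (the single TF's rank is uniform
  on $1..n$) — distributionally identical, two orders of magnitude faster.
* All randomness is funnelled through explicit integer seeds; equal spec +
  seed reproduces bit-identical outputs.
* TOM denominators are guarded although they cannot be non-positive under
  the adjacency invariants.

# Known limitations

No block-wise approximate network construction: dense $G \times G$ matrices
limit practical size to a few tens of thousands of genes on a large-memory
machine. No dynamic-hybrid (PAM) cut refinement, no bootstrap module
significance, no DAG-aware enrichment, and the TF rank test's published
operating characteristics cannot be reproduced without the original module
composition — the package reproduces the *procedure* and verifies it against
closed forms and calibration instead.
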