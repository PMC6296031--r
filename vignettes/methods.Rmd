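---
title: "Methods: longitudinal microglia transcriptome analysis with ensemble co-expression networks"
author: "gliadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliadyn)
```

# Scope and design

`gliadyn` implements the statistical backbone of a longitudinal bulk RNA-seq
study of microglia in a tauopathy mouse model (rTg4510 transgenic vs
wild-type, sampled at 2, 4, 6 and 8 months with four replicates per
genotype-age cell), together with the network stages used to relate the
mouse differential-expression results to a human brain co-expression
network. Every stage can be exercised on synthetic data with planted ground
truth, so the whole pipeline is testable without any external download.

The stages, in order:

1. **Sample QC exclusion** — a sample is excluded iff any tracked metric
   (mapping rate, mapped reads, 3' bias, rRNA/mito fraction, adapter
   content) falls outside its configured pass range.
2. **Exon-to-gene rollup** — exon filtering, a robust two-way fit per gene,
   and per-sample median normalization.
3. **Factorial differential expression** — per-gene 2 × 4 genotype-by-month
   cell-means OLS, genotype contrasts at each age, per-contrast BH FDR.
4. **Temporal clustering** — correlation-distance hierarchical clustering of
   DEG trajectories into four canonical longitudinal patterns.
5. **Gene-set and regulator statistics** — hypergeometric
   over-representation analysis and signed-regulon activation z-scores.
6. **Ensemble network inference** — several base co-expression methods,
   mean-rank aggregation, BIC neighborhood edge selection, consensus
   community detection, marker-based cell-type annotation.
7. **Cross-species mapping** — ortholog conversion, Fisher overlap
   enrichment with odds ratios and Q-values, and degree-based connectivity
   comparison between DEG age groups.

# The rollup model

Gene-level signals are summarized from exon-level counts under the two-way
additive model

$$\log_2(x_{es} + 1) \approx \mu_s + \alpha_e,$$

where $\mu_s$ is the gene's signal in sample $s$ and $\alpha_e$ is a fixed
exon effect (exon proportions are assumed constant across libraries).
Before fitting, exons are filtered with a strict rule: an exon is removed
when **more than** 80% of samples have **fewer than** 10 counts; exactly
80% low is retained, and a count of exactly 10 is not low. Genes whose
exons are all removed are dropped and reported.

The robust fit defaults to median polish (alternating row/column medians,
at most 20 sweeps, tolerance $10^{-6}$); hitting the sweep cap is accepted
rather than warned about. After polishing, the mean exon effect is folded
into the overall term so that exon effects are centered at zero mean —
this makes the recovered sample effects equal the true $\mu_s$ exactly on
noiseless additive data whose exon effects sum to zero, and makes the
output equivariant under adding a constant. Huber M-estimation
(`MASS::rlm` with sum-to-zero exon contrasts) is available as an option;
both resist a single wildly corrupted cell (+20 log2 units) to within 0.1,
where a plain per-sample mean is displaced by 20 divided by the number of
exons. A single-exon gene passes through unchanged.

Normalization is additive per-sample median centering on the log2 scale:
each sample is shifted so its median equals the grand median of per-sample
medians, and the offsets are recorded. The alternative reading of the
normalization step (centering each gene's mean across samples) is not
applied by default; `rollup(..., normalize = FALSE)` gives access to
unnormalized signals for callers who want a different convention. The
log2 pseudocount is 1.

# Differential expression

Each gene is fit by OLS on the full-interaction cell-means parameterization
of the 2 × 4 design; the residual variance is pooled across all eight
cells, giving $N - 8$ degrees of freedom. The contrast at age $m$ is the
TG−WT cell-mean difference with the usual pooled-variance t statistic. No
empirical-Bayes moderation is applied — the model is a plain factorial
linear model, and the no-moderation choice is deliberate so that p-values
have their exact finite-sample distribution under Gaussian noise (the test
suite checks uniformity under the null by Kolmogorov–Smirnov).

Degenerate genes (zero pooled residual variance) receive explicit
conventions: a zero contrast gets $p = 1$; a nonzero contrast with zero
residual gets $p = 0$ and the gene is flagged.

DEGs are called with the strict double threshold **FDR < 0.05 and
|fold change| > 1.5**, where the fold change is the signed anti-logged
value $\mathrm{sign}(\beta)\,2^{|\beta|}$ (so down-regulation means
fold change < −1.5) and FDR is Benjamini–Hochberg applied **within each
age's contrast** separately across genes; no across-age correction is
performed. A gene at exactly 1.5-fold is not a DEG regardless of its FDR.

Summaries reproduce the study's bookkeeping: per-age totals split by
direction and by |fold change| above/below 2, the 15-cell Venn partition
over the four age sets, and the persistence fraction — the share of
earliest-age DEGs that remain DEGs at every later age.

# Temporal clustering

Profiles are per-cell medians across replicates (an 8-vector per gene:
WT then TG at each age), standardized per gene; constant profiles are
excluded and reported. The distance is $1 - r$ (Pearson), which is
invariant to affine rescaling of a profile. Linkage is **average**, not
Ward: Ward's minimum-variance update is only meaningful for squared
Euclidean distances, and the sample-level clustering (where the data are
standardized per gene and distances are Euclidean) is the only place Ward
is used. The tree is cut at $k = 4$; a gap-statistic helper is provided
for exploration but the default analysis fixes $k$.

Cut clusters are renumbered onto four canonical longitudinal patterns
(1: TG down with age, WT flat; 2: TG up, WT flat; 3: TG up with a
mid-course peak, WT down; 4: TG down, WT moderately up) by maximizing the
total correlation between cluster median profiles and the canonical
curves over all 24 renumberings — an exact assignment at $k = 4$.

# Gene sets and upstream regulators

Over-representation analysis uses the hypergeometric upper tail
$P(X \ge k)$ for a query of size $n$ against a set of size $K$ in a
universe of size $N$, BH-adjusted across sets, with the significance
convention $p < 0.05$ **and** $q < 0.1$. The universe defaults to the union
of the collection and should in practice be the set of genes surviving
rollup.

The upstream-regulator statistic takes a user-supplied signed regulon file
(regulator, target, predicted sign). Over a regulon's targets that are
DEGs at the chosen age,

$$z = \frac{\sum_t \mathrm{match}_t}{\sqrt{N}}, \qquad
\mathrm{match}_t = \begin{cases} +1 & \text{predicted = observed sign} \\
-1 & \text{otherwise,} \end{cases}$$

so $|z| \le \sqrt{N}$ with equality iff all matches agree (or all
disagree). The accompanying p-value is the direction-blind hypergeometric
enrichment of the regulon's targets in the DEG list, which guards against
biased sign annotations. The "top regulators" gate is: keep $p < 0.05$,
rank by $|z|$ descending, break ties lexicographically, take the top 10.
A regulon with no DEG targets has an undefined $z$, reported as missing.

# Ensemble network inference

Six base methods produce symmetric non-negative weight matrices:
soft-threshold correlation adjacency $|r|^\beta$ (default $\beta = 6$);
binned mutual information with ARACNe-style DPI pruning; lasso and ridge
per-node neighborhood regressions (per-node penalty chosen by BIC along
the path, weights symmetrized by the larger directed magnitude); an
MRMR-style forward selection on the MI matrix; and a max-MI-per-node
filter. The tree-ensemble and stability-selection members of the original
nine-method ensemble are represented by the neighborhood-regression
family — the ensemble contract (rank aggregation over edge lists) is
method-agnostic.

**MI estimator.** Equal-frequency binning with $\lceil\sqrt{n}\rceil$ bins
(rank-based, deterministic under ties) and the Miller–Madow small-sample
correction. The correction is load-bearing: the plug-in estimator's upward
bias is roughly constant across pairs (about $(B-1)^2/2n \approx 0.5$ nat
at these bin counts), which flattens the *relative* differences that DPI
pruning compares; without it the indirect edge of a noisy Markov chain
survives pruning in most runs. The DPI tolerance is $\varepsilon = 0.15$:
the weakest edge of a triangle is zeroed when it falls below
$(1-\varepsilon)$ of the smaller of the other two.

**Rank aggregation.** Within each method, edges are ranked by descending
weight with average ranks for ties, over the common pair universe; the
aggregate is the arithmetic mean rank, with deterministic ordering by
(mean rank, lexicographic pair id). Methods with different pair universes
are rejected rather than silently intersected.

**BIC edge selection.** For each node, candidate neighbors are taken in
aggregate-rank order and added greedily to a linear regression of the node
on its selected neighbors while the BIC strictly decreases, stopping at
the first non-improvement or at the neighborhood cap (default 10). The
final edge set is the **union** over nodes. On pure noise this keeps the
mean neighborhood near 0.3 when the aggregated methods are diverse
(correlation, MI, lasso); aggregating two near-identical
correlation-shaped methods instead lets each node's top candidate be its
maximal-|r| partner and pushes the null neighborhood size toward 1, which
is why the shipped configuration mixes estimator families.

**Consensus modules.** Louvain, walktrap, fast-greedy and label
propagation are run under fixed seeds; the node-pair co-assignment
frequency matrix is thresholded at 0.5; the consensus graph is partitioned
by Louvain with a fixed seed; modules are numbered by decreasing size with
ties broken by smallest member id. Cell-type labels come from Fisher
enrichment against disjointified marker sets (genes in more than one
marker set are dropped), labeling a module only when the best cell type's
BH q-value is below 0.05.

# Cross-species mapping

DEG sets are mapped through a two-column ortholog table; in one-to-one
mode, sources with zero or multiple targets (and targets claimed by
multiple sources) are dropped and reported. Overlap enrichment builds one
2 × 2 table per (DEG set, module) pair over the shared universe —
implemented as the intersection of the mapped universe and the network
node set, since the published analysis leaves the universe unstated — with
Fisher's exact two-sided p, BH Q-values across all pairs, and the sample
cross-product odds ratio $ad/bc$ with the Haldane–Anscombe 0.5 correction
when any cell is zero (the conditional MLE that `fisher.test` reports is
*not* used as the headline OR). Connectivity comparisons extract network
degrees per age group and use the two-sided Wilcoxon rank-sum test, exact
when both groups have at most 12 genes and no ties, otherwise the
tie-corrected normal approximation with continuity correction.

# The synthetic-data generator

The generator is first-class, tested code; it defines the conditions under
which every downstream guarantee is demonstrated.

* **Design**: 2 genotypes × ages {2, 4, 6, 8} × 4 replicates (32 samples);
  a configurable number of samples receives a corrupted mapping rate so the
  QC stage excludes exactly the 28-of-32 scenario.
* **Counts**: negative binomial with variance $\mu + \mu^2\phi$. Gene
  baselines are log-normal around $2^{10}$ counts (log2 mean 10, sd 0.5),
  per-gene dispersion $\phi$ log-normal (median 0.02, sdlog 0.3), library
  factors log-normal (sdlog 0.05). These emulate deep sequencing of sorted
  cells from inbred animals: low biological dispersion and tight library
  sizes. They are also what makes the generator's calibration guarantee
  attainable — each planted gene's realized mean log2 group difference
  stays within ±0.2 of its pattern curve at 50 replicates per cell; with
  high dispersion or strong depth variation the low-count tail alone
  exceeds that band.
* **Exons**: 1–10 exons per gene with Dirichlet proportions fixed across
  samples, matching the rollup model's assumption.
* **Patterns**: piecewise-linear log2 shift curves per genotype, zero at
  the first age and reaching up to ±3 log2 at the terminal age, one curve
  pair per canonical pattern.
* **Co-expression**: a latent-factor model — genes in a module load on an
  independent module factor plus independent noise, so the expected
  within-module correlation $\ell^2/(\ell^2+\sigma^2)$ strictly exceeds
  the between-module expectation of zero.
* **Auxiliary files**: GMT sets built from the planted patterns plus
  random null sets; one "active" regulator per pattern whose predicted
  signs equal the pattern's terminal direction, plus null regulators with
  random targets and signs; marker sets collecting module genes by
  cell-type label; a one-to-one ortholog map over a configurable fraction
  of the universe.

What the generator does **not** emulate: GC/length biases, batch effects,
sample-to-sample correlation structure, sex as a covariate (the emulated
study used females only), isoform-level variation, and realistic
effect-size distributions — planted effect sizes are chosen for
testability. Passing the planted-recovery suites therefore demonstrates
correctness of the statistics, not performance on real tissue data.

# Numerical conventions and degenerate inputs

* Seeds fully determine every generated object; generation restores the
  caller's RNG state.
* BH is `p.adjust(..., "BH")`, cross-checked in the tests against the
  hand-written step-up formula.
* Zero-variance genes are excluded (and reported) before PCA, correlation
  clustering and standardization; a constant input matrix is an error.
* PCA component signs are fixed by making the largest-magnitude loading
  positive.
* Ties: average ranks within methods; lexicographic pair ids; module
  renumbering ties broken by smallest member id; regulator ranking ties
  broken lexicographically.
* An empty consensus graph degenerates to one module per node.

# Problem sizes used by the checks

The shipped test suite and the acceptance script demonstrate the
guarantees at desk scale, chosen as the smallest sizes at which each
property is comfortably away from its Monte-Carlo noise floor: null-FDR
calibration at 2000 genes across replicate simulations; power at 100
planted genes per run; temporal-pattern recovery at 200 genes per pattern;
end-to-end network recovery at 120 genes, 4 modules, 300 samples; DPI
behavior over 20 replicate chains. The published-count worked examples
(persistence percentage, cluster shares, signature shares, per-age table
reconstructions) are exact arithmetic on the bundled reference tables.

# Known limitations

* The regulator statistic implements the unweighted activation z-score;
  knowledge-base edge weights and bias corrections are out of scope, so
  numeric agreement with proprietary tools is not expected.
* The Fisher universe convention and the ortholog-mode default
  (one-to-one) are configurable because the published analysis does not
  pin them down; results are sensitive to both.
* Count-based GLMs, variance moderation, mixed models and surrogate
  variables are deliberately absent: the DE model is the plain factorial
  OLS described above.
* The network stages assume approximately continuous expression values;
  they are not designed for sparse single-cell matrices.
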