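---
title: "Convergence analysis for pooled CRISPR-KO screens: models and methods"
author: "koconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence analysis for pooled CRISPR-KO screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koconverge)
```

# The scientific problem

When many different risk genes for the same disorder are knocked out one at
a time in the same cellular context, their downstream transcriptomic
effects often *converge*: a shared set of genes moves in the same direction
under every perturbation. Quantifying that convergence — which genes, how
strongly, in which cell types, predictable from what — is the core job of
this package. It provides the full analysis chain for pooled CRISPR-KO
perturbation screens: convergent-gene calling by meta-analysis, a composite
network-convergence score, similarity features that predict convergence
strength, an in silico perturbation engine, signature-reversal drug
queries, and behavioral rescue classification, all exercisable end to end
on synthetic data with planted ground truth.

# Convergent genes by meta-analysis

Each knockout (KO) contributes a differential-expression summary per gene:
log2 fold change $\beta_i$, standard error $se_i$, p-value $p_i$, sample
size $n_i$. `meta_analyze()` combines studies per gene; the default method
is the signed Stouffer (sample-size weighted) combination used by
P-value-based meta-analysis tools,

$$Z = \frac{\sum_i w_i Z_i}{\sqrt{\sum_i w_i^2}},\qquad
w_i = \sqrt{n_i},\qquad
Z_i = \mathrm{sign}(\beta_i)\,\Phi^{-1}(1 - p_i/2),$$

with an inverse-variance alternative
($\hat\beta = \sum_i \beta_i/se_i^2 \,/\, \sum_i 1/se_i^2$) retained for
effect estimation. Cochran's heterogeneity statistic
$Q = \sum_i (\beta_i - \hat\beta)^2 / se_i^2$ (df $= k - 1$) is always
computed on the effect scale with inverse-variance weights, even when the
combined p comes from the sample-size method: significance can be combined
on the p scale, but heterogeneity is a property of effects. A gene is
**convergent** (`call_convergent()`) iff

* Benjamini–Hochberg FDR of the meta p-value $< 0.05$,
* Cochran's $Q$ p-value $> 0.05$ (no detectable heterogeneity), and
* every study's log2FC has the identical nonzero sign.

A zero fold change carries no direction and blocks the call. BH is applied
within each (cell type × KO subset) analysis, because each subset is its
own experiment; a global correction across thousands of subsets would
couple analyses that are reported separately. Gene-level convergence
strength is the ratio of convergent genes to the mean per-KO DEG count
(`convergence_ratio()`).

`enumerate_ko_subsets()` enumerates all KO subsets in a size range
exhaustively (e.g. 502 subsets of sizes 2–9 from nine KOs; 372 of sizes
2–5), with optional seeded down-sampling for large designs. The companion
visual tools are `rrho_map()` (rank–rank hypergeometric overlap: signed
$-\log_{10} p$ of top-list overlaps on a threshold grid, positive for
enrichment above expectation, negative for depletion) and
`correlate_profiles()` (pairwise Pearson correlation of log2FC profiles
over the union of genes nominally significant, $p < 0.01$, in either
member).

# Network-level convergence

`build_consensus_network()` stands in for sparse-factor co-expression
reconstruction: over `n_runs = 40` bootstrap resamples it emits edges with
$|r| \ge$ `corr_min` and keeps those reappearing in at least a `dup_min`
fraction of runs, recording per-edge duplication counts. The builder is a
declared stand-in — it reproduces exactly the two properties the score
consumes (co-expression edges and per-edge run duplication) and is
pluggable, so a heavier factor-model builder can be swapped in without
touching the score.

`network_convergence_score()` computes the composite

$$\mathrm{score} = C_p + \big[\mathrm{max}L_p - L_p\big]
  + \mathrm{mean}\!\Big(\textstyle\sum \mathrm{MF} + \mathrm{BP} +
    \mathrm{CC}\ \mathrm{semsim}\Big)
  + \frac{n_\mathrm{dup}}{n_\mathrm{runs}},$$

where $C_p$ is the mean local clustering coefficient (degree-<2 nodes
contribute 0), $L_p$ the mean shortest path over connected ordered pairs
(disconnected pairs excluded and counted), $\mathrm{max}L_p$ the largest
$L_p$ in the scored collection, the semantic term averages the
three-namespace similarity *sum* over unordered node pairs, and the
duplication ratio uses the **minimum** edge duplication over retained edges
— the most conservative reproducibility reading. Two genuinely open choices
were fixed and documented: the reference collection for $\mathrm{max}L_p$
is the batch of networks scored together (configurable; a single-network
batch gets a zero path term), and duplication is per-edge minimum rather
than per-node or whole-network.

# Semantic similarity and convergence prediction

Term information content is corpus-based, $IC(t) = -\log(n_t / N)$
(natural log; only relative comparisons matter). Term similarity defaults
to Lin, $2\,IC(\mathrm{MICA}) / (IC(t_1) + IC(t_2))$, with Resnik
(max-IC, normalized by the corpus maximum) as an alternative; gene-to-gene
similarity is the best-match average over the genes' *directly annotated*
terms — using ancestor-closed sets would let every pair share the root and
inflate all similarities — and KO-set similarity is the mean over unordered
gene pairs. Annotations are always propagated to ancestors (true-path
rule) before IC computation, matching standard ontology semantics.

`train_convergence_model()` fits a 500-tree regression random forest
(`mtry = ceil(p/3)`, the standard regression default) on BP/CC/MF
similarity, brain co-expression correlation, KO-set size and one-hot cell
type, with a seeded 70/30 split stratified by cell type. Importances are
out-of-bag permutation %IncMSE and node-purity increase; evaluation reports
RMSE and Pearson r on the holdout. Predictions on new rows impute missing
numeric features by training medians and refuse unseen cell-type levels.

# The energy model and in silico knockouts

The in silico engine is a Gaussian energy model over the concatenated
expression vector of a bulk context plus $C$ cell-type contexts across a
gene panel. Each context contributes a precision block whose off-diagonal
support is exactly that context's gene regulatory network (GRN), and a
deconvolution penalty $\lambda \sum_g (x_{0g} - f^T x_{1..C,g})^2$ couples
each bulk gene to the cell-fraction-weighted combination of its cell-type
copies. One convention to note: the quadratic-form matrices are interpreted
directly as precision blocks — the conventional factor of 2 between an
energy $x^T J x$ and a Gaussian precision is absorbed into $J$, which only
rescales the interaction weights. Assemblies that are not positive definite
are repaired by diagonal loading (logged) or rejected with the offending
eigenvalue.

A knockout clamps one coordinate at $\mathrm{sign} \times k$ (defaults:
$k = 2$, negative sign, mimicking strong knockdown on the Z-scored
expression scale). Because the energy is quadratic, the "infinitely strong
clamp" limit is analytic: `lnctp_perturb()` conditions the Gaussian
exactly via the partitioned precision,
$E[x_r \mid x_j = v] = \mu_r - \Omega_{rr}^{-1}\Omega_{rj}(v - \mu_j)$,
and reports $\Delta = E[x] - E[x \mid \mathrm{clamp}]$ (before minus
after, so knocking a gene down gives positive $\Delta$ at the target). A
Gibbs sampling estimator of the same expectation is retained for parity
with sampling-based workflows; its standard errors use 20-batch means to
absorb autocorrelation, and closed form and sampler agree within 3 SE in
the test suite. The clamped coordinate's $\Delta$ equals
$\mu_j - \mathrm{sign}\,k$ to machine precision by construction. When the
model carries per-individual genotype mean shifts, deltas are averaged
across individuals; `fit_reduced_model()` learns the genotype-free reduced
model by node-wise ridge pseudolikelihood (default ridge $10^{-3}$)
restricted to GRN support, with $(i,j)/(j,i)$ averaging — support
exactness is enforced, not estimated.

In silico convergent genes for a perturbation set use a two-tailed
one-sample sign test on the deltas that clear a noise threshold
$|\Delta| \ge \tau$ (default $\tau = 0.3$):
$p = \min(1,\ 2\,P(\mathrm{Binom}(n, \tfrac12) \le \min(n_+, n_-)))$,
convergent iff $p < 0.1$. The doubling form (capped at 1) is used because
it matches exact enumeration of the fair-coin tail; a consequence worth
stating is that at $\alpha = 0.1$ at least five sign-consistent qualifying
perturbations are required, so genes with fewer qualifying entries are
flagged *untestable* rather than non-convergent. Set comparisons use
two-sided Fisher/hypergeometric tests against the full model panel as
background, and `semantic_distance_test()` compares between-set versus
within-set Jaccard similarity of enriched terms' leading edges with a
one-sided rank-sum test.

# Enrichment machinery

`hypergeom_ora()` is the one-sided upper-tail hypergeometric test with an
observed/expected enrichment ratio. `gsea_preranked()` implements the
weighted Kolmogorov–Smirnov running sum (weight exponent 1 by default;
0 recovers the classic statistic — which of the two a given published
analysis used is often unstated, and weighted is the modern default), with
leading-edge extraction at the signed extremum, gene-label permutation
p-values, and NES normalized by the mean absolute same-sign permutation
score. `bh_fdr()` delegates to the standard step-up implementation.
`downsample_enrichment()` re-runs ORA on seeded subsamples of each gene
set at sizes (100, 250, 500, 750, 1000) × 10 repetitions — 50 tests per
eligible set — to separate genuine enrichment from set-size artifacts.

# Behavioral fingerprints and drug rescue

Larval behavior tables are long-format measurements of 24 parameters (six
visual-startle parameters for lights-off and lights-on stimuli; six
sleep/wake parameters for day and night). `fit_behavior_effect()` fits
`value ~ group + (1 | batch_date)` and reports a Wald normal p for the
group coefficient (the mixed-model p-value method is configurable in
principle; the Wald normal approximation is the simplest defensible choice
and single-batch data fall back to OLS). A mutant's fingerprint is the
24-vector of $\mathrm{sign}(\beta)(-\log_{10} p)$; it flips sign exactly
under label swap. Mutants cluster by average-linkage on $1 - r$ over
fingerprints; drugs match a mutant when $|r| > 0.5$ with $p < 0.05$,
labeled correlate or anti-correlate by sign.

`cmap_query()` scores an up/down query against ranked signatures: weighted
KS enrichment of each query set, combined as
$\mathrm{wtcs} = (ES_{up} - ES_{down})/2$ when the two scores oppose and 0
otherwise; NCS divides by the mean same-sign wtcs within the signature's
perturbation group; FDR is the fraction of vehicle ("null") signatures
whose $|NCS|$ reaches the reference's. A signature is a *reverser* when
$NCS \le -1.00$ and $FDR \le 0.05$.

`classify_rescue()` gates on a nominally significant mutant effect
($p < 0.06$, strict — the mixed use of $<$ and $\le$ in verbal category
definitions is resolved as strict $<$ for the gate and $\ge$ for the
rescued condition) and assigns, in precedence order: **rescued** (drug
contrast no longer significant), **over_corrected** (significant, flipped
sign), **partial_rescue** (significant, same sign, smaller $|\beta|$),
**exacerbated** (p at least as strong and larger $|\beta|$, same sign;
"appreciably larger" is realized as strict inequality with no extra
margin), else **unchanged**. The classifier is verified against a
brute-force truth table over a full (p, beta) grid.

# gRNA abundance contracts

Counts from sorted-fraction screens are normalized by the per-sample *sum*
of scramble-control counts (sum, mean, or median would all be consistent
with common practice; the sum is used and documented), making all
downstream log2 fold changes exactly depth-invariant. Gene abundance sums
retained guides, excluding guides with editing efficiency strictly below
5% when efficiencies are provided. Fraction and condition log2FCs guard
ratios with a pseudo-abundance of $10^{-9}$ applied to normalized
abundances (not raw counts) and average replicates on the log scale.

# What the synthetic data emulates — and what it does not

Every generator is a pure function of (config, seed).

* `simulate_perturbation_screen()` plants `n_convergent_true` genes whose
  single true effect (direction random, magnitude
  $\mathcal N(1.0,\ 0.25)$ log2FC by default) is shared by all KOs in the
  designated cell type; all other gene × KO effects are exactly zero, so
  the non-planted background is a calibrated global null. Standard errors
  are $noise\_sd/\sqrt{per\_ko\_n}$ with per-gene lognormal jitter
  (sdlog 0.2) so that inverse-variance and sample-size weighting are
  distinguishable in tests. Defaults (9 KOs, 2000 genes, 100 planted,
  4 pseudobulk replicates, noise 0.5) give ≥90% recall at ≤5% false calls
  end to end. The published noise model of pseudobulk log2FCs is not
  stated anywhere we could adopt it from; these defaults are declared, not
  inferred.
* `simulate_lnctp_population()` draws individuals from the energy model
  itself, so parameter-recovery tests have exact ground truth; its sample
  covariance converges entrywise at the $1/\sqrt{n}$ rate.
* `simulate_ontology()` builds a random rooted DAG with true-path
  propagated annotations — topology only, no biological term structure.
* `simulate_behavior_table()` uses Gaussian residuals and Gaussian batch
  intercepts (the working assumption of the mixed model itself; empirical
  behavioral distributions are heavier-tailed), with genotype and drug
  shifts added on the mutant rows.
* `simulate_grna_counts()` is multinomial at fixed depth with lognormal
  library composition and planted per-fraction log2 shifts.

None of the generators model raw read- or UMI-level single-cell data,
droplets/doublets, demultiplexing, or real GO term structure. Passing
tests therefore demonstrate correctness of the statistical machinery and
recoverability under the generators' assumptions — not robustness to the
full noise structure of real screens.

# Numerical choices and problem sizes

Diagonal loading for indefinite precisions doubles geometrically from
`1e-6`-scale steps (30 attempts max, logged). P-values are floored at
`1e-300` before $-\log_{10}$ or inverse-normal transforms. Expression-bin
matching in `module_score()` uses 24 equal-frequency bins with 100 control
draws per set gene, and accepts a reference average profile so a
perturbed matrix can be scored against its baseline. The test suite and
the acceptance script run meta-analysis recovery at 2000 genes × 9 KOs,
the global null at 1000 genes × 5 KOs, Gibbs agreement on a 100-gene
model, chain recovery at n = 500, and rescue classification at 30 larvae
per group — sizes chosen to put Monte-Carlo error well inside each
acceptance band while completing in seconds to minutes.

# Known limitations

* The consensus network builder is correlation-based; latent-factor
  builders may resolve different edge sets (the score is agnostic).
* Wald normal mixed-model p-values are mildly anticonservative at few
  batches; Satterthwaite or LRT alternatives would need an extra
  dependency.
* The sign-test reading of the delta-matrix restriction treats
  sub-threshold entries as excluded (standard sign-test convention for
  zeros); an alternative reading that zeroes them before testing would be
  more conservative.
* Exhaustive KO-subset enumeration grows as $2^n$; the seeded
  down-sampler is the intended path beyond ~20 KOs.
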