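---
title: "Models and methods behind platetx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind platetx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`platetx` analyses plate-based high-throughput transcriptomic (HTTr)
screens: experiments in which every well of a 96- or 384-well plate is an
independently barcoded RNA-seq sample, typically one perturbation at one
concentration per well, with a pool of vehicle (DMSO) wells as the shared
baseline. Such screens sit awkwardly between bulk RNA-seq (deep, few
samples) and single-cell RNA-seq (shallow, zero-inflated, thousands of
cells): the designs are large and structured, input material per well is
small, and count matrices are sparser than bulk tools assume while sample
numbers are far below what single-cell models need. This vignette explains
the models the package implements, the defaults it chooses and why, what
the simulator does and does not emulate, and the numerical decisions a
maintainer would want recorded.

```{r setup, eval = FALSE}
library(platetx)
sim <- simulate_screen(sim_config(seed = 1))
scr <- filter_genes(sim$screen)
```

# Data model

A `Screen` couples a gene-by-well count matrix with one metadata record per
well barcode (treatment, concentration, unit, sample type, replicate,
plate, well coordinate) and an append-only provenance log. Counts are read
from the MatrixMarket triplet layout written by Cell Ranger or STARsolo;
metadata from a delimited sheet whose headers are mapped case-insensitively
through an extensible synonym table. Validation is strict by design:
screens involve large, often hand-edited treatment tables, so missing
values, characters outside `[A-Za-z0-9._-]` in identifier columns
(treatment strings end up in file names), invalid well coordinates,
negative concentrations and duplicate (plate, well) pairs are all hard
errors, while single-replicate groups and unbalanced designs are warnings.
Well coordinates accept both `"A1"` and `"A01"` and canonicalise to the
unpadded form.

# Quality control

**RLE.** For a normalised matrix `N`, the relative log expression is
`rle[g, j] = log2(N[g, j] + c) - median_j' log2(N[g, j'] + c)` with
pseudocount `c = 1` throughout the package. Flat, zero-centred per-well RLE
distributions indicate that normalisation removed technical well-to-well
variation.

**Average coefficient of variation.** The scalar score attached to an RLE
assessment is the mean over genes of `sd/mean` of normalised counts across
the selected wells (vehicle wells by default), restricted to genes with
mean at least 1 (on the normalised scale). It quantifies exactly the spread
an RLE plot displays, is zero for identical wells, and is invariant to a
global rescaling. An alternative convention — the mean per-well CV of RLE
values — is available behind the `per_well` flag; the per-gene form is the
default because it is directly comparable across normalisation methods and
does not depend on a per-well centring.

**Gene filtering.** A gene is kept when its aggregated count reaches `t`
(default 5) in at least `k` (default 2) sample groups, a group being a
treatment-by-concentration cell of the design. Aggregation defaults to the
group *sum*: at typical plate-screen depths a handful of reads spread over
the wells of a group is real signal, and the sum reading is the natural one
for "reads in a sample group". The stricter per-well-minimum rule is
available (`aggregation = "per_well_min"`). Filtering is monotone in `t`,
independent of row and column order, and logged in provenance.

**Outliers.** A well is flagged when |median RLE| exceeds 1 (log2), when
its RLE IQR exceeds twice the cohort median IQR, or when it detects fewer
than 200 genes. All three thresholds are explicit configuration; they are
deliberately conservative defaults for 384-well screens and should be
reviewed per protocol.

**Variance decomposition.** Per gene, a sequential (type-I)
sum-of-squares decomposition of a linear model on declared metadata
factors, in declared order, with the order recorded in the output. Type-I
was chosen because plate designs here are balanced or nearly so — where
factors are orthogonal the decomposition is unique — and because it is
exactly reproducible and cheap for thousands of genes (one incremental QR
per factor block for all genes at once). Aliased factors are reported as
`NA` with a warning rather than silently absorbed.

# Normalisation

Four scaling families are provided behind one `NormFactors` contract
(per-well size factor and effective library size):

* **CPM** — library-size scaling; the baseline every comparison includes.
* **Median-of-ratios** — DESeq-style factors (via
  `DESeq2::estimateSizeFactorsForMatrix`): per well, the median ratio of
  counts to the gene's geometric mean across wells, over genes positive in
  every well. Factors are returned unscaled. Because any zero removes a
  gene from the reference, the error message for reference-free matrices
  advises filtering first.
* **TMM / TMMwsp** — trimmed mean of M-values (via
  `edgeR::calcNormFactors`), with M-trim 0.3 and A-trim 0.05 and the
  reference well chosen as the one whose upper-quartile proportion is
  closest to the mean — deterministic and overridable. TMMwsp rescues
  singleton-positive genes by pairing them largest-to-largest across the
  well pair, which keeps factors stable under heavy zero inflation; it is
  therefore the default feeding the log-scale engines. The test suite pins
  the TMM factors to an independent re-derivation of the published
  trimming rule. TMM-family factors are rescaled to geometric mean one.
* **Control-gene factor removal** — an RUV-style correction: the first `k`
  singular directions of the row-centred log matrix restricted to declared
  control genes define unwanted-variation scores; every gene is regressed
  on the scores and recentred. The scores are exported so they can instead
  enter a DE design as covariates, which is the statistically cleaner use.

# Zero inflation and observation weights

Wells with little input material show more zeros than a negative binomial
(NB) predicts. The package first quantifies this: for each gene the
expected zero fraction under the fitted NB is
`mean_j (theta / (theta + mu_j))^theta`, and the excess of the observed
zero fraction over it — averaged over genes — is the screen-level
zero-inflation score (near zero for NB data, strongly positive under
dropout).

Weights come from a per-gene zero-inflated NB mixture fitted by EM. The
E-step gives every zero observation a dropout responsibility
`z = pi / (pi + (1 - pi) * NB0)`; the M-step re-estimates `pi` (mean of
`z`), the group means (Newton on the log scale with size-factor offsets)
and `theta` (damped Newton on log-theta, floored at `1e-3` and capped at
`1e6`). The published latent-factor formulation of this model carries a
sample-level factor dimension and a ridge penalty; those have no effect on
the *weight formula* that downstream engines consume, so the package fits
the intercept-only per-gene mixture and documents that simplification
prominently — the latent-factor machinery is intentionally not
implemented. Iterations that would decrease a gene's observed-data
log-likelihood are reverted and the gene frozen, making the reported
likelihood path non-decreasing by construction; convergence is declared at
`|delta loglik| < 1e-4` or 100 iterations. Weights are exactly 1 for every
positive count and `1 - z` for zeros, and enter both dispersion estimation
and model fitting in the weighted engines — passing them to the fit alone
would leave dispersions biased by the same dropouts the weights discount.

# Differential expression

All five engines answer the same question — one treatment group against
the vehicle pool — and fill one result contract (`gene_id`, `gene_name`,
`base_mean`, `log2fc`, `stat`, `pvalue`, BH `padj`, engine tag, group
sizes), so screens can switch engines without touching downstream code:

* `nbql` — NB GLM with log link, effective-library-size offsets (TMM),
  dispersion shrunk toward a trend with prior df 10, quasi-likelihood
  F-test (edgeR).
* `voom` — `log2((count + 0.5) / (eff. libsize + 1) * 1e6)` with TMMwsp
  factors, precision weights from the lowess mean-variance trend (span
  0.5), weighted least squares, moderated t (limma).
* `trend` — the same log-CPM, unweighted least squares, moderated t with
  an intensity-trend prior (limma-trend), as DRUG-seq-style pipelines use.
* `wald_nb` — median-of-ratios offsets, trended dispersion shrinkage and a
  Wald z-test (DESeq2), with independent filtering and Cook's censoring
  disabled so every gene in the filtered screen is reported; `padj` is
  recomputed with the package's BH for contract uniformity.
* `ranksum` — Wilcoxon rank-sum on CPM, exact when both groups have at
  most 8 wells and the gene is tie-free, otherwise the tie- and
  continuity-corrected normal approximation. Constant genes report p = 1.
  Its fold change is the descriptive
  `log2((mean CPM + 1) / (mean CPM + 1))` ratio, with a 1-CPM pseudocount;
  model engines report model coefficients.

ZINB weights are accepted by `nbql` and `voom` (multiplying the engines'
own observation weights); all-ones weights reproduce the unweighted runs
exactly. No engine uses randomness, so multi-treatment screens are
bit-reproducible under any worker count — that determinism is asserted in
the tests, and is why permutation-based inference lives in the enrichment
module (with explicit seeds) rather than inside engines. Significance cuts
are never baked into results; summaries take `padj < 0.05` and
`|log2fc| > 1` as defaults.

Two caveats surfaced by the package's own test suite are worth knowing.
First, TMMwsp's singleton pairing breaks count ties in input order, so
results under TMMwsp are stable under gene permutation only to ~1e-3 in
p-values (CPM and TMM are exactly order-invariant). Second, on
zero-inflated null screens the log-scale engines can produce occasional
adjusted-significant false calls: a single dropout zero in a small
treatment group yields a large |log2fc| while empirical-Bayes shrinkage
pulls the gene's honestly large variance toward the cohort trend,
overstating confidence. The nominal error rate stays calibrated; the tail
does not. This is precisely the failure mode the ZINB weights address, and
the weighted-engine acceptance test demonstrates the repair; for
unweighted runs on sparse screens, treat isolated huge-|log2fc| calls at
marginal padj with suspicion.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability with BH
across sets. Preranked enrichment implements the weighted running-sum
statistic (hit weight `|r|^p`, default `p = 1`; `p = 0` gives the
unweighted KS form) with the null generated by *gene-label* permutation —
the appropriate null for preranked input, stated explicitly because
phenotype permutation answers a different question. NES divides the
observed ES by the mean |null ES| of matching sign; sets whose null
produces fewer than 10 same-sign draws are flagged rather than guessed,
and permutation p-values are floored at `1/(n_perm + 1)`. Signature
scoring ranks the query by its DE statistic and tests the top-`n`
(default 500) genes of a reference perturbation profile as a set.

# Dose-response

Responses (per-gene log2 fold change, or a per-set summary, each
concentration against vehicle) are fitted with the four-parameter logistic
`y(x) = lower + (upper - lower) / (1 + (ec50/x)^h)` on the log10-dose
axis. The vehicle is the zero-dose anchor of the *response definition* and
never enters the fit, avoiding log(0) workarounds. Fitting is
Levenberg-Marquardt from a grid of starts (Hill in {±0.5, ±1, ±2}, EC50 at
dose quantiles, asymptotes from the terminal responses); because some
starts sit at singular points of the Jacobian, refinement walks the start
list until three fits succeed, and the final RSS never exceeds the best
grid start's. The model is invariant under
`(lower, upper, h) -> (upper, lower, -h)`, so fits are reported in the
canonical orientation `upper >= lower`; `y(ec50)` equals the asymptote
midpoint by construction. Flat series (range below `1e-8`) and
out-of-range EC50s (outside `[min dose / 100, max dose * 100]` bounds,
with an in-range flag for the observed dose span) are flagged, never
silently extrapolated. Benchmark-dose machinery is out of scope.

Pathway-level profiles offer two response scales, and the distinction
matters. The permutation NES answers "at which dose does a coherent set
response become detectable?" — being rank-based it saturates as soon as
the shift clears noise, so its half-max sits systematically below the
member genes' half-maximal dose (the package's own simulations show
NES-derived EC50s an order of magnitude left of the planted gene-level
median when potencies are coherent). The mean log2 fold change of the set
genes (`response = "mean_lfc"`) is proportional to the average gene
response and is the scale to report as a pathway EC50; the NES remains
the right tool for detection-threshold questions and stays the default
response for enrichment-style profiles.

# Benchmark harness

Four resampling procedures probe how analysis choices shape results, each
a pure function of (screen, config, seed): threshold sweeps of the gene
filter scored by sparsity, detected genes and average CV per
normalisation; false-positive estimation by splitting the vehicle pool
into two seeded pools of 8 and repeatedly drawing 3-well pseudo-groups
(the one-pool variant is a configuration option); leave-one-out replicate
subsampling against the full-replicate reference; and control-count sweeps
with seeded control draws. Summary tables report means with standard
errors over repeats (`sd/sqrt(R)`).

# The simulator, and what passing tests mean

`simulate_screen` draws counts from a zero-inflated NB:
`count[g, j] ~ ZINB(s_j * mu_g * 2^lfc(g, j) * batch[g, j], theta_g,
pi_g)`. Defaults describe one 384-well plate at the scale the package
targets: 32 treatments in triplicate, 19 vehicle wells, one dose compound
at 8 half-log concentrations in triplicate; baseline log2-means
`N(3, 2)`; the dispersion trend `1/theta = 0.1 + 1/mu` (BCV ~0.32 for
abundant genes); mild abundance-dependent dropout
`logit(pi) = -2.2 - 0.8 log(mu + 1)` (about 6% extra zeros for mu near 1,
negligible above mu ~100); log-normal well depths (sd 0.3); 10% of genes
differentially expressed per treatment at |log2fc| = 2 with random sign,
planted on genes with baseline mean at least 2 so the effect is
estimable; dose-compound responses follow a 4PL on the log2-fold-change
scale with EC50s log-uniform inside the dose range. A row-gradient batch
preset exists for the variance-decomposition and factor-removal tests and
is off by default. These values were chosen once as a realistic MAC-Seq-
scale regime; the acceptance suite runs against them unchanged.

The simulator emulates marginal count behaviour, depth variation, planted
effects and simple plate gradients. It does *not* emulate gene-gene
correlation beyond shared batch factors, UMI collisions, ambient
contamination, cytotoxicity-driven global shifts, or compositional
distortion from very strong responses. Tests passing on this generator
therefore certify the statistical machinery against data that satisfies
each engine's own assumptions plus dropout; they do not certify behaviour
under correlated pathway co-regulation or severe composition change, which
is why the TMM composition test plants its bias explicitly.

# Problem sizes and reproducibility

The test and acceptance workloads use desk-scale versions of the study
design — 2000-gene screens at 3-vs-19 for calibration and recovery (20
seeds), 50-seed dropout and EC50-recovery simulations, and the full
5000-gene default plate for the end-to-end CLI determinism check — sizes
chosen so the whole suite exercises every module at meaningful power on a
single CPU. All randomness flows through explicit seeds (`with_seed`
restores the caller's RNG state), engines are RNG-free, and the CLI
writes a manifest (version, configuration echo and hash, output
checksums) so identical configuration and seed give identical artifacts.

# Known limitations

Single-plate designs are first-class; multi-plate support is barcode-level
concatenation with a per-plate control default, not a batch-correction
scheme. The ZINB weights use the intercept-only per-gene mixture described
above. LFC shrinkage estimators, multi-model dose-response selection,
benchmark-dose estimation, embedding algorithms (UMAP/MDS — the package
exports distance matrices only) and all plot rendering are deliberately
out of scope; the tables the plots would show are the product.
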