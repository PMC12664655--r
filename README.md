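# platetx

Analysis toolkit for plate-based high-throughput transcriptomics (HTTr)
screens — experiments where each well of a 96- or 384-well plate is a
barcoded RNA-seq sample (one perturbation × concentration per well, DMSO
vehicle wells as the shared baseline). These screens combine large,
structured designs with shallow, zero-inflated counts, so they fall
between the assumptions of bulk and single-cell RNA-seq tooling.

`platetx` is for screening groups and analysts who need the whole path
from raw plate outputs to ranked biology in one place:

* **Ingestion & validation** — Cell Ranger / STARsolo sparse triplets
  (`matrix.mtx` + `features.tsv` + `barcodes.tsv`), metadata sheets with a
  synonym-mapped schema, strict validation (missing values, stray
  characters in identifiers, well-coordinate and concentration checks),
  barcode-accurate joining into a `Screen`.
* **QC & normalisation** — per-well metrics, relative log expression (RLE)
  with a scalar average coefficient-of-variation score, group-wise gene
  filtering (default: ≥ 5 reads in ≥ 2 sample groups), variance
  decomposition, outlier flagging; CPM, median-of-ratios, TMM and TMMwsp
  factors, and RUV-style control-gene factor removal.
* **Zero inflation** — per-gene excess-zero assessment and observation
  weights from a zero-inflated negative binomial EM
  (`w = 1` for positive counts, the posterior NB probability for zeros).
* **Differential expression** — five engines behind one result contract:
  NB quasi-likelihood F-test (`nbql`), precision-weighted moderated t
  (`voom`), intensity-trend moderated t (`trend`), NB Wald (`wald_nb`),
  Wilcoxon rank-sum (`ranksum`); ZINB weights plug into `nbql`/`voom`.
* **Screen mode** — every treatment vs shared vehicle controls, in
  parallel with bit-identical results at any worker count; summaries,
  UpSet-style exclusive overlaps, treatment distance matrices.
* **Enrichment & dose-response** — hypergeometric over-representation,
  preranked running-sum enrichment with a seeded gene-permutation NES,
  signature scoring against a reference profile (top-500 by default), and
  4PL dose-response fits with EC50 extraction at gene and pathway level.
* **Benchmark harness** — filter sweeps, DMSO-split false-positive
  estimation, replicate subsampling, control-count sweeps, engine
  overlaps; every procedure seeded and reproducible.
* **Simulator** — ZINB plate screens with known ground truth (planted DE
  signatures, dose compounds, depth gradients, batch presets); the fixture
  source for the whole test suite.

The statistical core of a treatment-vs-vehicle call, for the default
engine, is the NB GLM
`y_gj ~ NB(mu_gj, theta_g)`, `log mu_gj = x_j' beta_g + log(N_j f_j)`
with TMM factors `f_j`, trended empirical-Bayes dispersion shrinkage and a
quasi-likelihood F-test on the treatment coefficient; multiplicity is
controlled with Benjamini–Hochberg. Zero inflation is handled by weighting
observations with `w = (1-pi)NB0 / (pi + (1-pi)NB0)`,
`NB0 = (theta/(theta+mu))^theta`, estimated per gene by EM.

## Worked example

```r
library(platetx)

sim <- simulate_screen(sim_config(seed = 1))   # default 384-well screen
scr <- filter_genes(sim$screen)                # >=5 reads in >=2 groups
scr
#> Screen: 4940 genes x 139 wells, 41 treatment group(s)
#> provenance:
#>  - simulate_screen: seed=1
#>  - assemble_screen: 5000 genes x 139 wells
#>  - filter_genes: t=5 k=2 agg=group_sum grouping=treatmentxconcentration; removed 60 of 5000 genes

qc <- compute_qc_summary(scr)
sum(qc$outlier)
#> [1] 0

md  <- screen_metadata(scr)
res <- de_run("nbql", scr,
              de_design(md$barcode[md$treatment == "T01"],
                        control_wells(scr)))
head(res[order(res$padj), c("gene_id", "base_mean", "log2fc",
                            "stat", "pvalue", "padj")], 5)
#>      gene_id base_mean log2fc  stat   pvalue     padj
#> 346   G00350      1624   2.57 102.2 2.88e-18 1.42e-14
#> 1156  G01176       581   2.85  90.3 9.78e-17 2.42e-13
#> 2417  G02452       828   2.56  83.9 7.09e-16 1.17e-12
#> 3318  G03364      4243   2.27  81.7 1.42e-15 1.75e-12
#> 2131  G02164      3490   2.36  79.8 2.56e-15 2.53e-12
```

`G00350` tops the list with a fitted log2 fold change of 2.57 (~6-fold up)
against the simulator's planted |log2fc| = 2 signature for treatment T01;
at `padj < 0.05` and `|log2fc| > 1` this run calls 343 genes, 334 of them
among T01's 500 planted DE genes (the misses are the low-abundance tail,
where 3-vs-19 has little power). The same `DEResult` table feeds
`ora_hypergeom()` / `gsea_collection()` for pathway context,
`signature_score()` for matching against a reference perturbation, and
`gene_response_profile()` + `fit_4pl()` for EC50s of dose-series
compounds.

A command-line wrapper covering the same workflow
(`simulate`, `validate`, `qc`, `filter`, `normalize`, `de`, `screen`,
`dose`, `bench`) is installed at
`system.file("cli", "platetx", package = "platetx")`; every run writes a
manifest with the configuration hash, seed and output checksums.

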