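#' @title Differential expression engines
#' @name de
#' @description One treatment-vs-vehicle comparison under five statistical
#'   engines sharing a single result contract: NB GLM with quasi-likelihood
#'   F-tests (`nbql`, edgeR-backed), precision-weighted moderated t
#'   (`voom`), intensity-trend moderated t (`trend`), NB Wald test
#'   (`wald_nb`, DESeq2-backed) and the Wilcoxon rank-sum test (`ranksum`).
#'   The `nbql` and `voom` engines accept ZINB observation weights.
NULL

DE_ENGINES <- c("nbql", "voom", "trend", "wald_nb", "ranksum")

#' Describe a differential-expression design
#'
#' @param treatment_wells Barcodes of treatment wells.
#' @param control_wells Barcodes of vehicle-control wells.
#' @param covariates Optional matrix/data.frame of per-well covariates
#'   (rows named by barcode), e.g. unwanted-variation factor scores.
#' @param normalisation Normalisation method name, or `NULL` for the
#'   engine's default (TMM for `nbql`, TMMwsp for `voom`/`trend`,
#'   median-of-ratios for `wald_nb`, CPM for `ranksum`).
#' @param weights Optional observation weight matrix (genes x wells of the
#'   screen), e.g. from [estimate_zinb_weights()].
#' @param prior_df Prior degrees of freedom for dispersion moderation in the
#'   NB engines.
#' @return A `de_design`.
#' @export
de_design <- function(treatment_wells, control_wells, covariates = NULL,
                      normalisation = NULL, weights = NULL, prior_df = 10) {
  if (length(intersect(treatment_wells, control_wells)))
    stop("treatment and control wells must be disjoint")
  if (length(treatment_wells) < 1 || length(control_wells) < 1)
    stop("each side of the design needs at least 1 well")
  if (length(treatment_wells) < 2 || length(control_wells) < 2)
    warning("a side has a single well; engines requiring residual df will fail")
  structure(list(treatment_wells = treatment_wells,
                 control_wells = control_wells, covariates = covariates,
                 normalisation = normalisation, weights = weights,
                 prior_df = prior_df),
            class = "de_design")
}

# Subset the screen to the design wells (controls first) and build the
# model matrix with the treatment indicator last.
design_context <- function(screen, design) {
  counts <- screen_counts(screen)
  wells <- c(design$control_wells, design$treatment_wells)
  idx <- match(wells, colnames(counts))
  if (anyNA(idx)) stop("design wells not all present in the screen")
  y <- counts[, idx, drop = FALSE]
  group <- factor(rep(c("ctrl", "treat"),
                      c(length(design$control_wells),
                        length(design$treatment_wells))),
                  levels = c("ctrl", "treat"))
  df <- data.frame(group = group)
  if (!is.null(design$covariates)) {
    cv <- as.data.frame(design$covariates)
    ci <- match(wells, rownames(cv))
    if (anyNA(ci)) stop("covariate rows must be named by well barcode")
    df <- cbind(cv[ci, , drop = FALSE], df)
  }
  X <- model.matrix(~ ., data = df)
  W <- design$weights
  if (!is.null(W)) {
    if (!all(dim(W) == dim(counts)) &&
        !all(dim(W) == c(nrow(y), ncol(y))))
      stop("weights dimensions do not match the screen")
    if (all(dim(W) == dim(counts))) W <- W[, idx, drop = FALSE]
  }
  list(y = y, X = X, group = group, df = df, weights = W,
       coef = "grouptreat",
       n_treat = length(design$treatment_wells),
       n_ctrl = length(design$control_wells))
}

new_de_result <- function(screen, ctx, log2fc, stat, pvalue, engine,
                          base_mean) {
  gid <- screen$counts$gene_ids
  data.frame(gene_id = gid,
             gene_name = screen$counts$gene_names,
             base_mean = unname(base_mean),
             log2fc = unname(log2fc), stat = unname(stat),
             pvalue = unname(pvalue), padj = adjust_bh(unname(pvalue)),
             engine = engine, n_treat = ctx$n_treat, n_ctrl = ctx$n_ctrl,
             row.names = NULL)
}

engine_factors <- function(y, normalisation, default) {
  method <- normalisation %||% default
  switch(method,
         cpm = norm_cpm(y)$factors,
         tmm = norm_tmm(y),
         tmmwsp = norm_tmm(y, singleton_pairing = TRUE),
         median_of_ratios = norm_median_of_ratios(y),
         stop(sprintf("unknown normalisation '%s'", method)))
}

#' NB GLM with quasi-likelihood F-test
#'
#' Per gene, a negative binomial GLM with log link and effective-library-
#' size offsets (TMM factors by default); gene-wise dispersions are shrunk
#' toward a mean-dispersion trend with `prior_df` prior degrees of freedom
#' and the treatment coefficient is tested with a quasi-likelihood F-test
#' with moderated denominator degrees of freedom. Optional observation
#' weights enter both dispersion estimation and the GLM fit.
#'
#' @param screen A filtered `Screen`.
#' @param design A [de_design()].
#' @return A `DEResult` data.frame: `gene_id`, `gene_name`, `base_mean`
#'   (mean CPM), `log2fc`, `stat` (F), `pvalue`, `padj` (BH), `engine`,
#'   `n_treat`, `n_ctrl`.
#' @export
de_nbql <- function(screen, design) {
  ctx <- design_context(screen, design)
  if (ncol(ctx$y) - qr(ctx$X)$rank < 1) stop("no residual degrees of freedom")
  f <- engine_factors(ctx$y, design$normalisation, "tmm")
  dge <- edgeR::DGEList(counts = ctx$y, norm.factors = f$size_factor)
  if (!is.null(ctx$weights)) dge$weights <- ctx$weights
  dge <- edgeR::estimateDisp(dge, ctx$X, prior.df = design$prior_df)
  fit <- edgeR::glmQLFit(dge, ctx$X)
  res <- edgeR::glmQLFTest(fit, coef = ctx$coef)
  tab <- res$table
  base_mean <- rowMeans(edgeR::cpm(dge))
  new_de_result(screen, ctx, tab$logFC, tab$F, tab$PValue, "nbql", base_mean)
}

voom_logcpm <- function(y, eff_lib) {
  t(log2(t(y + 0.5) / (eff_lib + 1) * 1e6))
}

#' Precision-weighted moderated t (voom)
#'
#' Log2-CPM values `log2((count + 0.5) / (effective libsize + 1) * 1e6)`
#' (TMMwsp effective library sizes by default, suiting zero-inflated data)
#' are fitted per gene by weighted least squares with precision weights from
#' the fitted mean-variance (lowess) trend; the treatment coefficient is
#' tested with an empirical-Bayes moderated t. External ZINB weights
#' multiply the precision weights.
#'
#' @inheritParams de_nbql
#' @return A `DEResult` data.frame (`stat` is the moderated t).
#' @export
de_voom <- function(screen, design) {
  ctx <- design_context(screen, design)
  if (ncol(ctx$y) - qr(ctx$X)$rank < 1) stop("no residual degrees of freedom")
  f <- engine_factors(ctx$y, design$normalisation, "tmmwsp")
  v <- limma::voom(ctx$y, ctx$X, lib.size = f$effective_libsize, span = 0.5)
  if (!is.null(ctx$weights)) v$weights <- v$weights * ctx$weights
  fit <- limma::eBayes(limma::lmFit(v, ctx$X))
  tt <- limma::topTable(fit, coef = ctx$coef, number = Inf, sort.by = "none")
  base_mean <- rowMeans(normalized_matrix(ctx$y, f))
  new_de_result(screen, ctx, tt$logFC, tt$t, tt$P.Value, "voom", base_mean)
}

#' Intensity-trend moderated t (limma-trend)
#'
#' Unweighted least squares on the same log2-CPM values as [de_voom()],
#' with the empirical-Bayes prior variance a trend over mean abundance
#' (`eBayes(trend = TRUE)`), matching DRUG-seq-style analysis.
#'
#' @inheritParams de_nbql
#' @return A `DEResult` data.frame (`stat` is the moderated t).
#' @export
de_trend <- function(screen, design) {
  ctx <- design_context(screen, design)
  if (ncol(ctx$y) - qr(ctx$X)$rank < 1) stop("no residual degrees of freedom")
  f <- engine_factors(ctx$y, design$normalisation, "tmmwsp")
  E <- voom_logcpm(ctx$y, f$effective_libsize)
  fit <- limma::eBayes(limma::lmFit(E, ctx$X), trend = TRUE)
  tt <- limma::topTable(fit, coef = ctx$coef, number = Inf, sort.by = "none")
  base_mean <- rowMeans(normalized_matrix(ctx$y, f))
  new_de_result(screen, ctx, tt$logFC, tt$t, tt$P.Value, "trend", base_mean)
}

#' NB Wald test (DESeq2)
#'
#' Median-of-ratios size factors, trended dispersion shrinkage with
#' empirical-Bayes weighting and a Wald z-test on the treatment
#' coefficient, via DESeq2 with independent filtering and Cook's-distance
#' censoring disabled so every gene is reported; `padj` is recomputed with
#' [adjust_bh()] for contract consistency.
#'
#' @inheritParams de_nbql
#' @return A `DEResult` data.frame (`stat` is the Wald z).
#' @export
de_wald_nb <- function(screen, design) {
  ctx <- design_context(screen, design)
  if (ncol(ctx$y) - qr(ctx$X)$rank < 1) stop("no residual degrees of freedom")
  cd <- ctx$df
  fml <- stats::as.formula(paste("~", paste(colnames(cd), collapse = " + ")))
  mode(ctx$y) <- "integer"
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = ctx$y, colData = cd, design = fml))
  dds <- tryCatch(
    suppressMessages(DESeq2::DESeq(dds, quiet = TRUE, fitType = "parametric")),
    error = function(e)
      suppressMessages(DESeq2::DESeq(dds, quiet = TRUE, fitType = "mean")))
  res <- DESeq2::results(dds, contrast = c("group", "treat", "ctrl"),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  new_de_result(screen, ctx, res$log2FoldChange, res$stat, res$pvalue,
                "wald_nb", res$baseMean)
}

#' Wilcoxon rank-sum test per gene
#'
#' Two-sided rank-sum test on normalised values (CPM by default). The exact
#' null distribution is used when both groups have at most 8 wells and the
#' gene has no ties; otherwise the normal approximation with tie and
#' continuity corrections. `log2fc` is
#' `log2((mean CPM_treat + 1) / (mean CPM_ctrl + 1))`.
#'
#' @inheritParams de_nbql
#' @return A `DEResult` data.frame (`stat` is the rank-sum W).
#' @export
de_ranksum <- function(screen, design) {
  ctx <- design_context(screen, design)
  f <- engine_factors(ctx$y, design$normalisation, "cpm")
  norm <- normalized_matrix(ctx$y, f)
  tr <- ctx$group == "treat"
  can_exact <- sum(tr) <= 8 && sum(!tr) <= 8
  res <- t(apply(norm, 1, function(v) {
    x <- v[tr]; y <- v[!tr]
    if (all(v == v[1]))                  # constant gene: no evidence
      return(c(sum(tr) * sum(!tr) / 2, 1))
    exact <- can_exact && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
    c(wt$statistic, wt$p.value)
  }))
  log2fc <- log2((rowMeans(norm[, tr, drop = FALSE]) + 1) /
                 (rowMeans(norm[, !tr, drop = FALSE]) + 1))
  new_de_result(screen, ctx, log2fc, res[, 1], res[, 2], "ranksum",
                rowMeans(norm))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: p-values sorted ascending, `q_i = min_{j >= i}
#' p_j * m / j` clipped at 1, returned in input order. `NA`s are propagated
#' and excluded from `m`.
#'
#' @param pvalues Numeric vector in [0, 1], `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Run a DE engine with observation weights
#'
#' Dispatches to the weighted form of an engine; observation weights enter
#' the engine's likelihood (nbql) or least-squares (voom) as multipliers.
#' All-ones weights reproduce the unweighted engine exactly.
#'
#' @param engine `"nbql"` or `"voom"`.
#' @param screen A filtered `Screen`.
#' @param design A [de_design()].
#' @param weights Weight matrix (genes x screen wells or genes x design
#'   wells), e.g. `estimate_zinb_weights(...)$weights`.
#' @return A `DEResult` data.frame.
#' @export
de_with_weights <- function(engine, screen, design, weights) {
  engine <- match.arg(engine, c("nbql", "voom"))
  design$weights <- weights
  de_run(engine, screen, design)
}

#' Run a DE engine by name
#'
#' @param engine One of `"nbql"`, `"voom"`, `"trend"`, `"wald_nb"`,
#'   `"ranksum"`.
#' @param screen A filtered `Screen`.
#' @param design A [de_design()].
#' @return A `DEResult` data.frame.
#' @export
de_run <- function(engine, screen, design) {
  engine <- match.arg(engine, DE_ENGINES)
  switch(engine,
         nbql = de_nbql(screen, design),
         voom = de_voom(screen, design),
         trend = de_trend(screen, design),
         wald_nb = de_wald_nb(screen, design),
         ranksum = de_ranksum(screen, design))
}

#' Write a DE result as TSV
#'
#' Stable column order: gene_id, gene_name, base_mean, log2fc, stat,
#' pvalue, padj, engine, n_treat, n_ctrl.
#'
#' @param result A `DEResult` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(result, path) {
  cols <- c("gene_id", "gene_name", "base_mean", "log2fc", "stat",
            "pvalue", "padj", "engine", "n_treat", "n_ctrl")
  write.table(result[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
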