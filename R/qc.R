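#' @title Quality control for plate screens
#' @name qc
#' @description Per-well QC metrics, relative log expression (RLE)
#'   distributions with a scalar average coefficient-of-variation score,
#'   group-wise gene filtering, variance decomposition and outlier flagging.
NULL

#' Default outlier rule
#'
#' A well is flagged when |median RLE| exceeds `max_abs_median`, when its RLE
#' IQR exceeds `iqr_mult` times the cohort median IQR, or when it detects
#' fewer than `min_detected` genes.
#'
#' @param max_abs_median Threshold on |median RLE| (log2 units).
#' @param iqr_mult Multiplier of the cohort median RLE IQR.
#' @param min_detected Minimum detected genes per well.
#' @return List of thresholds.
#' @export
outlier_rule <- function(max_abs_median = 1.0, iqr_mult = 2.0,
                         min_detected = 200L) {
  list(max_abs_median = max_abs_median, iqr_mult = iqr_mult,
       min_detected = as.integer(min_detected))
}

#' Relative log expression (RLE) of a normalised matrix
#'
#' `rle[g, j] = log2(norm[g, j] + pseudocount) - median_ref log2(norm[g, .] +
#' pseudocount)`, the per-gene log-ratio to the gene's median over the
#' reference wells (default: all wells). Flat, zero-centred RLE
#' distributions indicate effective normalisation.
#'
#' @param norm Normalised matrix (genes x wells), finite.
#' @param pseudocount Positive pseudocount for the log transform.
#' @param reference_wells Optional well subset (names or indices) defining
#'   the per-gene reference median.
#' @return An `rle_result`: `rle_values` matrix, `per_well_summary`
#'   (`barcode`, `median_rle`, `rle_iqr`), `avg_cv` over all wells,
#'   `pseudocount`.
#' @export
compute_rle <- function(norm, pseudocount = 1, reference_wells = NULL) {
  norm <- as.matrix(norm)
  if (ncol(norm) < 2) stop("RLE needs at least 2 wells")
  if (!all(is.finite(norm))) stop("normalised matrix must be finite")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  lg <- log2(norm + pseudocount)
  ref <- if (is.null(reference_wells)) seq_len(ncol(norm))
         else if (is.character(reference_wells)) match(reference_wells, colnames(norm))
         else reference_wells
  if (anyNA(ref)) stop("reference_wells not found in matrix columns")
  ref_med <- apply(lg[, ref, drop = FALSE], 1, median)
  rle <- lg - ref_med
  per_well <- data.frame(
    barcode = colnames(norm) %||% as.character(seq_len(ncol(norm))),
    median_rle = apply(rle, 2, median),
    rle_iqr = apply(rle, 2, IQR),
    row.names = NULL)
  avg <- tryCatch(average_cv(norm), error = function(e) NA_real_)
  structure(list(rle_values = rle, per_well_summary = per_well,
                 avg_cv = avg, pseudocount = pseudocount),
            class = "rle_result")
}

#' Average coefficient of variation of normalised counts
#'
#' For each gene with mean normalised count >= `min_mean` across the selected
#' wells, `CV_g = sd_g / mean_g` (sample sd); returns the mean of `CV_g` over
#' those genes. Quantifies the residual spread that RLE plots display; lower
#' is better. An alternative convention — the mean per-well CV of RLE values
#' — is available via `per_well = TRUE`.
#'
#' @param norm Normalised matrix (genes x wells).
#' @param wells Optional well subset (names or indices).
#' @param min_mean Minimum mean normalised count for a gene to contribute.
#' @param per_well Use the per-well-CV-of-RLE convention instead.
#' @return Non-negative scalar.
#' @export
average_cv <- function(norm, wells = NULL, min_mean = 1, per_well = FALSE) {
  norm <- as.matrix(norm)
  if (!is.null(wells)) {
    idx <- if (is.character(wells)) match(wells, colnames(norm)) else wells
    if (anyNA(idx)) stop("wells not found in matrix columns")
    norm <- norm[, idx, drop = FALSE]
  }
  if (ncol(norm) < 2) stop("average_cv needs at least 2 wells")
  mu <- rowMeans(norm)
  keep <- mu >= min_mean & mu > 0
  if (!any(keep)) stop("no gene passes min_mean; lower min_mean or filter less")
  if (per_well) {
    rle <- log2(norm[keep, , drop = FALSE] + 1)
    rle <- rle - apply(rle, 1, median)
    cvs <- apply(rle, 2, function(x) sd(x) / max(abs(mean(x)), .Machine$double.eps))
    return(mean(abs(cvs)))
  }
  s <- apply(norm[keep, , drop = FALSE], 1, sd)
  mean(s / mu[keep])
}

#' Per-well QC summary
#'
#' One record per well: total counts, detected genes (count > 0), fraction
#' of zero genes, RLE median and IQR, and the outlier flag from
#' [flag_outliers()].
#'
#' @param screen A `Screen`.
#' @param norm Optional normalised matrix; defaults to CPM of the screen
#'   counts.
#' @param rule Outlier thresholds, see [outlier_rule()].
#' @return `data.frame` with one row per well.
#' @export
compute_qc_summary <- function(screen, norm = NULL, rule = outlier_rule()) {
  counts <- screen_counts(screen)
  # safe CPM: an all-zero well yields zeros (and is flagged downstream)
  # rather than failing the whole summary
  if (is.null(norm))
    norm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
  detected <- colSums(counts > 0)
  qc <- data.frame(
    barcode = colnames(counts),
    total_counts = colSums(counts),
    detected_genes = detected,
    fraction_zero = 1 - detected / nrow(counts),
    row.names = NULL)
  rle <- compute_rle(norm)
  qc$median_rle <- rle$per_well_summary$median_rle
  qc$rle_iqr <- rle$per_well_summary$rle_iqr
  qc$outlier <- flag_outliers(rle, qc, rule)
  qc
}

#' Flag outlier wells
#'
#' A well is an outlier if |median RLE| > `rule$max_abs_median`, or its RLE
#' IQR exceeds `rule$iqr_mult` x the cohort median IQR, or it detects fewer
#' than `rule$min_detected` genes.
#'
#' @param rle An `rle_result`.
#' @param qc QC summary `data.frame` with `detected_genes` (optional; the
#'   detected-genes floor is skipped when absent).
#' @param rule See [outlier_rule()].
#' @return Logical vector, one element per well.
#' @export
flag_outliers <- function(rle, qc = NULL, rule = outlier_rule()) {
  pw <- rle$per_well_summary
  cohort_iqr <- median(pw$rle_iqr)
  flag <- abs(pw$median_rle) > rule$max_abs_median |
    pw$rle_iqr > rule$iqr_mult * cohort_iqr
  if (!is.null(qc) && "detected_genes" %in% names(qc))
    flag <- flag | qc$detected_genes < rule$min_detected
  unname(flag)
}

#' Gene filter specification
#'
#' Keep a gene when its aggregated count reaches `min_count` in at least
#' `min_groups` sample groups. Groups are defined by metadata columns
#' (default treatment x concentration). Aggregation `"group_sum"` totals
#' counts within a group; `"per_well_min"` is the stricter per-well rule
#' (every well of the group must reach `min_count`).
#'
#' @param min_count Non-negative count threshold `t`.
#' @param min_groups Positive number of groups `k`.
#' @param grouping Metadata columns defining a sample group.
#' @param aggregation `"group_sum"` or `"per_well_min"`.
#' @return A `gene_filter_spec`.
#' @export
gene_filter_spec <- function(min_count = 5L, min_groups = 2L,
                             grouping = c("treatment", "concentration"),
                             aggregation = c("group_sum", "per_well_min")) {
  stopifnot(min_count >= 0, min_groups >= 1)
  structure(list(min_count = min_count, min_groups = as.integer(min_groups),
                 grouping = grouping,
                 aggregation = match.arg(aggregation)),
            class = "gene_filter_spec")
}

#' Filter genes by group-wise counts
#'
#' Applies a [gene_filter_spec()] to a `Screen`; the default (>= 5 reads in
#' >= 2 sample groups, group sums) matches standard HTTr practice. The
#' applied spec and the number of removed genes are appended to the screen's
#' provenance.
#'
#' @param screen A `Screen`.
#' @param spec A [gene_filter_spec()].
#' @return The filtered `Screen`.
#' @export
filter_genes <- function(screen, spec = gene_filter_spec()) {
  md <- screen$metadata
  miss <- setdiff(spec$grouping, names(md))
  if (length(miss))
    stop(sprintf("grouping column(s) not in metadata: %s",
                 paste(miss, collapse = ", ")))
  grp <- interaction(md[spec$grouping], drop = TRUE, lex.order = TRUE)
  if (spec$min_groups > nlevels(grp))
    stop(sprintf("min_groups (%d) exceeds number of groups (%d)",
                 spec$min_groups, nlevels(grp)))
  counts <- screen_counts(screen)
  agg <- vapply(levels(grp), function(g) {
    sub <- counts[, grp == g, drop = FALSE]
    if (spec$aggregation == "group_sum") rowSums(sub)
    else apply(sub, 1, min)
  }, numeric(nrow(counts)))
  keep <- rowSums(agg >= spec$min_count) >= spec$min_groups
  out <- screen
  out$counts <- count_matrix(counts[keep, , drop = FALSE],
                             gene_ids = screen$counts$gene_ids[keep],
                             gene_names = screen$counts$gene_names[keep],
                             barcodes = screen$counts$barcodes)
  out$provenance <- c(screen$provenance, sprintf(
    "filter_genes: t=%g k=%d agg=%s grouping=%s; removed %d of %d genes",
    spec$min_count, spec$min_groups, spec$aggregation,
    paste(spec$grouping, collapse = "x"), sum(!keep), length(keep)))
  out
}

#' Variance decomposition across metadata factors
#'
#' Per gene, a sequential (type-I) sum-of-squares decomposition of a linear
#' model of the (log-) normalised values on the declared factors, in the
#' declared order; fractions are averaged across genes and the residual is
#' one minus the factor fractions. Aliased (confounded) factors are reported
#' with `NA` fractions and a warning.
#'
#' @param log_norm Matrix of (log-) normalised values, genes x wells.
#' @param factors `data.frame` of metadata columns (one row per well), each
#'   treated as a factor with >= 2 levels.
#' @return A `variance_decomposition`: `average` data.frame (`factor`,
#'   `fraction`) including the residual, `per_gene` fraction matrix and the
#'   factor `order`.
#' @export
variance_decomposition <- function(log_norm, factors) {
  log_norm <- as.matrix(log_norm)
  factors <- as.data.frame(factors)
  factors[] <- lapply(factors, function(x) factor(x))
  few <- names(factors)[vapply(factors, nlevels, 1L) < 2]
  if (length(few))
    stop(sprintf("factor(s) with < 2 levels: %s", paste(few, collapse = ", ")))
  Y <- t(log_norm)                      # wells x genes
  terms <- names(factors)
  X_full <- model.matrix(~ ., data = factors)
  assign <- attr(X_full, "assign")
  aliased <- character(0)
  # sequential RSS: project on growing column blocks
  rss <- matrix(NA_real_, nrow = length(terms) + 1, ncol = ncol(Y))
  tss <- colSums(scale(Y, scale = FALSE)^2)
  rss[1, ] <- tss
  prev_rank <- 1L
  for (k in seq_along(terms)) {
    Xk <- X_full[, assign <= k, drop = FALSE]
    fit <- lm.fit(Xk, Y)
    if (fit$rank <= prev_rank && k > 0) aliased <- c(aliased, terms[k])
    prev_rank <- fit$rank
    rss[k + 1, ] <- colSums(as.matrix(fit$residuals)^2)
  }
  if (length(aliased))
    warning(sprintf("aliased factor(s): %s (fraction undefined)",
                    paste(aliased, collapse = ", ")))
  ss <- -diff(rss)                       # terms x genes
  denom <- pmax(tss, .Machine$double.eps)
  frac <- sweep(rbind(ss, rss[nrow(rss), ]), 2, denom, "/")
  rownames(frac) <- c(terms, "residual")
  frac[rownames(frac) %in% aliased, ] <- NA_real_
  avg <- rowMeans(frac, na.rm = FALSE)
  structure(list(
    average = data.frame(factor = rownames(frac), fraction = unname(avg)),
    per_gene = t(frac), order = terms), class = "variance_decomposition")
}
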