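#' @title Normalisation of plate count matrices
#' @name normalize
#' @description Per-well scaling factors and normalised matrices under the
#'   methods typically compared on HTTr data: library-size CPM,
#'   median-of-ratios, TMM and its singleton-pairing variant TMMwsp for
#'   zero-inflated data, and control-gene factor removal.
NULL

as_count_values <- function(counts) {
  if (inherits(counts, "Screen")) return(screen_counts(counts))
  if (inherits(counts, "count_matrix")) return(counts$values)
  as.matrix(counts)
}

norm_factors_table <- function(counts, method, size_factor, effective_libsize) {
  data.frame(barcode = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             method = method, size_factor = size_factor,
             effective_libsize = effective_libsize, row.names = NULL)
}

#' Counts per million
#'
#' `cpm[g, j] = counts[g, j] / libsize_j * 1e6`. Column sums of the output
#' all equal one million.
#'
#' @param counts Count matrix, `count_matrix` or `Screen`.
#' @return List with `matrix` (CPM) and `factors` (a `NormFactors` table:
#'   `barcode`, `method`, `size_factor`, `effective_libsize`).
#' @export
norm_cpm <- function(counts) {
  m <- as_count_values(counts)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    bad <- colnames(m)[libsize == 0] %||% which(libsize == 0)
    stop(sprintf("all-zero well(s): %s", paste(bad, collapse = ", ")))
  }
  cpm <- sweep(m, 2, libsize, "/") * 1e6
  list(matrix = cpm,
       factors = norm_factors_table(m, "cpm", libsize / 1e6, libsize))
}

#' Median-of-ratios size factors
#'
#' Classic DESeq-style size factors: per well, the median over all-positive
#' genes of the ratio of the count to the gene's geometric mean across
#' wells. Factors are returned unscaled (no geometric-mean-1 rescaling).
#' Genes containing any zero do not contribute to the reference, so
#' pre-filtering low-count genes is advisable.
#'
#' @param counts Count matrix, `count_matrix` or `Screen`.
#' @return A `NormFactors` table; `effective_libsize` equals the size factor
#'   scaled to the mean library size.
#' @export
norm_median_of_ratios <- function(counts) {
  m <- as_count_values(counts)
  if (!any(rowSums(m > 0) == ncol(m)))
    stop(paste0("no gene is positive in every well; filter low-count genes ",
                "(e.g. filter_genes) before median-of-ratios normalisation"))
  sf <- DESeq2::estimateSizeFactorsForMatrix(m)
  norm_factors_table(m, "median_of_ratios", unname(sf),
                     unname(sf) * mean(colSums(m)))
}

#' TMM parameters
#'
#' @param logratio_trim Two-sided trim fraction on M-values (log ratios).
#' @param abundance_trim Two-sided trim fraction on A-values (abundances).
#' @param reference_well Explicit reference well (name or index); default
#'   `NULL` selects the well whose upper-quartile proportion is closest to
#'   the mean upper quartile.
#' @param min_count Counts below this are treated as zero when forming
#'   gene pairs (0 disables).
#' @return A `tmm_params` list.
#' @export
tmm_params <- function(logratio_trim = 0.3, abundance_trim = 0.05,
                       reference_well = NULL, min_count = 0) {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abundance_trim >= 0, abundance_trim < 0.5)
  structure(list(logratio_trim = logratio_trim,
                 abundance_trim = abundance_trim,
                 reference_well = reference_well, min_count = min_count),
            class = "tmm_params")
}

#' TMM / TMMwsp scaling factors
#'
#' Trimmed mean of M-values: for each well against a reference well, M and A
#' values are computed over genes positive in both, doubly trimmed by M and
#' A quantiles, and the factor is two to the precision-weighted mean of the
#' trimmed M values; factors are rescaled to geometric mean 1. With
#' `singleton_pairing` (the TMMwsp variant for heavily zero-inflated data),
#' genes positive in only one member of the pair are ranked by count and
#' greedily paired largest-to-largest across the two wells to form surrogate
#' ratios. Precision weights are the inverse asymptotic variance of M,
#' `1/count_obs - 1/libsize_obs + 1/count_ref - 1/libsize_ref` per gene.
#'
#' @param counts Count matrix, `count_matrix` or `Screen`.
#' @param params A [tmm_params()].
#' @param singleton_pairing Use the TMMwsp singleton-pairing variant.
#' @return A `NormFactors` table; `effective_libsize = libsize x factor`.
#' @export
norm_tmm <- function(counts, params = tmm_params(), singleton_pairing = FALSE) {
  m <- as_count_values(counts)
  if (ncol(m) < 2) stop("TMM needs at least 2 wells")
  work <- m
  if (params$min_count > 0) work[work < params$min_count] <- 0
  libsize <- colSums(m)
  ref <- params$reference_well
  if (is.null(ref)) {
    f75 <- apply(work, 2, quantile, probs = 0.75) / libsize
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(m))
  if (!singleton_pairing) {
    pairs <- colSums(work > 0 & work[, ref] > 0)
    low <- which(pairs < 10)
  } else low <- integer(0)
  f <- edgeR::calcNormFactors(
    work, lib.size = libsize,
    method = if (singleton_pairing) "TMMwsp" else "TMM",
    refColumn = ref, logratioTrim = params$logratio_trim,
    sumTrim = params$abundance_trim)
  if (length(low)) {
    warning(sprintf("fewer than 10 usable gene pairs for well(s) %s; factor set to 1",
                    paste(colnames(m)[low] %||% low, collapse = ", ")))
    f[low] <- 1
    f <- f / exp(mean(log(f)))
  }
  norm_factors_table(m, if (singleton_pairing) "tmmwsp" else "tmm",
                     unname(f), unname(f) * libsize)
}

#' Normalised matrix from factors
#'
#' CPM computed against the effective library sizes of a `NormFactors`
#' table, so TMM-family and median-of-ratios factors yield comparable
#' normalised matrices.
#'
#' @param counts Count matrix, `count_matrix` or `Screen`.
#' @param factors A `NormFactors` table from one of the `norm_*` functions.
#' @return Normalised matrix (genes x wells).
#' @export
normalized_matrix <- function(counts, factors) {
  m <- as_count_values(counts)
  stopifnot(nrow(factors) == ncol(m))
  sweep(m, 2, factors$effective_libsize, "/") * 1e6
}

#' Normalise a screen by method name
#'
#' @param screen A `Screen` (or count matrix).
#' @param method One of `"cpm"`, `"tmm"`, `"tmmwsp"`, `"median_of_ratios"`.
#' @return List with `matrix` and `factors`.
#' @export
normalize_screen <- function(screen,
                             method = c("cpm", "tmm", "tmmwsp",
                                        "median_of_ratios")) {
  method <- match.arg(method)
  m <- as_count_values(screen)
  if (method == "cpm") return(norm_cpm(m))
  factors <- switch(method,
    tmm = norm_tmm(m),
    tmmwsp = norm_tmm(m, singleton_pairing = TRUE),
    median_of_ratios = norm_median_of_ratios(m))
  list(matrix = normalized_matrix(m, factors), factors = factors)
}

#' Remove control-gene variation
#'
#' RUV-style correction: the first `k` singular directions of the
#' row-centred log matrix restricted to a set of (negative-)control genes
#' define unwanted-variation factors; every gene is regressed on the factor
#' scores and the corrected matrix is residuals plus gene means. Factor
#' scores are also returned for use as covariates in differential
#' expression.
#'
#' @param log_counts Log-scale matrix (genes x wells).
#' @param control_genes Character vector of control gene ids (rownames) or
#'   integer indices.
#' @param k Number of factors to remove (0 = identity).
#' @return List with `corrected` matrix, `scores` (wells x k) and
#'   `loadings` used for the control genes.
#' @export
remove_control_variation <- function(log_counts, control_genes, k = 1) {
  x <- as.matrix(log_counts)
  idx <- if (is.character(control_genes)) match(control_genes, rownames(x))
         else control_genes
  if (anyNA(idx)) stop("control_genes not all present in matrix rownames")
  if (k >= ncol(x)) stop("k must be smaller than the number of wells")
  if (k == 0)
    return(list(corrected = x,
                scores = matrix(0, ncol(x), 0), loadings = NULL))
  ctrl <- x[idx, , drop = FALSE]
  ctrl_c <- ctrl - rowMeans(ctrl)
  r <- qr(ctrl_c)$rank
  if (k >= r)
    stop(sprintf("k (%d) must be below the rank of the centred control submatrix (%d)",
                 k, r))
  sv <- svd(ctrl_c, nu = k, nv = k)
  scores <- sv$v[, seq_len(k), drop = FALSE]        # wells x k, orthonormal
  rownames(scores) <- colnames(x)
  xc <- x - rowMeans(x)
  beta <- xc %*% scores                              # genes x k
  corrected <- x - beta %*% t(scores)
  list(corrected = corrected, scores = scores,
       loadings = sv$u %*% diag(sv$d[seq_len(k)], k))
}
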