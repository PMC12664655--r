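#' @title Enrichment analysis
#' @name enrich
#' @description Gene-set context for DE results: GMT collections,
#'   hypergeometric over-representation, preranked running-sum enrichment
#'   with a gene-label permutation NES, and signature scoring against a
#'   reference perturbation profile.
NULL

#' Load a GMT gene-set collection
#'
#' One set per line: `name TAB description TAB gene [TAB gene ...]`.
#' Duplicate genes within a set are deduplicated; empty sets and duplicate
#' set names are rejected.
#'
#' @param path GMT file path.
#' @param uppercase Uppercase gene identifiers on load.
#' @return Named list of character vectors with attribute `source`.
#' @export
load_gmt <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop(sprintf("missing file: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop(sprintf("malformed GMT line %d: empty gene set '%s'", i, f[1]))
    if (uppercase) genes <- toupper(genes)
    if (f[1] %in% names(sets))
      stop(sprintf("malformed GMT line %d: duplicate set name '%s'", i, f[1]))
    sets[[f[1]]] <- genes
  }
  attr(sets, "source") <- path
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Per set, the upper-tail hypergeometric probability of observing at least
#' the seen overlap between the DE genes and the set within the universe:
#' population `N = |universe|`, successes `K = |set intersect universe|`,
#' draws `n = |de_genes|`, observed `k`. BH adjustment across sets; fold
#' enrichment `(k/n) / (K/N)`.
#'
#' @param de_genes Character vector of hit genes (intersected with the
#'   universe; genes outside it are dropped with a warning).
#' @param universe Character vector of all testable genes.
#' @param sets Named list of gene sets.
#' @param min_overlap Report only sets with overlap >= this.
#' @return `data.frame`: `set`, `set_size`, `overlap`, `fold_enrichment`,
#'   `pvalue`, `padj`, `genes` (pipe-joined overlap).
#' @export
ora_hypergeom <- function(de_genes, universe, sets, min_overlap = 0L) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    warning(sprintf("%d DE gene(s) outside the universe dropped", length(outside)))
    de_genes <- intersect(de_genes, universe)
  }
  de_genes <- unique(de_genes)
  N <- length(universe); n <- length(de_genes)
  rows <- lapply(names(sets), function(s) {
    K <- length(intersect(sets[[s]], universe))
    ov <- intersect(de_genes, sets[[s]])
    k <- length(ov)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (k == 0 || K == 0 || n == 0) 0 else (k / n) / (K / N)
    data.frame(set = s, set_size = K, overlap = k, fold_enrichment = fe,
               pvalue = p, genes = paste(ov, collapse = "|"))
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$pvalue)
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "set_size", "overlap", "fold_enrichment", "pvalue",
          "padj", "genes")]
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for hit
# positions `pos` (indices into a ranking of length N sorted by decreasing
# statistic) with weights |r|^p at the hits. Returns the signed maximum
# deviation and its position.
running_es <- function(pos, wts, N) {
  o <- order(pos)
  pos <- pos[o]; wts <- wts[o]
  K <- length(pos)
  NR <- sum(wts)
  if (NR == 0) wts <- rep(1 / K, K) else wts <- wts / NR
  miss <- 1 / (N - K)
  cum_hit <- cumsum(wts)
  # deviation just after each hit, and just before each hit
  up <- cum_hit - (pos - seq_len(K)) * miss
  down <- c(0, cum_hit[-K]) - (pos - 1 - (seq_len(K) - 1)) * miss
  i_max <- which.max(up); i_min <- which.min(down)
  if (up[i_max] >= -down[i_min] || down[i_min] > 0)
    list(es = up[i_max], at = pos[i_max])
  else list(es = down[i_min], at = pos[i_min])
}

#' Preranked gene-set enrichment with permutation NES
#'
#' Walking the ranking in decreasing order of the statistic, hits add
#' `|r|^p / sum_set |r|^p` and misses subtract `1/(N - K)`; the enrichment
#' score (ES) is the signed maximum deviation of the running sum. The null
#' is generated by gene-label permutation (`n_perm` seeded draws of K
#' positions); `NES = ES / mean(|null ES| of matching sign)` and the
#' permutation p-value is `(1 + #{same-sign null at least as extreme}) /
#' (1 + #same-sign null)`.
#'
#' @param ranked_stats Named numeric vector (gene -> statistic), no `NA`.
#' @param set Character vector of set genes (>= 3 must intersect the
#'   ranking).
#' @param weight_exponent Hit-weight exponent `p` (1 = classic weighted KS,
#'   0 = unweighted).
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draws.
#' @return A `gsea_result` one-row data.frame: `es`, `nes`, `pvalue`,
#'   `leading_edge` (pipe-joined), `n_hits`, `n_perm`, `seed`, `flagged`.
#' @export
gsea_preranked <- function(ranked_stats, set, weight_exponent = 1,
                           n_perm = 1000L, seed = 1L) {
  if (anyNA(ranked_stats)) stop("ranking contains NA")
  ord <- order(ranked_stats, decreasing = TRUE)
  genes <- names(ranked_stats)[ord]
  r <- ranked_stats[ord]
  N <- length(r)
  hits <- which(genes %in% set)
  K <- length(hits)
  if (K < 3) stop("fewer than 3 set genes present in the ranking")
  flagged <- FALSE
  if (K >= N) {
    return(structure(data.frame(es = NA_real_, nes = NA_real_,
                                pvalue = NA_real_, leading_edge = "",
                                n_hits = K, n_perm = n_perm, seed = seed,
                                flagged = TRUE), class = c("gsea_result", "data.frame")))
  }
  wts_all <- abs(r)^weight_exponent
  obs <- running_es(hits, wts_all[hits], N)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pos <- sample.int(N, K)
    running_es(pos, wts_all[pos], N)$es
  }, numeric(1)))
  same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (length(same) < 10) {
    nes <- NA_real_; p <- NA_real_; flagged <- TRUE
  } else {
    nes <- obs$es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  }
  le <- if (obs$es >= 0) genes[hits[hits <= obs$at]]
        else genes[hits[hits >= obs$at]]
  structure(data.frame(es = obs$es, nes = nes, pvalue = p,
                       leading_edge = paste(le, collapse = "|"),
                       n_hits = K, n_perm = n_perm, seed = seed,
                       flagged = flagged),
            class = c("gsea_result", "data.frame"))
}

#' Enrichment of multiple sets against one ranking
#'
#' @param ranked_stats Named numeric vector (gene -> statistic).
#' @param sets Named list of gene sets (sets with < 3 ranked genes are
#'   skipped).
#' @param ... Passed to [gsea_preranked()].
#' @return `data.frame` with one row per set and BH-adjusted p across sets.
#' @export
gsea_collection <- function(ranked_stats, sets, ...) {
  rows <- lapply(names(sets), function(s) {
    res <- tryCatch(gsea_preranked(ranked_stats, sets[[s]], ...),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(set = s), res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set had at least 3 genes in the ranking")
  out$padj <- adjust_bh(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Score a DE result against a reference perturbation signature
#'
#' Builds the signature as the top `top_n` genes of a reference ranked
#' profile (largest statistic first), ranks the query genes by their DE
#' statistic and delegates to [gsea_preranked()]. A positive NES with small
#' p indicates the query reproduces the reference response.
#'
#' @param query A `DEResult` data.frame (uses `stat` ranking).
#' @param reference_profile Named numeric vector (gene -> statistic) or a
#'   character vector of genes already ordered best-first.
#' @param top_n Signature size (default 500).
#' @param ... Passed to [gsea_preranked()].
#' @return A `gsea_result` row.
#' @export
signature_score <- function(query, reference_profile, top_n = 500L, ...) {
  ref_genes <- if (is.numeric(reference_profile))
    names(sort(reference_profile, decreasing = TRUE))
  else as.character(reference_profile)
  sig <- head(ref_genes, top_n)
  ranked <- setNames(query$stat, query$gene_id)
  ranked <- ranked[!is.na(ranked)]
  if (length(intersect(sig, names(ranked))) < top_n / 2)
    stop("signature/universe overlap below top_n/2; check identifier spaces")
  res <- gsea_preranked(ranked, sig, ...)
  if (res$n_hits >= length(ranked)) res$flagged <- TRUE
  res
}
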