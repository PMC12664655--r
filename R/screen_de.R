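#' @title Multi-treatment screen analysis
#' @name screen_de
#' @description Run differential expression for every treatment against the
#'   shared vehicle controls, summarise hit counts and up/down ratios, and
#'   compare treatments or engines via exclusive-overlap (UpSet) counts and
#'   distance matrices. Per-treatment tasks are pure functions of the screen
#'   and design, so any worker count yields bit-identical results.
NULL

#' Run DE for every treatment vs shared controls
#'
#' One [de_run()] per distinct treatment x concentration (vehicle wells
#' excluded), each against the same vehicle controls on the same plate.
#' Treatments with fewer than `min_reps` wells are skipped with a warning.
#'
#' @param screen A filtered `Screen`.
#' @param control_label Vehicle treatment name used when no `sample_type`
#'   column identifies vehicle wells.
#' @param engine DE engine name, see [de_run()].
#' @param group_by Metadata columns defining one analysis unit.
#' @param parallelism Worker count (forked via `parallel::mclapply`; results
#'   are independent of the worker count).
#' @param min_reps Minimum treatment wells to attempt DE.
#' @param weights Optional observation weight matrix (genes x screen wells)
#'   passed to weight-capable engines.
#' @return A `screen_de_results`: named list `results` (one `DEResult` per
#'   treatment key), `engine`, `control_wells`, `skipped`.
#' @export
run_all_de <- function(screen, control_label = "DMSO", engine = "nbql",
                       group_by = c("treatment", "concentration"),
                       parallelism = 1L, min_reps = 2L, weights = NULL) {
  md <- screen$metadata
  ctrl <- control_wells(screen, control_label)
  if (length(ctrl) < 2) stop("need at least 2 resolvable control wells")
  is_ctrl <- md$barcode %in% ctrl
  key <- interaction(md[group_by], drop = TRUE, lex.order = TRUE, sep = "_")
  keys <- setdiff(unique(as.character(key[!is_ctrl])),
                  unique(as.character(key[is_ctrl])))
  if (length(keys) < 1) stop("no treatment groups to analyse")
  sizes <- vapply(keys, function(k) sum(key == k & !is_ctrl), 1L)
  skipped <- keys[sizes < min_reps]
  for (k in skipped)
    warning(sprintf("skipping '%s': %d replicate(s) < min_reps", k,
                    sizes[[k]]))
  keys <- setdiff(keys, skipped)
  run_one <- function(k) {
    tw <- md$barcode[key == k & !is_ctrl]
    plates <- unique(md$plate[md$barcode %in% tw])
    cw <- ctrl[md$plate[match(ctrl, md$barcode)] %in% plates]
    if (length(cw) < 2) cw <- ctrl
    de_run(engine, screen,
           de_design(tw, cw, weights = weights))
  }
  res <- if (parallelism > 1L)
    parallel::mclapply(keys, run_one, mc.cores = parallelism)
  else lapply(keys, run_one)
  names(res) <- keys
  structure(list(results = res, engine = engine, control_wells = ctrl,
                 skipped = skipped, group_by = group_by),
            class = "screen_de_results")
}

#' Per-treatment DE summary
#'
#' Counts of up/down-regulated genes passing `|log2fc| > lfc_cut` and
#' `padj < padj_cut` per treatment, the up/down ratio (`Inf` when hits are
#' all up, `NA` when there are no hits) and the top-k genes by adjusted p.
#'
#' @param results A `screen_de_results` (or named list of `DEResult`s).
#' @param lfc_cut Absolute log2 fold-change cut.
#' @param padj_cut Adjusted-p cut.
#' @param top_k Genes to report per treatment.
#' @return `data.frame` with one row per treatment.
#' @export
de_summary <- function(results, lfc_cut = 1, padj_cut = 0.05, top_k = 10L) {
  res <- if (inherits(results, "screen_de_results")) results$results else results
  rows <- lapply(names(res), function(k) {
    r <- res[[k]]
    hit <- !is.na(r$padj) & r$padj < padj_cut & abs(r$log2fc) > lfc_cut
    n_up <- sum(hit & r$log2fc > 0); n_down <- sum(hit & r$log2fc < 0)
    ratio <- if (n_up + n_down == 0) NA_real_
             else if (n_down == 0) Inf else n_up / n_down
    ord <- order(r$padj, r$pvalue)
    data.frame(treatment = k, n_up = n_up, n_down = n_down,
               n_total = n_up + n_down, up_down_ratio = ratio,
               top_genes = paste(head(r$gene_id[ord], top_k), collapse = ","))
  })
  do.call(rbind, rows)
}

#' DE gene sets from screen results
#'
#' @param results A `screen_de_results` or named list of `DEResult`s.
#' @param lfc_cut,padj_cut Hit thresholds.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Named list of gene-id character vectors.
#' @export
de_gene_sets <- function(results, lfc_cut = 1, padj_cut = 0.05,
                         direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  res <- if (inherits(results, "screen_de_results")) results$results else results
  lapply(res, function(r) {
    hit <- !is.na(r$padj) & r$padj < padj_cut & abs(r$log2fc) > lfc_cut
    hit <- switch(direction, both = hit,
                  up = hit & r$log2fc > 0, down = hit & r$log2fc < 0)
    r$gene_id[hit]
  })
}

#' Exclusive overlap (UpSet) counts
#'
#' For k named sets, the count of elements lying in exactly each non-empty
#' combination of sets (UpSet semantics). Exclusive counts sum to the union
#' size, and each set's size is the sum of the combinations containing it.
#'
#' @param sets Named list of >= 2 vectors (k <= 12).
#' @return An `overlap_table`: `combos` data.frame (`combo`, `degree`,
#'   `count`), `set_sizes`, `union_size`.
#' @export
overlap_counts <- function(sets) {
  k <- length(sets)
  if (k < 2) stop("need at least 2 sets")
  if (k > 12) stop("more than 12 sets: combinatorial table too large")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, ncol = k)
  pattern <- apply(memb, 1, function(b) paste(names(sets)[b], collapse = "&"))
  tab <- table(pattern)
  combos <- data.frame(combo = names(tab),
                       degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                       count = as.integer(tab), row.names = NULL)
  combos <- combos[order(-combos$degree, combos$combo), , drop = FALSE]
  rownames(combos) <- NULL
  structure(list(combos = combos,
                 set_sizes = vapply(sets, length, 1L),
                 union_size = length(universe)),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("overlap_table: %d sets, union %d\n", length(x$set_sizes),
              x$union_size))
  print(x$combos)
  invisible(x)
}

#' Distance matrix between treatments
#'
#' Jaccard distance on DE gene sets at the stated cuts, or one minus the
#' Spearman correlation of log2 fold-change vectors over the shared gene
#' universe.
#'
#' @param results A `screen_de_results` or named list of `DEResult`s.
#' @param metric `"jaccard_on_sets"` or `"spearman_on_lfc"`.
#' @param lfc_cut,padj_cut Hit thresholds for the Jaccard metric.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
treatment_distance <- function(results,
                               metric = c("jaccard_on_sets", "spearman_on_lfc"),
                               lfc_cut = 1, padj_cut = 0.05) {
  metric <- match.arg(metric)
  res <- if (inherits(results, "screen_de_results")) results$results else results
  if (length(res) < 2) stop("need at least 2 treatments")
  nms <- names(res)
  D <- matrix(0, length(res), length(res), dimnames = list(nms, nms))
  if (metric == "jaccard_on_sets") {
    sets <- de_gene_sets(res, lfc_cut, padj_cut)
    for (i in seq_along(res)) for (j in seq_along(res)) {
      if (i >= j) next
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0) {
        warning(sprintf("empty DE sets for '%s' and '%s'; distance set to 1",
                        nms[i], nms[j]))
        d <- 1
      } else d <- 1 - length(intersect(sets[[i]], sets[[j]])) / u
      D[i, j] <- D[j, i] <- d
    }
  } else {
    genes <- Reduce(intersect, lapply(res, function(r) r$gene_id))
    L <- vapply(res, function(r) r$log2fc[match(genes, r$gene_id)],
                numeric(length(genes)))
    C <- cor(L, method = "spearman")
    D <- 1 - C
    diag(D) <- 0
  }
  D
}
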