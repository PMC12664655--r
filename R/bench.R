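#' @title Resampling benchmark harness
#' @name bench
#' @description Reusable procedures probing how analysis choices shape
#'   screen results: gene-filter sweeps, false-positive estimation from
#'   random splits of the vehicle pool, leave-one-out replicate
#'   subsampling, control-count sweeps and cross-engine overlap. Every
#'   procedure is a pure function of (screen, config, seed) and reproduces
#'   exactly under the same seed.
NULL

#' Benchmark configuration
#'
#' @param thresholds Ascending minimum-count thresholds for filter sweeps.
#' @param engines DE engine names.
#' @param lfc_cut,padj_cut,p_cut Hit thresholds (|log2fc|, BH-adjusted p,
#'   nominal p).
#' @param n_repeats Number of resampling repeats `R`.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param min_groups Groups threshold `k` for the gene filter.
#' @param norm_methods Normalisations scored in [filter_sweep()].
#' @return A `bench_config` list.
#' @export
bench_config <- function(thresholds = c(0, 1, 2, 5, 10, 20),
                         engines = c("nbql", "voom"),
                         lfc_cut = 1, padj_cut = 0.05, p_cut = 0.05,
                         n_repeats = 3L, seed = 1L, min_groups = 2L,
                         norm_methods = c("cpm", "tmm", "tmmwsp")) {
  stopifnot(n_repeats >= 1, lfc_cut > 0, padj_cut > 0, p_cut > 0,
            !is.unsorted(thresholds))
  structure(as.list(environment()), class = "bench_config")
}

se_of <- function(x) sd(x) / sqrt(length(x))

#' Gene-filter sweep
#'
#' For each minimum-count threshold, applies the group-sum gene filter and
#' reports the sparsity (zero fraction), the number of retained genes and
#' the average coefficient of variation under each normalisation, all
#' measured on the given wells (typically the vehicle controls).
#'
#' @param screen A `Screen`.
#' @param config A [bench_config()].
#' @param wells Well barcodes to measure on; default the vehicle controls,
#'   falling back to all wells.
#' @return `data.frame`: one row per threshold x normalisation.
#' @export
filter_sweep <- function(screen, config = bench_config(), wells = NULL) {
  if (is.null(wells)) {
    wells <- control_wells(screen)
    if (length(wells) < 2) wells <- screen$counts$barcodes
  }
  rows <- list()
  for (t in config$thresholds) {
    filt <- filter_genes(screen, gene_filter_spec(min_count = t,
                                                  min_groups = config$min_groups))
    sub <- screen_counts(filt)[, wells, drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("threshold %g eliminates all genes", t))
      for (m in config$norm_methods)
        rows[[length(rows) + 1]] <- data.frame(
          threshold = t, norm = m, sparsity = NA_real_,
          detected_genes = 0L, avg_cv = NA_real_)
      next
    }
    for (m in config$norm_methods) {
      nm <- tryCatch(normalize_screen(sub, m)$matrix,
                     error = function(e) NULL)
      acv <- if (is.null(nm)) NA_real_
             else tryCatch(average_cv(nm), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, norm = m, sparsity = mean(sub == 0),
        detected_genes = nrow(sub), avg_cv = acv)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "wells") <- wells
  out
}

# Seeded fixed partition of the vehicle pool into two pools of pool_size.
split_control_pools <- function(ctrl, pool_size, seed, scheme) {
  if (scheme == "two_pools") {
    if (length(ctrl) < 2 * pool_size)
      stop(sprintf("need >= %d control wells for two pools of %d, have %d",
                   2 * pool_size, pool_size, length(ctrl)))
    perm <- with_seed(seed, sample(ctrl))
    list(perm[seq_len(pool_size)],
         perm[pool_size + seq_len(pool_size)])
  } else {
    if (length(ctrl) < pool_size)
      stop(sprintf("need >= %d control wells, have %d", pool_size,
                   length(ctrl)))
    pool <- with_seed(seed, sample(ctrl, pool_size))
    list(pool, pool)
  }
}

#' False-positive estimation from vehicle splits
#'
#' The vehicle wells are partitioned once (seeded) into two pools of
#' `pool_size`; each repeat draws two disjoint groups of `n` wells from the
#' two pools, runs each engine on this null contrast and counts genes with
#' nominal `p < p_cut` and `|log2fc| > lfc_cut`, and separately with
#' `padj < padj_cut`. Under the global null the padj-based count should be
#' zero almost always.
#'
#' @param screen A filtered `Screen`.
#' @param control_label Vehicle treatment name.
#' @param n Wells per group.
#' @param pool_size Pool size per side.
#' @param config A [bench_config()] (engines, cuts, repeats, seed).
#' @param scheme `"two_pools"` (two disjoint seeded pools) or
#'   `"single_pool"` (both groups drawn disjointly from one pool).
#' @return List with `repeats` (per repeat x engine counts) and `summary`
#'   (mean and standard error per engine).
#' @export
null_split_fpr <- function(screen, control_label = "DMSO", n = 3L,
                           pool_size = 8L, config = bench_config(),
                           scheme = c("two_pools", "single_pool")) {
  scheme <- match.arg(scheme)
  if (n > pool_size) stop("n must not exceed pool_size")
  ctrl <- control_wells(screen, control_label)
  pools <- split_control_pools(ctrl, pool_size, config$seed, scheme)
  rows <- list()
  for (r in seq_len(config$n_repeats)) {
    gsel <- with_seed(config$seed + r, {
      g1 <- sample(pools[[1]], n)
      g2 <- if (scheme == "two_pools") sample(pools[[2]], n)
            else sample(setdiff(pools[[2]], g1), n)
      list(g1, g2)
    })
    for (eng in config$engines) {
      res <- de_run(eng, screen, de_design(gsel[[1]], gsel[[2]]))
      big <- abs(res$log2fc) > config$lfc_cut
      rows[[length(rows) + 1]] <- data.frame(
        repeat_id = r, engine = eng,
        n_nominal = sum(res$pvalue < config$p_cut & big, na.rm = TRUE),
        n_padj = sum(res$padj < config$padj_cut & big, na.rm = TRUE),
        frac_nominal = mean(res$pvalue < config$p_cut, na.rm = TRUE))
    }
  }
  rep_tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(rep_tab, rep_tab$engine), function(d)
    data.frame(engine = d$engine[1],
               mean_nominal = mean(d$n_nominal), se_nominal = se_of(d$n_nominal),
               mean_padj = mean(d$n_padj), se_padj = se_of(d$n_padj))))
  rownames(summ) <- NULL
  list(repeats = rep_tab, summary = summ, pools = pools, scheme = scheme)
}

#' Replicate subsampling concordance
#'
#' The reference DE set uses all `n_full` replicates of the treatment; each
#' leave-one-out subset of `n_full - 1` replicates is re-analysed and its
#' DE set compared with the reference (overlap percent and count change).
#'
#' @param screen A filtered `Screen`.
#' @param treatment Treatment name with exactly `n_full` wells.
#' @param control_label Vehicle treatment name.
#' @param n_full Full replicate count (default 3).
#' @param config A [bench_config()].
#' @return List with `subsets` (per engine x leave-one-out row) and
#'   `summary` (mean and se of the overlap percent per engine), plus the
#'   reference DE counts.
#' @export
replicate_subsample <- function(screen, treatment, control_label = "DMSO",
                                n_full = 3L, config = bench_config()) {
  md <- screen$metadata
  tw <- md$barcode[md$treatment == treatment]
  if (length(tw) != n_full)
    stop(sprintf("treatment '%s' has %d wells, expected n_full = %d",
                 treatment, length(tw), n_full))
  ctrl <- control_wells(screen, control_label)
  hit_set <- function(res) {
    hit <- !is.na(res$padj) & res$padj < config$padj_cut &
      abs(res$log2fc) > config$lfc_cut
    res$gene_id[hit]
  }
  rows <- list(); refs <- list()
  for (eng in config$engines) {
    ref <- hit_set(de_run(eng, screen, de_design(tw, ctrl)))
    refs[[eng]] <- ref
    for (i in seq_len(n_full)) {
      sub <- hit_set(de_run(eng, screen, de_design(tw[-i], ctrl)))
      ov <- if (length(ref) == 0) NA_real_
            else 100 * length(intersect(sub, ref)) / length(ref)
      if (length(ref) == 0 && i == 1)
        warning(sprintf("empty reference DE set for engine '%s'", eng))
      rows[[length(rows) + 1]] <- data.frame(
        engine = eng, left_out = i, n_ref = length(ref),
        n_sub = length(sub), overlap_pct = ov)
    }
  }
  sub_tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(sub_tab, sub_tab$engine), function(d)
    data.frame(engine = d$engine[1], n_ref = d$n_ref[1],
               mean_n_sub = mean(d$n_sub), se_n_sub = se_of(d$n_sub),
               mean_overlap_pct = mean(d$overlap_pct),
               se_overlap_pct = se_of(d$overlap_pct))))
  rownames(summ) <- NULL
  list(subsets = sub_tab, summary = summ, reference_sets = refs)
}

#' Control-count sweep
#'
#' For each control count `c`, draws `c` vehicle wells (`n_repeats` seeded
#' draws) and counts DE genes for the treatment against that reduced
#' control set, per engine.
#'
#' @param screen A filtered `Screen`.
#' @param treatment Treatment name.
#' @param control_label Vehicle treatment name.
#' @param control_counts Increasing control-well counts to test.
#' @param config A [bench_config()].
#' @return List with `draws` (per engine x count x repeat) and `summary`
#'   (mean and se per engine x count).
#' @export
control_count_sweep <- function(screen, treatment, control_label = "DMSO",
                                control_counts = c(2, 3, 5, 8, 12, 19),
                                config = bench_config()) {
  md <- screen$metadata
  tw <- md$barcode[md$treatment == treatment]
  ctrl <- control_wells(screen, control_label)
  if (max(control_counts) > length(ctrl))
    stop(sprintf("max control count (%d) exceeds available controls (%d)",
                 max(control_counts), length(ctrl)))
  rows <- list()
  for (cc in control_counts) for (r in seq_len(config$n_repeats)) {
    cw <- if (cc == length(ctrl)) ctrl
          else with_seed(config$seed + 1000L * cc + r, sample(ctrl, cc))
    for (eng in config$engines) {
      res <- de_run(eng, screen, de_design(tw, cw))
      hit <- !is.na(res$padj) & res$padj < config$padj_cut &
        abs(res$log2fc) > config$lfc_cut
      rows[[length(rows) + 1]] <- data.frame(
        engine = eng, n_controls = cc, repeat_id = r, n_de = sum(hit))
    }
  }
  draws <- do.call(rbind, rows)
  key <- paste(draws$engine, draws$n_controls)
  summ <- do.call(rbind, lapply(split(draws, key), function(d)
    data.frame(engine = d$engine[1], n_controls = d$n_controls[1],
               mean_n_de = mean(d$n_de), se_n_de = se_of(d$n_de))))
  summ <- summ[order(summ$engine, summ$n_controls), ]
  rownames(summ) <- NULL
  list(draws = draws, summary = summ)
}

#' Cross-engine overlap of DE calls
#'
#' Runs each engine on the treatment-vs-vehicle contrast, splits hits by
#' sign and tabulates exclusive overlaps (UpSet semantics) for the chosen
#' direction.
#'
#' @param screen A filtered `Screen`.
#' @param treatment Treatment name.
#' @param control_label Vehicle treatment name.
#' @param config A [bench_config()] (>= 2 engines).
#' @param direction `"up"` or `"down"`.
#' @return An [overlap_counts()] table over engines.
#' @export
engine_overlap <- function(screen, treatment, control_label = "DMSO",
                           config = bench_config(),
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(config$engines) < 2) stop("need at least 2 engines")
  md <- screen$metadata
  tw <- md$barcode[md$treatment == treatment]
  ctrl <- control_wells(screen, control_label)
  sets <- lapply(config$engines, function(eng) {
    res <- de_run(eng, screen, de_design(tw, ctrl))
    hit <- !is.na(res$padj) & res$padj < config$padj_cut &
      abs(res$log2fc) > config$lfc_cut
    hit <- if (direction == "up") hit & res$log2fc > 0
           else hit & res$log2fc < 0
    res$gene_id[hit]
  })
  names(sets) <- config$engines
  overlap_counts(sets)
}
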