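test_that("RLE is zero for identical or depth-scaled wells", {
  m <- matrix(c(10, 5, 2, 10, 5, 2), 3, 2)
  r <- compute_rle(m)
  expect_true(all(r$rle_values == 0))
  expect_equal(r$avg_cv, 0)

  # well B = 2 x well A: CPM removes depth, RLE flat
  a <- c(100, 50, 10, 5)
  cpm <- norm_cpm(cbind(A = a, B = 2 * a))$matrix
  expect_true(all(abs(compute_rle(cpm)$rle_values) < 1e-12))
})

test_that("RLE matches a hand computation on a small matrix", {
  m <- matrix(c(3, 0, 7, 1,
                1, 4, 7, 3,
                3, 8, 0, 1), 4, 3)
  r <- compute_rle(m, pseudocount = 1)
  lg <- log2(m + 1)
  expected <- lg - apply(lg, 1, median)
  expect_equal(unname(r$rle_values), unname(expected))
  expect_equal(r$per_well_summary$median_rle, apply(expected, 2, median))
  # per-gene rows are median-centred at 0 with the all-wells reference
  expect_true(all(abs(apply(r$rle_values, 1, median)) < 1e-12))
  expect_error(compute_rle(m[, 1, drop = FALSE]), "2 wells")
})

test_that("average CV follows the sd/mean definition and its invariances", {
  expect_equal(average_cv(matrix(5, 3, 4)), 0)
  one <- matrix(c(10, 10, 40), 1, 3)
  expect_equal(average_cv(one), sd(c(10, 10, 40)) / 20)
  # invariant to global rescaling
  m <- nb_matrix(60, 6, seed = 2) + 1
  expect_equal(average_cv(m), average_cv(m * 7.3))
  expect_error(average_cv(m, min_mean = 1e9), "min_mean")
})

test_that("normalising a depth-confounded screen lowers the average CV", {
  set.seed(42)
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    mu <- 2^rnorm(150, 5, 1.5)
    depth <- exp(seq(-0.8, 0.8, length.out = 10))
    m <- matrix(rnbinom(150 * 10, size = 8, mu = outer(mu, depth)), 150, 10)
    raw_cv <- average_cv(m, min_mean = 1)
    cpm_cv <- average_cv(sweep(m, 2, pmax(colSums(m), 1), "/") * 1e6,
                         min_mean = 1)
    if (cpm_cv < raw_cv) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("QC summary counts detection and zeros per well", {
  m <- cbind(w1 = c(0, 0, 5), w2 = c(1, 2, 3))
  rownames(m) <- paste0("g", 1:3)
  scr <- toy_screen(cbind(m, w3 = c(2, 2, 2), w4 = c(1, 1, 4)),
                    c("A", "A", "DMSO", "DMSO"))
  qc <- compute_qc_summary(scr)
  expect_equal(qc$detected_genes[1], 1)
  expect_equal(qc$fraction_zero[1], 2 / 3)
  expect_equal(qc$total_counts, unname(colSums(screen_counts(scr))))

  # brute-force recomputation on a simulated screen
  sim <- quick_sim(n_genes = 120, seed = 9)
  qs <- compute_qc_summary(sim$screen)
  counts <- screen_counts(sim$screen)
  for (j in c(1, 10, 20)) {
    expect_equal(qs$total_counts[j], sum(counts[, j]))
    expect_equal(qs$detected_genes[j], sum(counts[, j] > 0))
    expect_equal(qs$fraction_zero[j], mean(counts[, j] == 0))
  }

  # an all-zero well detects nothing and is flagged
  m2 <- nb_matrix(300, 6, mu = 20, seed = 3)
  m2[, 4] <- 0
  scr2 <- toy_screen(m2, c("A", "A", "A", "DMSO", "DMSO", "DMSO"))
  qc2 <- compute_qc_summary(scr2)
  expect_equal(qc2$detected_genes[4], 0)
  expect_true(qc2$outlier[4])
})

test_that("gene filtering applies the group-count rule", {
  # per-group sums (6,4), (5,5), (0,9); t=5, k=2 keeps only gene 2
  counts <- rbind(g1 = c(3, 3, 2, 2),
                  g2 = c(2, 3, 1, 4),
                  g3 = c(0, 0, 4, 5))
  scr <- toy_screen(counts, c("A", "A", "B", "B"))
  filt <- filter_genes(scr, gene_filter_spec(min_count = 5, min_groups = 2))
  expect_equal(rownames(screen_counts(filt)), "g2")
  expect_match(tail(filt$provenance, 1), "removed 2 of 3")

  # t = 0 keeps everything
  f0 <- filter_genes(scr, gene_filter_spec(min_count = 0, min_groups = 2))
  expect_equal(nrow(screen_counts(f0)), 3)

  # monotone in t, and independent of well/gene order
  sim <- quick_sim(n_genes = 200, seed = 4)
  g5 <- rownames(screen_counts(filter_genes(sim$screen,
                                            gene_filter_spec(min_count = 5))))
  g10 <- rownames(screen_counts(filter_genes(sim$screen,
                                             gene_filter_spec(min_count = 10))))
  expect_true(all(g10 %in% g5))

  perm_wells <- sample(ncol(screen_counts(sim$screen)))
  scr_perm <- sim$screen
  scr_perm$counts <- count_matrix(
    screen_counts(sim$screen)[, perm_wells],
    gene_ids = sim$screen$counts$gene_ids,
    barcodes = sim$screen$counts$barcodes[perm_wells])
  scr_perm$metadata <- sim$screen$metadata[perm_wells, ]
  g5p <- rownames(screen_counts(filter_genes(scr_perm,
                                             gene_filter_spec(min_count = 5))))
  expect_setequal(g5, g5p)

  expect_error(filter_genes(scr, gene_filter_spec(min_groups = 5)),
               "exceeds")
})

test_that("outlier flagging reacts to distortion but not depth", {
  m <- nb_matrix(500, 8, mu = 30, theta = 10, seed = 6)
  scr <- toy_screen(m, rep(c("A", "DMSO"), each = 4))
  cpm <- norm_cpm(m)$matrix
  expect_false(any(flag_outliers(compute_rle(cpm),
                                 compute_qc_summary(scr, cpm))))

  # a 100x deeper well is rescued by CPM
  m2 <- m; m2[, 3] <- m[, 3] * 100
  cpm2 <- norm_cpm(m2)$matrix
  scr2 <- toy_screen(m2, rep(c("A", "DMSO"), each = 4))
  expect_false(flag_outliers(compute_rle(cpm2),
                             compute_qc_summary(scr2, cpm2))[3])

  # zeroing half the genes in one well trips the detected-genes floor
  m3 <- m; m3[seq_len(250), 5] <- 0
  scr3 <- toy_screen(m3, rep(c("A", "DMSO"), each = 4))
  cpm3 <- norm_cpm(m3)$matrix
  flags <- flag_outliers(compute_rle(cpm3), compute_qc_summary(scr3, cpm3),
                         outlier_rule(min_detected = 400))
  expect_true(flags[5])
})

test_that("variance decomposition matches sequential ANOVA", {
  # a factor that fully determines the values
  y <- matrix(rep(c(1, 1, 1, 3, 3, 3), each = 5), 5, 6, byrow = FALSE)
  y <- rbind(y, y * 2)
  vd <- variance_decomposition(y, data.frame(grp = rep(c("a", "b"), each = 3)))
  expect_equal(vd$average$fraction[vd$average$factor == "grp"], 1)
  expect_equal(vd$average$fraction[vd$average$factor == "residual"], 0)

  # against per-gene anova(lm) with two orthogonal balanced factors
  set.seed(8)
  f1 <- rep(c("x", "y"), times = 6)
  f2 <- rep(c("p", "q", "r"), each = 4)
  ym <- matrix(rnorm(12 * 20, mean = as.numeric(factor(f1))), 20, 12,
               byrow = TRUE) + matrix(rnorm(240, sd = 0.5), 20, 12)
  vd2 <- variance_decomposition(ym, data.frame(a = f1, b = f2))
  oracle <- anova_frac_oracle(ym, list(a = f1, b = f2))
  expect_equal(unname(vd2$per_gene[, c("a", "b", "residual")]),
               unname(oracle), tolerance = 1e-10)
  # fractions sum to one per gene
  expect_true(all(abs(rowSums(vd2$per_gene) - 1) < 1e-10))

  # permuted labels explain almost nothing
  set.seed(9)
  y3 <- matrix(rnorm(48 * 30), 30, 48)
  vd3 <- variance_decomposition(y3, data.frame(g = sample(rep(c("a", "b"), 24))))
  expect_lt(vd3$average$fraction[vd3$average$factor == "g"], 0.1)

  # aliased factors warn
  expect_warning(
    variance_decomposition(ym, data.frame(a = f1, dup = f1)), "aliased")
})
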