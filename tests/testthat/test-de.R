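# Shared fixture: moderate NB screen with one treatment vs vehicle.
de_fixture <- function(seed = 1, n_genes = 300, frac_de = 0.1) {
  sim <- quick_sim(n_genes = n_genes, n_treatments = 1, n_reps = 3,
                   n_vehicle = 8, frac_de = frac_de, seed = seed)
  scr <- filter_genes(sim$screen)
  md <- screen_metadata(scr)
  list(screen = scr, truth = sim$truth,
       tw = md$barcode[md$treatment == "T01"],
       cw = control_wells(scr))
}

test_that("label swap negates log2fc and preserves p for every engine", {
  fx <- de_fixture(seed = 2)
  for (eng in c("nbql", "voom", "trend", "wald_nb", "ranksum")) {
    a <- de_run(eng, fx$screen, de_design(fx$tw, fx$cw))
    b <- de_run(eng, fx$screen, de_design(fx$cw, fx$tw))
    # wald_nb estimates by IRLS, converged to ~1e-6 on the coefficients
    tol <- if (eng == "wald_nb") 1e-4 else 1e-6
    expect_equal(a$log2fc, -b$log2fc, tolerance = tol, label = eng)
    expect_equal(a$pvalue, b$pvalue, tolerance = tol, label = eng)
    expect_true(all(a$pvalue >= 0 & a$pvalue <= 1, na.rm = TRUE), label = eng)
  }
})

test_that("engines are deterministic and stable under gene permutation", {
  fx <- de_fixture(seed = 3)
  perm <- sample(nrow(screen_counts(fx$screen)))
  scr_p <- fx$screen
  scr_p$counts <- count_matrix(
    screen_counts(fx$screen)[perm, ],
    gene_ids = fx$screen$counts$gene_ids[perm],
    gene_names = fx$screen$counts$gene_names[perm],
    barcodes = fx$screen$counts$barcodes)
  for (eng in c("voom", "trend", "ranksum")) {
    # strict check under CPM, which is exactly gene-order invariant
    d <- de_design(fx$tw, fx$cw, normalisation = "cpm")
    a <- de_run(eng, fx$screen, d)
    b <- de_run(eng, scr_p, d)
    expect_identical(a, de_run(eng, fx$screen, d), label = eng)
    reord <- b[match(a$gene_id, b$gene_id), ]
    rownames(reord) <- NULL
    expect_equal(a$pvalue, reord$pvalue, tolerance = 1e-10, label = eng)
  }
  # under TMMwsp the singleton-pairing step breaks count ties in input
  # order, so permutation stability holds only to small numerical jitter
  aw <- de_voom(fx$screen, de_design(fx$tw, fx$cw))
  bw <- de_voom(scr_p, de_design(fx$tw, fx$cw))
  reord <- bw[match(aw$gene_id, bw$gene_id), ]
  expect_equal(aw$pvalue, reord$pvalue, tolerance = 5e-3)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA propagation: NAs excluded from m
  p <- c(0.01, NA, 0.04)
  expect_equal(adjust_bh(p), c(0.02, NA, 0.04))
  # monotone in sorted order
  p2 <- runif(100)
  q <- adjust_bh(p2)
  expect_true(!is.unsorted(q[order(p2)]))
})

test_that("rank-sum engine reproduces exact enumeration", {
  # gene 2 complements gene 1 so library sizes are equal and CPM keeps
  # gene 1's ordering {1,2} vs {3,4}
  scr <- toy_screen(rbind(g1 = c(1, 2, 3, 4) * 100,
                          g2 = c(9, 8, 7, 6) * 100),
                    c("A", "A", "DMSO", "DMSO"))
  res <- de_ranksum(scr, de_design(c("BC001", "BC002"), c("BC003", "BC004")))
  expect_equal(res$pvalue[1], 1 / 3, tolerance = 1e-12)

  # identical groups: p = 1, log2fc = 0
  scr2 <- toy_screen(rbind(g1 = c(5, 7, 5, 7) * 50,
                           g2 = c(5, 3, 5, 3) * 50),
                     c("A", "A", "DMSO", "DMSO"))
  res2 <- de_ranksum(scr2, de_design(c("BC001", "BC002"), c("BC003", "BC004")))
  expect_equal(res2$pvalue, c(1, 1))
  expect_equal(res2$log2fc, c(0, 0))

  # exact path agrees with full enumeration across random 5v5 genes
  set.seed(42)
  m <- matrix(rnbinom(40 * 10, size = 5, mu = 50), 40, 10) + 1
  scr3 <- toy_screen(m, rep(c("A", "DMSO"), each = 5))
  d3 <- de_design(screen_metadata(scr3)$barcode[1:5],
                  screen_metadata(scr3)$barcode[6:10],
                  normalisation = "cpm")
  res3 <- de_ranksum(scr3, d3)
  cpm <- norm_cpm(screen_counts(scr3))$matrix
  keep <- which(apply(cpm, 1, function(v) !anyDuplicated(v)))[1:15]
  for (g in keep)
    expect_equal(res3$pvalue[g], wilcox_enum_p(cpm[g, 1:5], cpm[g, 6:10]),
                 tolerance = 1e-10)

  # normal approximation tracks enumeration at 6v6
  set.seed(43)
  m6 <- matrix(rnbinom(120 * 12, size = 5, mu = 60), 120, 12) + 1
  cpm6 <- norm_cpm(m6)$matrix
  noties <- which(apply(cpm6, 1, function(v) !anyDuplicated(v)))
  dmax <- 0
  for (g in head(noties, 60)) {
    x <- cpm6[g, 1:6]; y <- cpm6[g, 7:12]
    approx_p <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))$p.value
    dmax <- max(dmax, abs(approx_p - wilcox_enum_p(x, y)))
  }
  expect_lt(dmax, 0.02)
})

test_that("voom weights are flat on homoskedastic data and trend tracks voom", {
  # counts built so that log2-CPM has no mean-variance trend: large,
  # tight NB counts at a common mean
  set.seed(44)
  m <- matrix(rnbinom(400 * 12, size = 100, mu = 1000), 400, 12)
  scr <- toy_screen(m, rep(c("A", "DMSO"), each = 6))
  md <- screen_metadata(scr)
  d <- de_design(md$barcode[1:6], md$barcode[7:12])
  v <- limma::voom(screen_counts(scr), cbind(1, rep(0:1, each = 6)))
  expect_lt(sd(v$weights) / mean(v$weights), 0.1)

  rv <- de_voom(scr, d)
  rt <- de_trend(scr, d)
  expect_gt(cor(rv$pvalue, rt$pvalue, method = "spearman"), 0.95)

  # a constant gene is not called changed by trend
  m2 <- m; m2[1, ] <- 500
  scr2 <- toy_screen(m2, rep(c("A", "DMSO"), each = 6))
  rt2 <- de_trend(scr2, de_design(md$barcode[1:6], md$barcode[7:12],
                                  normalisation = "cpm"))
  expect_lt(abs(rt2$log2fc[1]), 0.05)
})

test_that("nbql and wald_nb agree on effect size at large n", {
  set.seed(45)
  sim <- quick_sim(n_genes = 250, n_treatments = 1, n_reps = 10,
                   n_vehicle = 10, frac_de = 0.15, seed = 46,
                   zi_b0 = -Inf)
  scr <- filter_genes(sim$screen)
  md <- screen_metadata(scr)
  tw <- md$barcode[md$treatment == "T01"]; cw <- control_wells(scr)
  a <- de_nbql(scr, de_design(tw, cw))
  b <- de_wald_nb(scr, de_design(tw, cw))
  strong <- which(a$base_mean > 50)
  rms <- sqrt(mean((a$log2fc[strong] - b$log2fc[strong])^2))
  expect_lt(rms, 0.1)
})

test_that("weighted engines reduce to unweighted at unit weights", {
  fx <- de_fixture(seed = 5, n_genes = 200)
  ones <- matrix(1, nrow(screen_counts(fx$screen)),
                 ncol(screen_counts(fx$screen)))
  for (eng in c("nbql", "voom")) {
    plain <- de_run(eng, fx$screen, de_design(fx$tw, fx$cw))
    weighted <- de_with_weights(eng, fx$screen, de_design(fx$tw, fx$cw), ones)
    weighted$engine <- plain$engine
    expect_equal(plain, weighted, tolerance = 1e-12, label = eng)
  }
  bad <- matrix(1, 3, 3)
  expect_error(de_with_weights("voom", fx$screen,
                               de_design(fx$tw, fx$cw), bad), "dimension")
})

test_that("zero weight removes an observation's influence", {
  set.seed(47)
  m <- matrix(rnbinom(150 * 10, size = 8, mu = 200), 150, 10)
  m[3, 7] <- m[3, 7] * 50                # gross outlier: gene 3, treat well 2
  scr <- toy_screen(m, rep(c("DMSO", "A"), each = 5))
  md <- screen_metadata(scr)
  cw <- md$barcode[1:5]; tw <- md$barcode[6:10]
  W <- matrix(1, 150, 10,
              dimnames = dimnames(screen_counts(scr)))
  W[3, 7] <- 0
  plain <- de_voom(scr, de_design(tw, cw, normalisation = "cpm"))
  zeroed <- de_with_weights("voom", scr,
                            de_design(tw, cw, normalisation = "cpm"), W)
  removed <- de_voom(scr, de_design(tw[-2], cw, normalisation = "cpm"))
  # the zero-weighted estimate tracks the explicit-removal estimate ...
  expect_equal(zeroed$log2fc[3], removed$log2fc[3], tolerance = 0.1)
  # ... while the unweighted estimate is dragged far up by the outlier
  expect_gt(plain$log2fc[3] - zeroed$log2fc[3], 1)
})

test_that("ZINB weighting reduces LFC bias under planted dropout", {
  set.seed(48)
  bias_w <- c(); bias_u <- c()
  for (s in 1:12) {
    set.seed(100 + s)
    G <- 60; n1 <- 4; n2 <- 8
    lfc <- 1.5
    mu_c <- 120
    y <- cbind(matrix(rnbinom(G * n1, size = 6, mu = mu_c * 2^lfc), G, n1),
               matrix(rnbinom(G * n2, size = 6, mu = mu_c), G, n2))
    drop <- matrix(rbinom(G * (n1 + n2), 1, 0.3), G, n1 + n2)
    y <- y * (1 - drop)
    rownames(y) <- sprintf("g%03d", 1:G)
    scr <- toy_screen(y, rep(c("A", "DMSO"), c(n1, n2)))
    md <- screen_metadata(scr)
    tw <- md$barcode[1:n1]; cw <- md$barcode[-(1:n1)]
    grp <- factor(rep(c("t", "c"), c(n1, n2)))
    zw <- estimate_zinb_weights(y, size_factors = rep(1, n1 + n2),
                                grouping = grp)
    ru <- de_voom(scr, de_design(tw, cw, normalisation = "cpm"))
    rw <- de_with_weights("voom", scr,
                          de_design(tw, cw, normalisation = "cpm"),
                          zw$weights)
    bias_u <- c(bias_u, mean(ru$log2fc) - lfc)
    bias_w <- c(bias_w, mean(rw$log2fc) - lfc)
  }
  expect_lt(mean(abs(bias_w)), mean(abs(bias_u)))
})
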