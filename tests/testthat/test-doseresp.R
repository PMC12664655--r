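test_that("noiseless 4PL curves are recovered exactly", {
  doses <- 10^seq(-2, 1.5, length.out = 8)
  for (h in c(-2, -1, 1, 2)) {
    y <- fourpl(doses, lower = 0, upper = 4, h = h, ec50 = 1.0)
    ft <- fit_4pl(doses, y)
    expect_true(ft$converged)
    expect_equal(ft$ec50, 1.0, tolerance = 1e-6)
    expect_equal(ft$hill, h, tolerance = 1e-5)
    expect_equal(ft$lower, 0, tolerance = 1e-5)
    expect_equal(ft$upper, 4, tolerance = 1e-5)
    # midpoint identity y(ec50) = (lower+upper)/2
    expect_equal(fourpl(ft$ec50, ft$lower, ft$upper, ft$hill, ft$ec50),
                 (ft$lower + ft$upper) / 2, tolerance = 1e-9)
  }
})

test_that("EC50 is scale-equivariant and other parameters invariant", {
  doses <- 10^seq(-1, 2, length.out = 8)
  y <- fourpl(doses, 0.5, 3, 1.2, 4) + c(0.02, -0.01, 0.03, 0, -0.02,
                                         0.01, 0.02, -0.03)
  a <- fit_4pl(doses, y)
  for (cfac in c(10, 0.01)) {
    b <- fit_4pl(doses * cfac, y)
    expect_equal(b$ec50, a$ec50 * cfac, tolerance = 1e-6)
    expect_equal(b$hill, a$hill, tolerance = 1e-6)
    expect_equal(b$lower, a$lower, tolerance = 1e-6)
    expect_equal(b$upper, a$upper, tolerance = 1e-6)
  }
})

test_that("flat and degenerate series are flagged, not extrapolated", {
  doses <- 10^seq(-1, 2, length.out = 6)
  ft <- fit_4pl(doses, rep(2, 6))
  expect_false(ft$converged)
  expect_true(is.na(ft$ec50))
  expect_error(fit_4pl(doses[1:3], 1:3), "4 distinct")
  expect_error(fit_4pl(-doses, rep(1, 6)), "positive")
})

test_that("noisy EC50 recovery stays within tolerance", {
  doses <- 10^seq(-2, 1.5, length.out = 8)
  set.seed(81)
  rel_err <- vapply(1:50, function(i) {
    y <- fourpl(doses, 0, 3, 1, 0.5) + rnorm(8, sd = 0.2)
    ft <- fit_4pl(doses, y)
    abs(ft$ec50 - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(rel_err), 0.25)
})

test_that("fit RSS never exceeds the best grid start", {
  set.seed(82)
  doses <- 10^seq(-2, 1, length.out = 8)
  for (i in 1:20) {
    y <- fourpl(doses, rnorm(1), rnorm(1, 3), sample(c(-1, 1), 1) * runif(1, 0.3, 3),
                10^runif(1, -1.5, 0.5)) + rnorm(8, sd = 0.3)
    ft <- fit_4pl(doses, y)
    # recompute the best grid-start RSS independently
    qs <- quantile(doses, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    lo0 <- y[1]; hi0 <- y[8]
    grid_rss <- Inf
    for (h0 in c(-2, -1, -0.5, 0.5, 1, 2)) for (e0 in qs)
      grid_rss <- min(grid_rss,
                      sum((fourpl(doses, lo0, hi0, h0, e0) - y)^2))
    expect_lte(ft$rss, grid_rss + 1e-9)
  }
})

dose_sim <- function(seed = 91, n_genes = 200, ec50_range = NULL) {
  simulate_screen(sim_config(
    n_genes = n_genes, n_treatments = 0, n_reps = 3, n_vehicle = 10,
    frac_de = 0.15, seed = seed,
    dose_compounds = list(list(name = "CMPD", replicates = 3,
                               concentrations = 10^seq(-2, 1, length.out = 8),
                               ec50_range = ec50_range))))
}

test_that("gene-level profiles are monotone for responsive genes", {
  sim <- dose_sim()
  scr <- filter_genes(sim$screen, gene_filter_spec(min_count = 5))
  prof <- gene_response_profile(scr, "CMPD", engine = "trend")
  truth <- sim$truth$dose$CMPD
  # planted ramp genes whose transition lies inside the dose range, so the
  # profile actually ramps over the tested doses
  doses <- attr(prof, "doses")
  strong <- truth$gene_id[abs(truth$upper) >= 2 &
                            sim$truth$gene_means[truth$gene_id] > 30 &
                            truth$ec50 <= max(doses) / 2 &
                            truth$gene_id %in% prof$gene_id]
  rho <- vapply(strong, function(g) {
    sub <- prof[prof$gene_id == g, ]
    sgn <- sign(truth$upper[truth$gene_id == g])
    cor(sub$dose, sgn * sub$response, method = "spearman")
  }, numeric(1))
  expect_gte(median(rho), 0.9)

  # a compound with < 4 concentrations is rejected
  expect_error(gene_response_profile(scr, "nonexistent"), "4")
})

test_that("gene and pathway EC50s track the planted truth", {
  # a coherent-potency compound: all responsive genes transition within
  # [0.1, 1], so gene profiles and the pathway NES ramp inside the dose
  # span instead of saturating at the lowest dose
  sim <- dose_sim(seed = 92, n_genes = 300, ec50_range = c(0.1, 1))
  scr <- filter_genes(sim$screen, gene_filter_spec(min_count = 5))
  truth <- sim$truth$dose$CMPD
  prof <- gene_response_profile(scr, "CMPD", engine = "trend")
  strong <- truth[abs(truth$upper) >= 2 &
                    sim$truth$gene_means[truth$gene_id] > 50 &
                    truth$gene_id %in% prof$gene_id, ]
  fits <- fit_dose_profiles(prof, genes = strong$gene_id)
  ok <- fits$converged & fits$ec50_in_range
  err <- abs(log10(fits$ec50[ok] / strong$ec50[match(fits$gene_id[ok],
                                                     strong$gene_id)]))
  expect_gte(mean(err < log10(3)), 0.6)

  # pathway-level: the set of planted up-ramp genes yields an EC50 within
  # 2x of the planted gene-level median
  up <- truth$gene_id[truth$upper >= 2 &
                        sim$truth$gene_means[truth$gene_id] > 30]
  med_true <- median(truth$ec50[truth$gene_id %in% up])
  # potency scale: the mean-LFC pathway response recovers the planted
  # gene-level EC50 median
  pw <- pathway_response_profile(scr, "CMPD", sets = list(ramp = up),
                                 engine = "trend", response = "mean_lfc")
  ft <- pw$fits[pw$fits$set == "ramp", ]
  expect_true(ft$converged)
  expect_lt(abs(log10(ft$ec50 / med_true)), log10(2))
  # detection scale: the NES profile ramps with dose and fits in range,
  # with its half-max at or below the gene-level potency (NES saturates
  # once the coherent shift is detectable)
  pwn <- pathway_response_profile(scr, "CMPD", sets = list(ramp = up),
                                  engine = "trend", n_perm = 200, seed = 4)
  ftn <- pwn$fits[pwn$fits$set == "ramp", ]
  expect_true(ftn$converged)
  nes_prof <- pwn$profile$nes
  expect_gt(cor(log10(pwn$profile$dose), nes_prof, method = "spearman"), 0.5)
  expect_lte(ftn$ec50, med_true * 2)

  # null gene sets give flat, flagged fits
  nullset <- setdiff(scr$counts$gene_ids, truth$gene_id)[1:30]
  pw0 <- pathway_response_profile(scr, "CMPD", sets = list(nil = nullset),
                                  engine = "trend", n_perm = 200, seed = 4)
  ft0 <- pw0$fits[pw0$fits$set == "nil", ]
  expect_true(!ft0$converged || !ft0$ec50_in_range ||
                abs(ft0$upper - ft0$lower) < 1.5)

  # an empty set intersection errors
  expect_error(pathway_response_profile(scr, "CMPD",
                                        sets = list(x = c("nope1", "nope2"))),
               "overlap")
})
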