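#' @title Ground-truth plate simulator
#' @name sim
#' @description Generates Screens with known ground truth for testing and
#'   benchmarking: zero-inflated negative binomial counts over a plate
#'   layout with treatments, vehicle controls and dose-series compounds,
#'   planted differential-expression signatures, per-well depth variation
#'   and optional batch gradients. Deterministic given the seed.
NULL

#' Simulator configuration
#'
#' Defaults mirror a 384-well screening plate: 32 single-dose treatments
#' at 3 replicates, 19 vehicle (DMSO) wells and one dose-series compound at
#' 8 half-log concentrations with 3 replicates. Gene baselines are
#' log-normal, dispersion follows the trend `1/theta = disp_a0 + disp_a1 /
#' mu`, dropout probability follows `logit(pi) = zi_b0 - zi_b1 * log(mu +
#' 1)` (mild zero inflation at typical depths), and well library sizes are
#' log-normal.
#'
#' @param n_genes Number of genes.
#' @param plate_format 384 or 96.
#' @param n_treatments Number of single-dose treatments.
#' @param n_reps Replicates per treatment.
#' @param n_vehicle Vehicle wells.
#' @param treatment_concentration,concentration_unit Dose annotation for the
#'   single-dose treatments.
#' @param dose_compounds List of dose-series compounds, each a list with
#'   `name`, `concentrations`, `replicates`, optional `frac_responsive`,
#'   `hill`, `max_lfc_sd`, and `ec50_range` (bounds for the log-uniform
#'   true EC50 draw; default well inside the dose span). `NULL` disables;
#'   the default simulates one.
#' @param baseline_log2_mean Mean/sd of the per-gene baseline log2 mean.
#' @param disp_a0,disp_a1 Dispersion trend coefficients.
#' @param zi_b0,zi_b1 Zero-inflation trend coefficients; `zi_b0 = -Inf`
#'   disables dropout.
#' @param libsize_sd Log-normal sd of per-well size factors.
#' @param frac_de Fraction of genes differentially expressed per treatment.
#' @param lfc Planted log2 fold-change magnitude (sign random per gene) when
#'   `lfc_sd = 0`; otherwise LFCs are drawn from `Normal(0, lfc_sd)`.
#' @param lfc_sd Standard deviation for normally drawn LFCs (0 = point
#'   mass at `+-lfc`).
#' @param de_min_log2_mean Planted DE genes are drawn among genes with
#'   baseline log2 mean at or above this (so signal is estimable).
#' @param batch `NULL` or `"row_gradient"` (multiplicative log2 gradient
#'   across plate rows).
#' @param batch_sd Log2 amplitude of the row gradient.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000L, plate_format = 384L,
                       n_treatments = 32L, n_reps = 3L, n_vehicle = 19L,
                       treatment_concentration = 10, concentration_unit = "uM",
                       dose_compounds = list(list(
                         name = "CMPD_dose",
                         concentrations = 10^seq(-2.5, 1, length.out = 8),
                         replicates = 3L)),
                       baseline_log2_mean = c(mean = 3, sd = 2),
                       disp_a0 = 0.1, disp_a1 = 1,
                       zi_b0 = -2.2, zi_b1 = 0.8,
                       libsize_sd = 0.3, frac_de = 0.1, lfc = 2,
                       lfc_sd = 0, de_min_log2_mean = 1,
                       batch = NULL, batch_sd = 0.5, seed = 1L) {
  stopifnot(plate_format %in% c(96L, 384L), n_genes > 0, frac_de >= 0,
            frac_de <= 1, libsize_sd >= 0, n_vehicle >= 2)
  cfg <- as.list(environment())
  n_wells <- n_treatments * n_reps + n_vehicle +
    sum(vapply(dose_compounds %||% list(), function(d)
      length(d$concentrations) * d$replicates, numeric(1)))
  if (n_wells > plate_format)
    stop(sprintf("layout needs %d wells but the plate has %d", n_wells,
                 plate_format))
  structure(cfg, class = "sim_config")
}

plate_wells <- function(plate_format) {
  rows <- if (plate_format == 96) LETTERS[1:8] else LETTERS[1:16]
  ncols <- if (plate_format == 96) 12 else 24
  as.vector(t(outer(rows, seq_len(ncols), paste0)))
}

#' Simulate a plate screen with known truth
#'
#' Counts are drawn per gene and well as a zero-inflated NB with mean
#' `size_factor_j x mu_g x 2^lfc(treatment_j, dose_j) x batch_{g,j}`, size
#' `theta_g` and dropout probability `pi_g`. The metadata sheet carries the
#' full required column set and passes [validate_metadata()].
#'
#' @param config A [sim_config()].
#' @return List with `screen` (a `Screen`) and `truth` (`sim_truth`: per
#'   treatment the planted DE table, per dose compound the per-gene 4PL
#'   truth, per-well size factors and batch multipliers, config echo).
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$n_genes
    gene_ids <- sprintf("G%05d", seq_len(G))
    mu0 <- 2^rnorm(G, config$baseline_log2_mean[["mean"]],
                   config$baseline_log2_mean[["sd"]])
    theta <- 1 / (config$disp_a0 + config$disp_a1 / mu0)
    pi_g <- if (is.finite(config$zi_b0))
      stats::plogis(config$zi_b0 - config$zi_b1 * log(mu0 + 1))
    else rep(0, G)

    # layout ------------------------------------------------------------
    treatments <- sprintf("T%02d", seq_len(config$n_treatments))
    md <- data.frame(treatment = character(), concentration = numeric(),
                     sample_type = character(), replicate = integer())
    for (t in treatments) md <- rbind(md, data.frame(
      treatment = t, concentration = config$treatment_concentration,
      sample_type = "treatment", replicate = seq_len(config$n_reps)))
    md <- rbind(md, data.frame(
      treatment = "DMSO", concentration = 0, sample_type = "vehicle",
      replicate = seq_len(config$n_vehicle)))
    for (d in config$dose_compounds %||% list())
      for (cc in d$concentrations) md <- rbind(md, data.frame(
        treatment = d$name, concentration = cc, sample_type = "treatment",
        replicate = seq_len(d$replicates)))
    n <- nrow(md)
    md$well <- plate_wells(config$plate_format)[seq_len(n)]
    md$barcode <- sprintf("BC%04d", seq_len(n))
    md$unit <- config$concentration_unit
    md$plate <- "P1"
    md <- md[, c("barcode", "well", "treatment", "concentration", "unit",
                 "sample_type", "replicate", "plate")]

    # truth ---------------------------------------------------------------
    eligible <- which(log2(mu0) >= config$de_min_log2_mean)
    n_de <- round(config$frac_de * G)
    de_truth <- list()
    lfc_mat <- matrix(0, G, n)
    for (t in treatments) {
      picks <- sample(eligible, min(n_de, length(eligible)))
      lfcs <- if (config$lfc_sd > 0) rnorm(length(picks), 0, config$lfc_sd)
              else sample(c(-1, 1), length(picks), replace = TRUE) * config$lfc
      de_truth[[t]] <- data.frame(gene_id = gene_ids[picks], lfc = lfcs)
      cols <- which(md$treatment == t)
      lfc_mat[picks, cols] <- lfcs
    }
    dose_truth <- list()
    for (d in config$dose_compounds %||% list()) {
      fr <- d$frac_responsive %||% config$frac_de
      picks <- sample(eligible, min(round(fr * G), length(eligible)))
      upper <- (d$max_lfc_sd %||% 0)
      uppers <- if (upper > 0) rnorm(length(picks), 0, upper)
                else sample(c(-1, 1), length(picks), replace = TRUE) * config$lfc
      rng <- range(d$concentrations)
      bounds <- d$ec50_range %||% c(rng[1] * 3, rng[2] / 3)
      ec50 <- 10^runif(length(picks), log10(bounds[1]), log10(bounds[2]))
      hill <- rep(d$hill %||% 1, length(picks))
      dose_truth[[d$name]] <- data.frame(gene_id = gene_ids[picks],
                                         lower = 0, upper = uppers,
                                         hill = hill, ec50 = ec50)
      for (cc in d$concentrations) {
        cols <- which(md$treatment == d$name & md$concentration == cc)
        lfc_mat[picks, cols] <- fourpl(cc, 0, uppers, hill, ec50)
      }
    }

    sf <- rlnorm(n, 0, config$libsize_sd)
    batch_mult <- matrix(1, G, n)
    if (identical(config$batch, "row_gradient")) {
      row_idx <- match(substr(md$well, 1, 1), LETTERS)
      grad <- (row_idx - mean(row_idx)) / max(abs(row_idx - mean(row_idx)))
      affected <- sample(G, round(G / 2))
      batch_mult[affected, ] <- 2^outer(rep(config$batch_sd, length(affected)),
                                        grad)
    }

    mean_mat <- (mu0 * 2^lfc_mat) * batch_mult * rep(sf, each = G)
    counts <- matrix(rnbinom(G * n, size = theta, mu = mean_mat), G, n)
    if (any(pi_g > 0)) {
      drop <- matrix(rbinom(G * n, 1, pi_g), G, n)
      counts[drop == 1] <- 0
    }
    dimnames(counts) <- list(gene_ids, md$barcode)

    cm <- count_matrix(counts, gene_ids = gene_ids, barcodes = md$barcode)
    class(md) <- c("plate_metadata", "data.frame")
    scr <- assemble_screen(cm, md)
    scr$provenance <- c(sprintf("simulate_screen: seed=%d", config$seed),
                        scr$provenance)
    truth <- structure(list(de = de_truth, dose = dose_truth,
                            size_factors = setNames(sf, md$barcode),
                            gene_means = setNames(mu0, gene_ids),
                            theta = setNames(theta, gene_ids),
                            pi = setNames(pi_g, gene_ids),
                            batch = config$batch, config = config),
                       class = "sim_truth")
    list(screen = scr, truth = truth)
  })
}

#' Write a simulated screen as a fixture directory
#'
#' Emits the MatrixMarket triplet, the metadata TSV and the ground truth
#' as JSON; [read_count_triplet()] / [read_metadata()] round-trip the
#' files exactly.
#'
#' @param screen A `Screen`.
#' @param truth A `sim_truth` (optional; skipped when `NULL`).
#' @param directory Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return `directory`, invisibly.
#' @export
write_fixture <- function(screen, truth, directory, overwrite = FALSE) {
  if (dir.exists(directory) && !overwrite &&
      length(list.files(directory)))
    stop(sprintf("directory '%s' exists; set overwrite = TRUE", directory))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_count_triplet(screen$counts, directory)
  write_metadata(screen$metadata, file.path(directory, "metadata.tsv"))
  if (!is.null(truth)) {
    tr <- truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(unclass(tr), file.path(directory, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(directory)
}

#' Read a fixture directory back into a Screen
#'
#' @param directory A [write_fixture()] directory.
#' @return A `Screen`.
#' @export
read_fixture <- function(directory) {
  cm <- read_count_triplet(directory)
  md <- read_metadata(file.path(directory, "metadata.tsv"))
  assemble_screen(cm, md)
}
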