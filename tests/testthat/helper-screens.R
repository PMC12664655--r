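# Fixture builders used across test files. Everything is generated in code.

# Build a Screen from a bare count matrix and a treatment label per well.
toy_screen <- function(counts, treatments,
                       concentrations = ifelse(treatments == "DMSO", 0, 10)) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  gene_ids <- rownames(counts) %||% sprintf("G%03d", seq_len(nrow(counts)))
  barcodes <- colnames(counts) %||% sprintf("BC%03d", seq_len(n))
  rownames(counts) <- gene_ids; colnames(counts) <- barcodes
  reps <- stats::ave(seq_len(n), paste(treatments, concentrations),
                     FUN = seq_along)
  md <- data.frame(
    barcode = barcodes,
    well = platetx:::plate_wells(384)[seq_len(n)],
    treatment = treatments,
    concentration = concentrations,
    unit = "uM",
    sample_type = ifelse(treatments == "DMSO", "vehicle", "treatment"),
    replicate = reps,
    plate = "P1")
  class(md) <- c("plate_metadata", "data.frame")
  assemble_screen(count_matrix(counts, gene_ids = gene_ids,
                               barcodes = barcodes), md)
}

# Small simulated screen: few treatments, no dose compound, fast.
quick_sim <- function(n_genes = 400, n_treatments = 2, n_reps = 3,
                      n_vehicle = 19, frac_de = 0.1, seed = 1, ...) {
  simulate_screen(sim_config(
    n_genes = n_genes, n_treatments = n_treatments, n_reps = n_reps,
    n_vehicle = n_vehicle, frac_de = frac_de, dose_compounds = NULL,
    seed = seed, ...))
}

# NB count matrix with planted group structure, no simulator involvement.
nb_matrix <- function(n_genes, n_wells, mu = 50, theta = 5, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(matrix(rnbinom(n_genes * n_wells, size = theta, mu = mu),
                    n_genes, n_wells,
                    dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                    sprintf("W%02d", seq_len(n_wells)))))
}
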