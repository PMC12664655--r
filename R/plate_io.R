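#' @title Count matrices, plate metadata and Screen objects
#' @name plate_io
#' @description Readers, writers and validators for the two plate-level
#'   inputs — a sparse gene-by-well count matrix (MatrixMarket triplet plus
#'   feature and barcode tables, as emitted by Cell Ranger or STARsolo) and a
#'   delimited plate metadata sheet — and the `Screen` container that joins
#'   them by well barcode.
NULL

#' Required metadata columns
#'
#' The minimal column set a plate metadata sheet must provide (after synonym
#' mapping): `barcode`, `well`, `treatment`, `concentration`, `unit`,
#' `sample_type`, `replicate`, `plate`.
#'
#' @return Character vector of canonical column names.
#' @export
required_metadata_columns <- function() {
  c("barcode", "well", "treatment", "concentration", "unit",
    "sample_type", "replicate", "plate")
}

#' Default metadata column synonyms
#'
#' Named character vector mapping foreign header names (matched
#' case-insensitively) to canonical column names. Users extend it via the
#' `synonyms` argument of [read_metadata()].
#'
#' @return Named character vector (`foreign = canonical`).
#' @export
default_metadata_synonyms <- function() {
  c(sample_barcode = "barcode", cell_barcode = "barcode",
    well_id = "well", well_position = "well",
    compound = "treatment", drug = "treatment", perturbation = "treatment",
    conc = "concentration", dose = "concentration",
    concentration_unit = "unit", dose_unit = "unit",
    type = "sample_type", well_type = "sample_type",
    rep = "replicate", replicate_id = "replicate",
    plate_id = "plate", plate_barcode = "plate")
}

#' Construct a count matrix
#'
#' @param values Integer matrix, genes in rows, wells in columns.
#' @param gene_ids Unique gene identifiers (rownames).
#' @param gene_names Display symbols, may repeat; defaults to `gene_ids`.
#' @param barcodes Unique well barcodes (colnames).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(values, gene_ids, gene_names = gene_ids, barcodes) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("counts must be non-negative")
  if (any(values != round(values))) stop("counts must be integral")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(barcodes))
    stop("dimension mismatch between values, gene_ids and barcodes")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, barcodes)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 gene_names = as.character(gene_names),
                 barcodes = as.character(barcodes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d wells (%.1f%% zeros)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$values == 0)))
  invisible(x)
}

triplet_file <- function(directory, stems, gzipped) {
  exts <- if (isTRUE(gzipped)) ".gz" else if (identical(gzipped, FALSE)) ""
          else c("", ".gz")
  for (stem in stems) for (e in exts) {
    f <- file.path(directory, paste0(stem, e))
    if (file.exists(f)) return(f)
  }
  stop(sprintf("missing file: none of %s found in '%s'",
               paste(stems, collapse = "/"), directory), call. = FALSE)
}

#' Read a sparse count triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` (or `genes.tsv`; 2- or 3-column
#' accepted, any type column ignored) and `barcodes.tsv`, each optionally
#' gzipped, and reconstructs the dense count matrix.
#'
#' @param directory Directory containing the three files.
#' @param gzipped `TRUE`, `FALSE`, or `NA` to auto-detect per file.
#' @return A [count_matrix()].
#' @export
read_count_triplet <- function(directory, gzipped = NA) {
  if (!dir.exists(directory))
    stop(sprintf("missing file: directory '%s' does not exist", directory))
  mf <- triplet_file(directory, "matrix.mtx", gzipped)
  ff <- triplet_file(directory, c("features.tsv", "genes.tsv"), gzipped)
  bf <- triplet_file(directory, "barcodes.tsv", gzipped)
  # readMM only warns when the header promises more entries than the file
  # holds; both warnings and errors here are format errors
  m <- tryCatch(Matrix::readMM(mf),
                error = function(e) stop(sprintf(
                  "format error reading '%s': %s", mf, conditionMessage(e)),
                  call. = FALSE),
                warning = function(w) stop(sprintf(
                  "format error reading '%s': %s", mf, conditionMessage(w)),
                  call. = FALSE))
  m <- as.matrix(m)
  if (any(m != round(m)))
    stop(sprintf("format error: non-integer value in '%s'", mf))
  feats <- read.delim(ff, header = FALSE, colClasses = "character")
  if (ncol(feats) < 1) stop(sprintf("format error: empty features file '%s'", ff))
  bcs <- read.delim(bf, header = FALSE, colClasses = "character")[[1]]
  if (nrow(feats) != nrow(m))
    stop(sprintf("format error: %d features but %d matrix rows", nrow(feats), nrow(m)))
  if (length(bcs) != ncol(m))
    stop(sprintf("format error: %d barcodes but %d matrix columns", length(bcs), ncol(m)))
  gene_names <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  count_matrix(m, gene_ids = feats[[1]], gene_names = gene_names, barcodes = bcs)
}

#' Write a count matrix as a sparse triplet directory
#'
#' Inverse of [read_count_triplet()]; the round trip is exact.
#'
#' @param cm A [count_matrix()].
#' @param directory Output directory (created if absent).
#' @param gzipped Compress the three files.
#' @return `directory`, invisibly.
#' @export
write_count_triplet <- function(cm, directory, gzipped = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(cm$values, sparse = TRUE), "generalMatrix")
  mf <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(sp, mf)
  feats <- data.frame(cm$gene_ids, cm$gene_names, "Gene Expression")
  ff <- file.path(directory, "features.tsv")
  write.table(feats, ff, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bf <- file.path(directory, "barcodes.tsv")
  writeLines(cm$barcodes, bf)
  if (gzipped) for (f in c(mf, ff, bf)) gzip_file(f)
  invisible(directory)
}

gzip_file <- function(path) {
  con <- gzfile(paste0(path, ".gz"), "wb")
  writeBin(readBin(path, "raw", file.size(path)), con)
  close(con)
  unlink(path)
}

#' Read a plate metadata sheet
#'
#' Reads a delimited metadata sheet, maps required columns case-insensitively
#' through a synonym table and checks the schema (required columns present,
#' barcodes unique). Extra columns are preserved verbatim.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param synonyms Named character vector mapping foreign header names to
#'   canonical names; merged over [default_metadata_synonyms()].
#' @param required Required canonical columns.
#' @return A `data.frame` of class `plate_metadata`.
#' @export
read_metadata <- function(path, dialect = c("auto", "csv", "tsv"),
                          synonyms = NULL,
                          required = required_metadata_columns()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("missing file: '%s'", path))
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  df <- if (dialect == "csv") read.csv(path, check.names = FALSE)
        else read.delim(path, check.names = FALSE)
  syn <- default_metadata_synonyms()
  if (!is.null(synonyms)) syn[tolower(names(synonyms))] <- unname(synonyms)
  names(syn) <- tolower(names(syn))
  nm <- names(df)
  lower <- tolower(nm)
  canon <- ifelse(lower %in% required, lower,
                  ifelse(lower %in% names(syn), syn[lower], nm))
  dup <- canon[duplicated(canon) & canon %in% required]
  if (length(dup))
    stop(sprintf("schema error: columns map to the same canonical name: %s",
                 paste(unique(dup), collapse = ", ")))
  names(df) <- canon
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if ("concentration" %in% names(df))
    df$concentration <- as.numeric(df$concentration)
  if ("replicate" %in% names(df))
    df$replicate <- as.integer(df$replicate)
  df$barcode <- as.character(df$barcode)
  if (anyDuplicated(df$barcode))
    stop(sprintf("schema error: duplicate barcode(s): %s",
                 paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", ")))
  class(df) <- c("plate_metadata", "data.frame")
  df
}

#' Write a plate metadata sheet
#' @param meta Metadata `data.frame`.
#' @param path Output path; dialect by extension (`.csv` else TSV).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(meta, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonicalise a well coordinate: "A01" -> "A1". Returns NA for unparsable
# or out-of-range coordinates for the declared plate format.
canonical_well <- function(well, plate_format = 384) {
  rows <- if (plate_format == 96) LETTERS[1:8] else LETTERS[1:16]
  ncol_max <- if (plate_format == 96) 12 else 24
  m <- regmatches(well, regexec("^([A-Pa-p])0*([0-9]+)$", as.character(well)))
  vapply(m, function(p) {
    if (length(p) != 3) return(NA_character_)
    r <- toupper(p[2]); cnum <- as.integer(p[3])
    if (!(r %in% rows) || is.na(cnum) || cnum < 1 || cnum > ncol_max)
      return(NA_character_)
    paste0(r, cnum)
  }, character(1))
}

#' Validate plate metadata
#'
#' Applies the rule set for screen metadata sheets: no missing values in
#' required columns, identifier columns restricted to a character whitelist,
#' valid well coordinates for the declared plate format, non-negative
#' concentrations and unique (plate, well) pairs. Warns on treatment groups
#' with a single replicate and on unbalanced replicate counts.
#'
#' @param meta Metadata from [read_metadata()] (or any conforming
#'   `data.frame`).
#' @param plate_format 384 (rows A-P, columns 1-24) or 96 (A-H, 1-12).
#' @param id_cols Columns subject to the identifier whitelist.
#' @param whitelist Regular-expression character class of allowed identifier
#'   characters.
#' @param required Required columns checked for missingness.
#' @return A `validation_report`: list with `errors` and `warnings` data
#'   frames (`row`, `column`, `rule`, `message`) and a `passed` flag
#'   (`TRUE` iff no errors).
#' @export
validate_metadata <- function(meta, plate_format = 384,
                              id_cols = c("barcode", "treatment", "plate"),
                              whitelist = "[A-Za-z0-9._-]",
                              required = required_metadata_columns()) {
  err <- list(); wrn <- list()
  add <- function(store, row, column, rule, message)
    c(store, list(data.frame(row = row, column = column, rule = rule,
                             message = message)))
  for (col in intersect(required, names(meta))) {
    v <- meta[[col]]
    bad <- which(is.na(v) | (is.character(v) & !nzchar(v)))
    for (i in bad)
      err <- add(err, i, col, "missing_value",
                 sprintf("missing value in required column '%s'", col))
  }
  pat <- sprintf("[^%s]", sub("^\\[(.*)\\]$", "\\1", whitelist))
  for (col in intersect(id_cols, names(meta))) {
    v <- as.character(meta[[col]])
    bad <- which(!is.na(v) & grepl(pat, v))
    for (i in bad) {
      chars <- unique(strsplit(gsub(sprintf("%s", whitelist), "", v[i]), "")[[1]])
      err <- add(err, i, col, "special_characters",
                 sprintf("'%s' contains disallowed character(s): %s",
                         v[i], paste(chars, collapse = " ")))
    }
  }
  if ("well" %in% names(meta)) {
    cw <- canonical_well(meta$well, plate_format)
    for (i in which(is.na(cw) & !is.na(meta$well)))
      err <- add(err, i, "well", "invalid_well",
                 sprintf("'%s' is not a valid %d-well coordinate",
                         meta$well[i], plate_format))
    if ("plate" %in% names(meta)) {
      key <- paste(meta$plate, cw)
      dups <- which(duplicated(key) & !is.na(cw))
      for (i in dups)
        err <- add(err, i, "well", "duplicate_well",
                   sprintf("duplicate (plate, well) pair: (%s, %s)",
                           meta$plate[i], cw[i]))
    }
  }
  if ("concentration" %in% names(meta)) {
    for (i in which(!is.na(meta$concentration) & meta$concentration < 0))
      err <- add(err, i, "concentration", "negative_concentration",
                 sprintf("negative concentration %g", meta$concentration[i]))
  }
  if (all(c("treatment", "concentration") %in% names(meta))) {
    grp <- paste(meta$treatment, meta$concentration)
    tab <- table(grp)
    singles <- names(tab)[tab == 1]
    for (g in singles)
      wrn <- add(wrn, NA_integer_, "treatment", "single_replicate",
                 sprintf("group '%s' has a single replicate", g))
    if (length(unique(tab)) > 1)
      wrn <- add(wrn, NA_integer_, "treatment", "unbalanced_replicates",
                 sprintf("replicate counts range from %d to %d across groups",
                         min(tab), max(tab)))
  }
  empty <- data.frame(row = integer(), column = character(),
                      rule = character(), message = character())
  errors <- if (length(err)) do.call(rbind, err) else empty
  warnings <- if (length(wrn)) do.call(rbind, wrn) else empty
  structure(list(errors = errors, warnings = warnings,
                 passed = nrow(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation %s: %d error(s), %d warning(s)\n",
              if (x$passed) "PASSED" else "FAILED",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(head(x$errors, 20))
  invisible(x)
}

#' Write a validation report as JSON
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(list(passed = report$passed, errors = report$errors,
                            warnings = report$warnings),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Join counts and metadata into a Screen
#'
#' Matches count-matrix columns to metadata rows by barcode and reorders the
#' counts to the metadata order. With `drop_unmatched`, barcodes present on
#' only one side are removed with a warning; otherwise any mismatch is an
#' error.
#'
#' @param counts A [count_matrix()].
#' @param meta Plate metadata.
#' @param drop_unmatched Drop one-sided barcodes instead of failing.
#' @return A `Screen`: list with `counts`, `metadata` and an append-only
#'   `provenance` log.
#' @export
assemble_screen <- function(counts, meta, drop_unmatched = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  common <- intersect(meta$barcode, counts$barcodes)
  if (length(common) == 0L)
    stop("no overlap between count-matrix barcodes and metadata barcodes")
  extra_c <- setdiff(counts$barcodes, meta$barcode)
  extra_m <- setdiff(meta$barcode, counts$barcodes)
  prov <- character()
  if (length(extra_c) || length(extra_m)) {
    if (!drop_unmatched)
      stop(sprintf(paste0("barcode mismatch: %d count-only, %d metadata-only ",
                          "barcodes (set drop_unmatched = TRUE to keep the ",
                          "intersection)"), length(extra_c), length(extra_m)))
    warning(sprintf("dropping %d unmatched barcode(s)",
                    length(extra_c) + length(extra_m)))
    prov <- sprintf("assemble_screen: dropped %d unmatched barcode(s)",
                    length(extra_c) + length(extra_m))
  }
  meta <- meta[meta$barcode %in% common, , drop = FALSE]
  rownames(meta) <- NULL
  idx <- match(meta$barcode, counts$barcodes)
  cm <- count_matrix(counts$values[, idx, drop = FALSE],
                     gene_ids = counts$gene_ids,
                     gene_names = counts$gene_names,
                     barcodes = counts$barcodes[idx])
  structure(list(counts = cm, metadata = meta,
                 provenance = c(prov,
                                sprintf("assemble_screen: %d genes x %d wells",
                                        nrow(cm$values), ncol(cm$values)))),
            class = "Screen")
}

#' @export
print.Screen <- function(x, ...) {
  cat(sprintf("Screen: %d genes x %d wells, %d treatment group(s)\n",
              nrow(x$counts$values), ncol(x$counts$values),
              length(unique(paste(x$metadata$treatment,
                                  x$metadata$concentration)))))
  cat("provenance:\n")
  for (p in x$provenance) cat(" -", p, "\n")
  invisible(x)
}

#' Raw count matrix of a Screen
#' @param screen A `Screen`.
#' @return Numeric matrix, genes x wells, with dimnames.
#' @export
screen_counts <- function(screen) screen$counts$values

#' Metadata of a Screen
#' @param screen A `Screen`.
#' @return The metadata `data.frame`, rows aligned with count columns.
#' @export
screen_metadata <- function(screen) screen$metadata

#' Resolve vehicle-control wells
#'
#' The `sample_type` column is authoritative (`"vehicle"` wells); when it
#' identifies none, wells whose treatment name matches `control_label`
#' case-insensitively are used.
#'
#' @param screen A `Screen`.
#' @param control_label Fallback vehicle treatment name.
#' @return Character vector of control well barcodes.
#' @export
control_wells <- function(screen, control_label = "DMSO") {
  md <- screen$metadata
  if ("sample_type" %in% names(md) && any(md$sample_type == "vehicle"))
    return(md$barcode[md$sample_type == "vehicle"])
  md$barcode[tolower(md$treatment) == tolower(control_label)]
}
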