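#' Read and write count matrices
#'
#' Counts travel as TSV (first column `gene_id`, one column per sample) or
#' as MatrixMarket (`.mtx` with `.rows` / `.cols` sidecar files holding the
#' gene and sample ids, one per line). Both encodings of the same matrix
#' parse to identical objects. Entries must be non-negative integers;
#' offending cells are reported by gene and sample.
#'
#' @param path File path. For `format = "mtx"` the sidecars are
#'   `<path>.rows` and `<path>.cols`.
#' @param format `"tsv"` or `"mtx"`.
#' @return `read_counts()`: an integer matrix with dimnames;
#'   `write_counts()`: the path, invisibly.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "gene_id") stopf("first TSV column must be 'gene_id'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(mm) || length(cols) != ncol(mm))
      stopf("sidecar id files do not match the matrix dimensions")
    dimnames(mm) <- list(rows, cols)
    m <- mm
  }
  if (anyDuplicated(rownames(m))) stopf("duplicate gene ids in %s", path)
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("invalid count at gene '%s', sample '%s': %s",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
          format(m[bad[1, , drop = FALSE]]))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read and write tabular artifacts (samples, truth, diameters, contrasts)
#'
#' Thin TSV helpers: tab-separated, UTF-8, `.` decimal separator, header
#' row mandatory. `read_samples()` validates the sample table,
#' `read_diameters()` the two-column diameter table.
#'
#' @param path File path.
#' @param df Data frame to write.
#' @return Readers return a `data.frame`; writers the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname write_tsv
#' @export
read_samples <- function(path) {
  check_design(read_tsv(path))
}

#' @rdname write_tsv
#' @export
read_diameters <- function(path) {
  check_diameters(read_tsv(path))
}

#' Run configuration for the end-to-end report
#'
#' Thresholds are entered as linear fold changes (1.5, 17) and converted to
#' log2 internally. `run_config()` builds a validated configuration;
#' `read_run_config()` loads one from YAML (unknown keys rejected, missing
#' keys defaulted).
#'
#' @param seed Integer master seed for the whole report.
#' @param organ `"KIDNEY"` or `"LIVER"`.
#' @param fold_change Linear fold-change threshold (> 1), default 1.5.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param extreme_fold Linear extreme-region bound (> 1), default 17.
#' @param min_total Gene filter threshold, default 10.
#' @param pseudocount Normalization offset, default 1.
#' @param n_genes,n_per_group Simulation size, defaults 4000 and 5.
#' @param diameters_per_stratum Measurements per stratum for the
#'   morphometry block, default `1e5`.
#' @param subset_sizes Subsampling sizes, default `c(1e4, 1e3)`.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, organ = "KIDNEY",
                       fold_change = 1.5, alpha = 0.05, extreme_fold = 17,
                       min_total = 10L, pseudocount = 1,
                       n_genes = 4000L, n_per_group = 5L,
                       diameters_per_stratum = 1e5, subset_sizes = c(1e4, 1e3)) {
  if (!is.numeric(fold_change) || fold_change <= 1)
    stopf("'fold_change' must be a linear fold change > 1")
  if (!is.numeric(extreme_fold) || extreme_fold <= 1)
    stopf("'extreme_fold' must be a linear fold change > 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must lie in (0, 1)")
  if (any(subset_sizes > diameters_per_stratum))
    stopf("'subset_sizes' cannot exceed 'diameters_per_stratum'")
  structure(list(
    seed = as.integer(seed), organ = organ,
    fold_change = fold_change, alpha = alpha, extreme_fold = extreme_fold,
    min_total = as.integer(min_total), pseudocount = pseudocount,
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    diameters_per_stratum = as.integer(diameters_per_stratum),
    subset_sizes = as.integer(subset_sizes)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg A `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
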