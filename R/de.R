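#' Filter low-count genes
#'
#' Keeps genes whose total count across samples reaches `min_total`,
#' preserving gene order. An empty result is allowed (with a warning), since
#' downstream code treats the gene universe as data.
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param min_total Minimum row sum, default 10.
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_total = 10L) {
  check_counts(counts)
  if (min_total < 0) stopf("'min_total' must be >= 0")
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) warnf("no gene passes min_total = %s", format(min_total))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the median-of-ratios
#' convention: for each sample, the median over reference genes of the ratio
#' of its count to the gene's geometric mean across samples. Only genes with
#' strictly positive counts in every sample form the reference. If no such
#' gene exists the function falls back to total-count ratios (sample total
#' over the geometric mean of totals) with a warning.
#'
#' @param counts Integer matrix, genes x samples.
#' @return A positive numeric vector, one factor per sample, named by
#'   sample.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(20, 40))
#' size_factors(m)   # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts) {
  check_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    warnf("no gene has all-positive counts; falling back to total-count ratios")
    tot <- colSums(counts)
    if (any(tot == 0)) stopf("cannot compute size factors: sample(s) with zero total counts")
    f <- tot / exp(mean(log(tot)))
  } else {
    refc <- counts[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(refc)))
    f <- apply(refc / geo, 2L, stats::median)
  }
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 normalization of counts
#'
#' Divides each sample by its size factor and takes
#' `log2(count / factor + pseudocount)`. With the default pseudocount of 1,
#' zero counts map to 0 and the matrix is finite everywhere.
#'
#' @param counts Integer matrix, genes x samples.
#' @param factors Positive per-sample factors, as from [size_factors()].
#' @param pseudocount Positive offset, default 1.
#' @return A numeric matrix of log2 normalized expression, same dimnames.
#' @export
normalize_log2 <- function(counts, factors = size_factors(counts), pseudocount = 1) {
  check_counts(counts)
  if (length(factors) != ncol(counts))
    stopf("'factors' must have one entry per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stopf("size factors must be finite and positive")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stopf("'pseudocount' must be > 0")
  log2(sweep(counts, 2L, factors, "/") + pseudocount)
}

#' Per-gene two-group contrast (Welch's t)
#'
#' For every gene, computes the mean log2 expression difference
#' (`group_b` minus `group_a`), a Welch two-sample t-test p-value, and the
#' Benjamini–Hochberg adjusted p-value across all tested genes. Degenerate
#' genes with zero variance in both groups get p = 1 when the means are
#' equal and the smallest positive double when they differ.
#'
#' @param em Log2 expression matrix, genes x samples (from
#'   [normalize_log2()]).
#' @param design Sample table with `sample_id` and `arm` columns covering
#'   the columns of `em`.
#' @param group_a,group_b Arm labels; the reported `log2fc` is
#'   `mean(group_b) - mean(group_a)` so that `group_a` is the reference
#'   (for a disease contrast, `group_a = "SHAM_VEH"`).
#' @return A `data.frame` with `gene_id`, `log2fc`, `p_raw`, `p_adj`.
#' @export
test_contrast <- function(em, design, group_a, group_b) {
  check_design(design)
  design <- design[design$sample_id %in% colnames(em), , drop = FALSE]
  ids_a <- design$sample_id[design$arm == group_a]
  ids_b <- design$sample_id[design$arm == group_b]
  if (length(ids_a) == 0L) stopf("unknown or absent group label '%s'", group_a)
  if (length(ids_b) == 0L) stopf("unknown or absent group label '%s'", group_b)
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stopf("each group needs >= 2 samples (got %d and %d)",
          length(ids_a), length(ids_b))

  xa <- em[, ids_a, drop = FALSE]
  xb <- em[, ids_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)

  se2 <- va / na + vb / nb
  lfc <- mb - ma
  p <- rep(NA_real_, nrow(em))
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, .Machine$double.xmin)
  ok <- !degen
  if (any(ok)) {
    tstat <- lfc[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
    p[ok] <- 2 * stats::pt(-abs(tstat), df = df)
  }
  data.frame(gene_id = rownames(em), log2fc = as.numeric(lfc),
             p_raw = p, p_adj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Volcano classification of a contrast
#'
#' Labels each gene `up`, `down`, or `ns` against a fold-change band and a
#' significance cut: `up` when `log2fc >= tau` and p < `alpha`, `down` when
#' `log2fc <= -tau` and p < `alpha`, `ns` otherwise. The defaults mirror
#' the usual volcano-plot guides: `tau = log2(1.5)` and `alpha = 0.05`
#' applied to the BH-adjusted p-value (set `use = "p_raw"` for the raw one).
#'
#' @param cr Contrast result from [test_contrast()].
#' @param tau Positive log2 fold-change threshold.
#' @param alpha Significance level in (0, 1).
#' @param use Which p-value column gates significance, `"p_adj"` (default)
#'   or `"p_raw"`.
#' @return A list with `labels` (factor `up`/`down`/`ns`, one per gene,
#'   named by gene) and `summary`, a `volcano_summary` list with counts
#'   `n_up`, `n_down`, `n_ns` and the thresholds used. The three counts
#'   always partition the tested genes.
#' @export
classify_volcano <- function(cr, tau = default_tau(), alpha = 0.05,
                             use = c("p_adj", "p_raw")) {
  use <- match.arg(use)
  if (!is.numeric(tau) || tau <= 0) stopf("'tau' must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("'alpha' must lie in (0, 1)")
  p <- cr[[use]]
  lab <- rep("ns", nrow(cr))
  lab[cr$log2fc >= tau & p < alpha] <- "up"
  lab[cr$log2fc <= -tau & p < alpha] <- "down"
  labels <- factor(lab, levels = c("up", "down", "ns"))
  names(labels) <- cr$gene_id
  summary <- structure(list(
    n_up = sum(labels == "up"), n_down = sum(labels == "down"),
    n_ns = sum(labels == "ns"), n_tested = nrow(cr),
    fc_threshold = tau, alpha = alpha, p_column = use
  ), class = "volcano_summary")
  list(labels = labels, summary = summary)
}

#' @export
print.volcano_summary <- function(x, ...) {
  cat(sprintf(
    "volcano summary: %d up, %d down, %d ns of %d genes (|log2FC| >= %.3f, %s < %g)\n",
    x$n_up, x$n_down, x$n_ns, x$n_tested, x$fc_threshold, x$p_column, x$alpha))
  invisible(x)
}

#' PCA summary of an expression matrix
#'
#' Runs a principal component analysis of the samples on the
#' `n_top` highest-variance genes (centered, optionally unit-scaled) and
#' returns the first two sample coordinates plus the explained-variance
#' fractions of all components.
#'
#' @param em Log2 expression matrix, genes x samples, at least 3 samples.
#' @param n_top Number of top-variance genes, clamped to the gene count
#'   with a warning; default 500.
#' @param scale. Unit-scale gene rows before the rotation; default `FALSE`.
#' @return A list with `coords` (`data.frame`: `sample_id`, `PC1`, `PC2`)
#'   and `explained` (variance fractions, non-increasing, summing to <= 1).
#' @export
pca_summary <- function(em, n_top = 500L, scale. = FALSE) {
  if (ncol(em) < 3L) stopf("PCA needs >= 3 samples")
  n_top <- as.integer(n_top)
  if (n_top > nrow(em)) {
    warnf("n_top = %d exceeds the %d available genes; using all genes",
          n_top, nrow(em))
    n_top <- nrow(em)
  }
  v <- apply(em, 1L, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  sub <- em[top, , drop = FALSE]
  if (scale.) sub <- sub[apply(sub, 1L, stats::var) > 0, , drop = FALSE]
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    coords = data.frame(sample_id = colnames(em),
                        PC1 = pc$x[, 1L],
                        PC2 = if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0,
                        row.names = NULL, stringsAsFactors = FALSE),
    explained = expl
  )
}

# shared validation of a count matrix
check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("'counts' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("'counts' needs unique rownames (gene ids)")
  if (any(counts < 0)) stopf("'counts' contains negative entries")
  invisible(counts)
}
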