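test_that("filter_genes keeps rows by total count, order preserved", {
  m <- rbind(a = c(0, 0), b = c(4, 5), c = c(5, 5))
  expect_identical(filter_genes(m, 0), m)
  expect_identical(rownames(filter_genes(m, 10)), "c")   # sums 0, 9, 10
  expect_warning(out <- filter_genes(m, 100), "no gene")
  expect_equal(nrow(out), 0L)

  set.seed(1)
  r <- matrix(rnbinom(50 * 12, mu = 5, size = 1), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  kept <- filter_genes(r, 40)
  # brute-force oracle: scan row sums one by one
  keep_oracle <- vapply(seq_len(nrow(r)), function(i) sum(r[i, ]) >= 40, logical(1))
  expect_identical(rownames(kept), rownames(r)[keep_oracle])
})

test_that("size_factors follows the median-of-ratios formula", {
  m <- rbind(g1 = c(5, 5), g2 = c(9, 9))
  expect_equal(unname(size_factors(m)), c(1, 1))

  doubled <- rbind(g1 = c(10, 20), g2 = c(20, 40))
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)

  # genes with zeros are excluded from the reference
  with_zero <- rbind(g1 = c(10, 20), g2 = c(20, 40), g3 = c(0, 1000))
  expect_equal(unname(size_factors(with_zero)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)

  all_zero_ref <- rbind(g1 = c(0, 4), g2 = c(6, 0))
  expect_warning(f <- size_factors(all_zero_ref), "total-count")
  expect_equal(unname(f), c(6, 4) / exp(mean(log(c(6, 4)))))
})

test_that("size_factors equals an independent per-gene loop (and DESeq2)", {
  set.seed(5)
  # odd gene count keeps the reference median interpolation-free, so the
  # raw-ratio and log-ratio median conventions coincide exactly
  m <- matrix(rnbinom(51 * 12, mu = 50, size = 2) + 1L, 51, 12,
              dimnames = list(sprintf("g%02d", 1:51), sprintf("s%02d", 1:12)))
  f <- size_factors(m)

  # naive oracle: explicit loops over genes and samples
  geo <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) geo[i] <- prod(m[i, ]^(1 / ncol(m)))
  oracle <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(0)
    for (i in seq_len(nrow(m)))
      if (all(m[i, ] > 0)) ratios <- c(ratios, m[i, j] / geo[i])
    oracle[j] <- median(ratios)
  }
  expect_equal(unname(f), oracle, tolerance = 1e-10)
  expect_equal(unname(f), unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("normalize_log2 maps counts to finite log2 expression", {
  m <- rbind(g = c(0L, 7L)); colnames(m) <- c("a", "b")
  em <- normalize_log2(m, factors = c(1, 1), pseudocount = 1)
  expect_equal(unname(em[1, ]), c(0, 3))    # log2(0+1), log2(7+1)

  set.seed(2)
  r <- matrix(rnbinom(30 * 6, mu = 20, size = 2), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  f <- size_factors(r)
  expect_equal(normalize_log2(2L * r, 2 * f), normalize_log2(r, f))
  expect_true(all(is.finite(normalize_log2(r, f))))
  expect_error(normalize_log2(r, rep(0, 6)), "positive")
  expect_error(normalize_log2(r, f, pseudocount = 0), "pseudocount")
})

test_that("test_contrast matches a per-gene Welch t.test loop", {
  set.seed(8)
  em <- matrix(rnorm(50 * 12, mean = 6), 50, 12,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  design <- data.frame(sample_id = colnames(em),
                       arm = rep(c("SHAM_VEH", "BDL_VEH"), each = 6),
                       stage = "S1", stringsAsFactors = FALSE)
  cr <- test_contrast(em, design, "SHAM_VEH", "BDL_VEH")

  for (i in c(1, 10, 25, 50)) {
    tt <- t.test(em[i, 7:12], em[i, 1:6], var.equal = FALSE)
    expect_equal(cr$log2fc[i], unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-10)
    expect_equal(cr$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
  p_oracle <- vapply(seq_len(nrow(em)), function(i)
    t.test(em[i, 7:12], em[i, 1:6])$p.value, numeric(1))
  expect_equal(cr$p_raw, p_oracle, tolerance = 1e-10)
  expect_equal(cr$p_adj, p.adjust(p_oracle, "BH"), tolerance = 1e-10)
})

test_that("test_contrast honors the degenerate and error contracts", {
  em <- rbind(flat = rep(5, 8), shift = rep(c(1, 2), each = 4))
  colnames(em) <- sprintf("s%d", 1:8)
  design <- data.frame(sample_id = colnames(em),
                       arm = rep(c("A", "B"), each = 4), stage = "S1",
                       stringsAsFactors = FALSE)
  cr <- test_contrast(em, design, "A", "B")
  expect_equal(cr$p_raw[1], 1)                       # zero var, equal means
  expect_equal(cr$p_raw[2], .Machine$double.xmin)    # zero var, shifted
  expect_equal(cr$log2fc[2], 1)

  expect_error(test_contrast(em, design, "A", "Z"), "unknown or absent")
  singleton <- design
  singleton$arm[1] <- "C"                    # arm C has a single sample
  expect_error(test_contrast(em, singleton, "C", "B"), ">= 2 samples")
})

test_that("swapping contrast groups negates fold changes, keeps p-values", {
  set.seed(11)
  em <- matrix(rnorm(40 * 10, 5), 40, 10,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  design <- data.frame(sample_id = colnames(em),
                       arm = rep(c("SHAM_VEH", "BDL_VEH"), 5), stage = "S1",
                       stringsAsFactors = FALSE)
  ab <- test_contrast(em, design, "SHAM_VEH", "BDL_VEH")
  ba <- test_contrast(em, design, "BDL_VEH", "SHAM_VEH")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_raw, ba$p_raw)
  expect_equal(ab$p_adj, ba$p_adj)
})

test_that("BH adjustment satisfies its order properties", {
  cr <- random_contrast(500, seed = 4)
  em_p <- cr$p_raw
  expect_true(all(cr$p_adj >= cr$p_raw & cr$p_adj <= 1))
  o <- order(em_p)
  expect_true(all(diff(cr$p_adj[o]) >= -1e-15))
})

test_that("classify_volcano partitions genes at the stated thresholds", {
  tau <- log2(1.5)
  cr <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(0.5, 1.0, -2.0),
                   p_raw = c(0.01, 0.01, 0.2),
                   p_adj = c(0.01, 0.01, 0.2), stringsAsFactors = FALSE)
  v <- classify_volcano(cr, tau = tau, alpha = 0.05)
  expect_equal(as.character(v$labels), c("ns", "up", "ns"))
  expect_equal(v$summary$n_up + v$summary$n_down + v$summary$n_ns, 3L)

  big <- random_contrast(2000, seed = 9)
  vb <- classify_volcano(big)
  expect_equal(vb$summary$n_up + vb$summary$n_down + vb$summary$n_ns, 2000L)
  expect_error(classify_volcano(big, tau = -1), "tau")
  expect_error(classify_volcano(big, alpha = 1.5), "alpha")
})

test_that("pca_summary returns sane coordinates and variance fractions", {
  set.seed(14)
  em <- matrix(rnorm(100 * 6, 5), 100, 6,
               dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  em[, 2] <- em[, 1]                         # duplicated sample profile
  p <- pca_summary(em, n_top = 50)
  expect_equal(p$coords$PC1[1], p$coords$PC1[2], tolerance = 1e-10)
  expect_equal(p$coords$PC2[1], p$coords$PC2[2], tolerance = 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  expect_warning(pca_summary(em, n_top = 1000), "exceeds")
  expect_error(pca_summary(em[, 1:2]), ">= 3 samples")
})

test_that("disease and control samples separate on PC1 in simulation", {
  pipe <- run_stage_pipeline(21, n_genes = 600)
  keep <- pipe$sim$design$arm %in% c("SHAM_VEH", "BDL_VEH")
  ids <- pipe$sim$design$sample_id[keep]
  p <- pca_summary(pipe$em[, ids], n_top = 300)
  grp <- as.integer(factor(pipe$sim$design$arm[match(ids, pipe$sim$design$sample_id)]))
  sil <- cluster::silhouette(grp, dist(p$coords$PC1))
  expect_gt(mean(sil[, "sil_width"]), 0)
})
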