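tau <- log2(1.5)

test_that("assign_pattern implements the region rule", {
  expect_equal(assign_pattern(3, 0, "UP"), "P1A")
  expect_equal(assign_pattern(4, 2, "UP", tau = 0.585), "P2A")
  expect_equal(assign_pattern(3, 3, "UP"), "NTA")
  expect_equal(assign_pattern(0.1, 2, "NONE", y_sig = TRUE), "P3A")
  expect_equal(assign_pattern(-3, -0.2, "DOWN"), "P1B")
  expect_equal(assign_pattern(-3, -3, "DOWN"), "NTB")
  expect_equal(assign_pattern(-4, -2, "DOWN", tau = 0.585), "P2B")
  expect_equal(assign_pattern(3, -1, "UP"), "OVERSHOOT_DOWN")
  expect_equal(assign_pattern(-3, 1, "DOWN"), "OVERSHOOT_UP")
  expect_equal(assign_pattern(0.1, 2, "NONE", y_sig = FALSE), "UNCHANGED")
  # closed bounds belong to the more-rescued group
  expect_equal(assign_pattern(4, 4 - tau, "UP", tau = tau), "P2A")
  expect_error(assign_pattern(Inf, 0, "UP"), "finite")
})

test_that("vectorized labeling equals the scalar rule on random pairs", {
  set.seed(31)
  n <- 1e4
  x <- rnorm(n, sd = 4); y <- rnorm(n, sd = 4)
  dereg <- sample(c("UP", "DOWN", "NONE"), n, replace = TRUE)
  dereg[dereg == "UP" & x < 0] <- "DOWN"    # keep dereg sign-consistent
  dereg[dereg == "DOWN" & x > 0] <- "UP"
  y_sig <- runif(n) < 0.5
  vec <- dipaR:::label_patterns(x, y, dereg, y_sig, tau)
  scal <- vapply(seq_len(n), function(i)
    assign_pattern(x[i], y[i], dereg[i], y_sig[i], tau), character(1))
  expect_identical(as.character(vec), scal)
  # partition: one label per gene, sizes sum to the universe
  expect_equal(sum(table(vec)), n)
})

test_that("build_dipa_table joins contrasts and is consistent with its rule", {
  pipe <- run_stage_pipeline(3, n_genes = 600)
  dt <- pipe$dt
  expect_s3_class(dt, "dipa_table")
  expect_equal(sum(pattern_sizes(dt)), nrow(dt))
  expect_true(all(!dt$extreme | dt$dereg != "NONE"))

  # treated identical to vehicle: deregulated genes sit on the diagonal
  same <- build_dipa_table(pipe$cx, pipe$cx)
  expect_true(all(same$label[same$dereg != "NONE"] %in% c("NTA", "NTB")))

  # treated fully back to normal: every deregulated gene is 1a/1b
  cy0 <- pipe$cx
  cy0$log2fc <- 0
  cy0$p_raw <- 1; cy0$p_adj <- 1
  full <- build_dipa_table(pipe$cx, cy0)
  expect_true(all(full$label[full$dereg != "NONE"] %in% c("P1A", "P1B")))

  disjoint <- pipe$cy
  disjoint$gene_id <- paste0("other_", disjoint$gene_id)
  expect_error(build_dipa_table(pipe$cx, disjoint), "share no genes")
  expect_warning(build_dipa_table(pipe$cx, pipe$cy[-1, ]), "universes differ")
})

test_that("diagonal contrasts produce no rescued labels", {
  cx <- random_contrast(2000, seed = 12)
  dt <- build_dipa_table(cx, cx)
  expect_equal(sum(dt$label %in% c("P1A", "P1B", "P2A", "P2B")), 0L)
})

test_that("labels recover the simulated archetypes for strong effects", {
  pipe <- run_stage_pipeline(17, rescue_attenuation = flat_attenuation(1))
  resc <- pipe$dt$label[pipe$truth$archetype == "RESCUED"]
  refr <- pipe$dt$label[pipe$truth$archetype == "REFRACTORY"]
  expect_gt(mean(resc %in% c("P1A", "P1B")), 0.9)
  expect_gt(mean(refr %in% c("NTA", "NTB")), 0.9)
})

test_that("extreme_subset applies the 17-fold bound to deregulated genes", {
  dt <- dipa_from_labels(c("a", "b", "c"), c("NTA", "NTA", "NTB"),
                         x = c(4.2, 4.0, -5))
  dt$dereg <- factor(c("UP", "UP", "DOWN"), levels = c("UP", "DOWN", "NONE"))
  got <- extreme_subset(dt)
  expect_true("a" %in% got)       # 2^4.2 > 17
  expect_false("b" %in% got)      # 2^4 = 16 < 17
  expect_true("c" %in% got)
  dt$dereg[3] <- "NONE"
  expect_false("c" %in% extreme_subset(dt))
})

test_that("rescue_percentage reproduces the printed study arithmetic", {
  expect_equal(rescue_percentage(3522, 372), 89.4)
  expect_equal(rescue_percentage(3538, 2672), 24.5)
  expect_equal(rescue_percentage(2759, 1334), 51.6)
  expect_equal(rescue_percentage(100, 100), 0)
  expect_lt(rescue_percentage(100, 150), 0)
  expect_warning(out <- rescue_percentage(0, 5), "undefined")
  expect_true(is.na(out))
})

test_that("rescue_summary pairs directions and validates thresholds", {
  cr <- random_contrast(3000, seed = 2)
  cr$log2fc <- cr$log2fc * 2
  cr$p_adj <- rep(c(1e-4, 0.5), length.out = 3000)   # guarantee calls
  v1 <- classify_volcano(cr)$summary
  cr2 <- cr; cr2$log2fc <- cr2$log2fc / 4
  v2 <- classify_volcano(cr2)$summary
  rs <- rescue_summary(v1, v2, organ = "KIDNEY", stage = "S1")
  expect_equal(rs$direction, c("UP", "DOWN"))
  expect_equal(rs$rescue_pct,
               rescue_percentage(c(v1$n_up, v1$n_down), c(v2$n_up, v2$n_down)))

  identical_rs <- rescue_summary(v1, v1)
  expect_equal(identical_rs$rescue_pct, c(0, 0))

  v3 <- classify_volcano(cr2, alpha = 0.01)$summary
  expect_error(rescue_summary(v1, v3), "different thresholds")
})

test_that("fully rescued labels decline from stage 1 to stage 4 by default", {
  counts_1a1b <- sapply(1:10, function(seed) {
    sapply(dipa_stages(), function(s) {
      pipe <- run_stage_pipeline(seed, stage = s, n_genes = 400,
                                 bdl_effect_log2_range = c(1, 5))
      sum(pipe$dt$label %in% c("P1A", "P1B"))
    })
  })
  avg <- rowMeans(counts_1a1b)
  expect_true(all(diff(avg) <= 0))
})
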