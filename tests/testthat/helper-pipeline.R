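# shared fixtures: small seeded simulations run through the DE + DiPa chain

run_stage_pipeline <- function(seed, stage = "S1", n_genes = 1000,
                               archetype_fractions = c(RESCUED = 0.4, PARTIAL = 0,
                                                       REFRACTORY = 0.4, DRUG_ONLY = 0,
                                                       "NULL" = 0.2),
                               bdl_effect_log2_range = c(3, 3),
                               rescue_attenuation = c(S1 = 0.9, S2 = 0.7,
                                                      S3 = 0.5, S4 = 0.3)) {
  d <- make_design(stages = stage, n_per_group = 5)
  cfg <- sim_config(n_genes = n_genes, seed = seed,
                    archetype_fractions = archetype_fractions,
                    bdl_effect_log2_range = bdl_effect_log2_range,
                    rescue_attenuation = rescue_attenuation)
  sim <- simulate_counts(d, cfg)
  cm <- filter_genes(sim$counts)
  em <- normalize_log2(cm, size_factors(cm))
  cx <- test_contrast(em, sim$design, "SHAM_VEH", "BDL_VEH")
  cy <- test_contrast(em, sim$design, "SHAM_VEH", "BDL_TRT")
  dt <- build_dipa_table(cx, cy)
  truth <- sim$truth[match(dt$gene_id, sim$truth$gene_id), ]
  list(sim = sim, em = em, cx = cx, cy = cy, dt = dt, truth = truth)
}

# flat-attenuation config helper
flat_attenuation <- function(a) c(S1 = a, S2 = a, S3 = a, S4 = a)

# random contrast-result table for property tests
random_contrast <- function(n, seed) {
  set.seed(seed)
  p <- runif(n)
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             log2fc = rnorm(n, sd = 3), p_raw = p,
             p_adj = p.adjust(p, "BH"), stringsAsFactors = FALSE)
}

# build a dipa_table-shaped data.frame directly from labels (for migration
# tests that do not need the DE layer)
dipa_from_labels <- function(gene_id, label, x = 0, y = 0) {
  structure(
    data.frame(gene_id = gene_id, x = x, y = y,
               dereg = "UP", y_sig = FALSE,
               label = factor(label, levels = pattern_levels()),
               extreme = FALSE, stringsAsFactors = FALSE),
    class = c("dipa_table", "data.frame"))
}
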