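# dipaR

Stage-dependent treatment-rescue analysis of bulk RNA-seq, with DiPa
pattern classification and diameter morphometry.

## What it is for

In disease models where a drug partially reverses a disease-induced
transcriptome change — e.g. ASBT-inhibitor therapy after bile duct
ligation (BDL) in mice — the interesting question is not just *which*
genes respond, but *how much of the disease signature is rescued, and how
that depends on the disease stage at which therapy starts*. `dipaR` is for
analysts of such three-arm designs (control, disease + vehicle,
disease + drug, replicated across several treatment-initiation stages).

The core is the **DiPa ("differentiation pattern") geometry**. For every
gene, two log2 ratios share the control reference:

    x = log2( disease+vehicle / control )      # what the disease did
    y = log2( disease+drug    / control )      # what remains under therapy

With a band half-width τ = log2(1.5) (the volcano fold-change threshold),
a gene deregulated by the disease (|x| ≥ τ and significant, BH-adjusted
p < 0.05) is

* **fully rescued** (group 1a/1b) if |y| < τ — back in the normal range;
* **partially rescued** (2a/2b) if it moved ≥ τ back toward normal but is
  still outside the band, τ ≤ y ≤ x − τ for up-regulated genes;
* **not treatable** (nta/ntb) if it sits on or beyond the diagonal,
  y > x − τ;
* **overshot** if the drug pushed it past the opposite band.

Genes untouched by the disease but moved ≥ τ by the drug (significantly)
form groups 3a/3b. Per direction, the **rescue percentage** is
`100 × (1 − n_deregulated_treated / n_deregulated_vehicle)`, and the
**extreme region** collects deregulated genes with at least a 17-fold
disease effect (|x| ≥ log2 17). Pattern-group membership can be
cross-tabulated between stages (`migration_matrix()`), with an exact
conservation check.

A second, independent component implements **diameter morphometry** for
image-derived measurement tables: a Tukey fence `Q3 + 1.5·(Q3 − Q1)`
computed on the sham control distribution defines "abnormally wide"
structures, and a stratified subsampling analysis quantifies how stable
per-group mean/SD are as a fixed per-stratum measurement count shrinks.

A seeded negative-binomial simulator with known gene archetypes
(rescued / partial / refractory / drug-only / null, with stage-attenuated
rescue) makes every stage of the pipeline testable without sequencing
data.

## Worked example

```r
library(dipaR)

design <- make_design(n_per_group = 5, organ = "KIDNEY")   # 60 samples
sim <- simulate_counts(design, sim_config(n_genes = 2000, seed = 3))

s1 <- design[design$stage == "S1", ]
cm <- filter_genes(sim$counts[, s1$sample_id])
em <- normalize_log2(cm, size_factors(cm))
cx <- test_contrast(em, s1, "SHAM_VEH", "BDL_VEH")   # disease effect
cy <- test_contrast(em, s1, "SHAM_VEH", "BDL_TRT")   # residual under drug

dt <- build_dipa_table(cx, cy)
pattern_sizes(dt)
#>            P1A            P1B            P2A            P2B            P3A
#>            100             84             59             49             22
#>            P3B            NTA            NTB   OVERSHOOT_UP OVERSHOOT_DOWN
#>             20             56             56              0              0
#>      UNCHANGED
#>           1554
```

100 + 84 genes are fully rescued at stage 1, 59 + 49 partially, 56 + 56 are
not treatable, and 1,554 genes were never deregulated. The same printed
arithmetic the study reports falls out of the volcano counts:

```r
rescue_percentage(3522, 372)    # 89.4  (% of down-regulated genes rescued)
tukey_fence(c(1, 1, 2, 2))$upper_fence   # 3.5
```

`run_report(run_config(seed = 1))` chains the whole pipeline — simulation,
per-stage DE and DiPa tables, rescue summaries, stage-1 → stage-4
migration with conservation check, and the diameter morphometry — into a
directory of TSV/JSON artifacts listed with MD5 checksums in
`manifest.json`; the bundle is bit-reproducible for a fixed seed.

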