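#' End-to-end synthetic analysis report
#'
#' Chains the whole pipeline on synthetic data: simulate counts for the full
#' 3-arm x 4-stage design, then per stage run filtering, median-of-ratios
#' normalization, the two contrasts (disease vs sham on x, treated vs sham
#' on y), volcano classification, the DiPa table with pattern-group sizes
#' and rescue summaries; cross-tabulate stage-1 vs stage-4 pattern
#' membership with a conservation check; and run the diameter morphometry
#' (sham-referenced Tukey fence, all/abnormal summaries, subsampling
#' stability). Every artifact is written under `outdir` and listed, with an
#' MD5 checksum, in `manifest.json`. Given the same configuration the
#' bundle is bit-reproducible.
#'
#' @param cfg A [run_config()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results: `design`,
#'   `volcano` (per stage), `dipa` (per stage), `rescue` (data.frame),
#'   `group_sizes`, `migration`, `conservation`, `fence`,
#'   `diameter_summary`, `stability`, `manifest`.
#' @export
run_report <- function(cfg = run_config(), outdir = tempfile("dipa_report_")) {
  if (!inherits(cfg, "run_config")) stopf("'cfg' must come from run_config()")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tau <- log2(cfg$fold_change)
  stages <- dipa_stages()

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("report stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- simulate -------------------------------------------------------------
  design <- make_design(n_per_group = cfg$n_per_group,
                        organ = if (cfg$organ %in% c("KIDNEY", "LIVER")) cfg$organ else "KIDNEY")
  sim <- step("simulate", simulate_counts(
    design, sim_config(n_genes = cfg$n_genes, n_per_group = cfg$n_per_group,
                       seed = cfg$seed)))
  write_tsv(sim$design, file.path(outdir, "design.tsv"))
  write_counts(sim$counts, file.path(outdir, "counts.tsv"))
  write_tsv(sim$truth, file.path(outdir, "truth.tsv"))

  # --- per-stage DE + DiPa --------------------------------------------------
  volcano <- list(); dipa <- list(); group_sizes <- list(); rescue <- list()
  for (s in stages) {
    res <- step(paste0("de_", s), {
      sub <- sim$design[sim$design$stage == s, , drop = FALSE]
      cm <- filter_genes(sim$counts[, sub$sample_id, drop = FALSE],
                         min_total = cfg$min_total)
      em <- normalize_log2(cm, size_factors(cm), pseudocount = cfg$pseudocount)
      cx <- test_contrast(em, sub, "SHAM_VEH", "BDL_VEH")
      cy <- test_contrast(em, sub, "SHAM_VEH", "BDL_TRT")
      list(cx = cx, cy = cy)
    })
    vx <- classify_volcano(res$cx, tau = tau, alpha = cfg$alpha)
    vy <- classify_volcano(res$cy, tau = tau, alpha = cfg$alpha)
    dt <- step(paste0("dipa_", s),
               build_dipa_table(res$cx, res$cy, tau = tau, alpha = cfg$alpha,
                                extreme_fold = cfg$extreme_fold))
    volcano[[s]] <- list(vehicle = vx$summary, treated = vy$summary)
    dipa[[s]] <- dt
    group_sizes[[s]] <- pattern_sizes(dt)
    rescue[[s]] <- rescue_summary(vx$summary, vy$summary,
                                  organ = cfg$organ, stage = s)
    write_tsv(res$cx, file.path(outdir, sprintf("contrast_x_%s.tsv", s)))
    write_tsv(res$cy, file.path(outdir, sprintf("contrast_y_%s.tsv", s)))
    write_tsv(as.data.frame(dt), file.path(outdir, sprintf("dipa_%s.tsv", s)))
    jsonlite::write_json(
      list(vehicle = unclass(vx$summary), treated = unclass(vy$summary),
           group_sizes = as.list(group_sizes[[s]])),
      file.path(outdir, sprintf("volcano_%s.json", s)), auto_unbox = TRUE)
  }
  rescue <- do.call(rbind, rescue)
  rownames(rescue) <- NULL
  write_tsv(rescue, file.path(outdir, "rescue.tsv"))

  # --- migration S1 -> S4 ---------------------------------------------------
  mm <- step("migration", migration_matrix(dipa$S1, dipa$S4, "S1", "S4"))
  shared <- intersect(dipa$S1$gene_id, dipa$S4$gene_id)
  origin_sizes <- pattern_sizes(dipa$S1[dipa$S1$gene_id %in% shared, ])
  conservation <- check_conservation(mm, origin_sizes)
  utils::write.table(
    data.frame(origin = rownames(mm$counts), mm$counts, check.names = FALSE),
    file.path(outdir, "migration_S1_S4.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(conservation, file.path(outdir, "conservation.json"),
                       auto_unbox = TRUE)

  # --- morphometry ----------------------------------------------------------
  morpho <- step("morphometry", {
    strata <- as.vector(outer(dipa_arms(), stages, paste, sep = "_"))
    dil <- ifelse(startsWith(strata, "SHAM"), 0,
                  ifelse(startsWith(strata, "BDL_VEH"), 0.15, 0.05))
    ds <- simulate_diameters(strata, cfg$diameters_per_stratum,
                             dilated_fraction = dil, seed = cfg$seed + 1L)
    fence <- tukey_fence(ds$value[ds$stratum == "SHAM_VEH_S1"])
    list(ds = ds, fence = fence,
         all = summarize_diameters(ds, "all"),
         abnormal = summarize_diameters(ds, "abnormal", fence),
         stability = subsample_stability(ds, cfg$subset_sizes,
                                         seed = cfg$seed + 2L))
  })
  jsonlite::write_json(unclass(morpho$fence), file.path(outdir, "fence.json"),
                       auto_unbox = TRUE)
  write_tsv(morpho$all, file.path(outdir, "diameter_summary_all.tsv"))
  write_tsv(morpho$abnormal, file.path(outdir, "diameter_summary_abnormal.tsv"))
  write_tsv(morpho$stability$per_stratum, file.path(outdir, "stability.tsv"))
  jsonlite::write_json(morpho$stability$per_size_max,
                       file.path(outdir, "stability_max.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- manifest -------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    thresholds = list(fold_change = cfg$fold_change, tau_log2 = tau,
                      alpha = cfg$alpha, extreme_fold = cfg$extreme_fold,
                      min_total = cfg$min_total, pseudocount = cfg$pseudocount),
    seed = cfg$seed,
    versions = list(package = as.character(utils::packageVersion("dipaR")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    artifacts = lapply(files, function(f) list(
      file = f, md5 = unname(tools::md5sum(file.path(outdir, f)))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(design = sim$design, truth = sim$truth, volcano = volcano,
                 dipa = dipa, group_sizes = group_sizes, rescue = rescue,
                 migration = mm, conservation = conservation,
                 fence = morpho$fence,
                 diameter_summary = list(all = morpho$all,
                                         abnormal = morpho$abnormal),
                 stability = morpho$stability,
                 manifest = manifest, outdir = outdir))
}

#' DiPa scatter plot
#'
#' Base-graphics scatter of the DiPa geometry: one point per gene at
#' (x, y) = (log2 disease/control, log2 treated/control), colored by pattern
#' group, with the normal-range band, the diagonal band and the extreme
#' bounds drawn as guides.
#'
#' @param dt A [build_dipa_table()] result.
#' @param ... Passed to [graphics::plot()].
#' @return The table, invisibly.
#' @export
plot_dipa <- function(dt, ...) {
  tau <- attr(dt, "tau") %||% default_tau()
  elog2 <- attr(dt, "extreme_log2") %||% default_extreme_log2()
  pal <- c(P1A = "#1b9e77", P1B = "#66c2a5", P2A = "#d95f02", P2B = "#fc8d62",
           P3A = "#7570b3", P3B = "#8da0cb", NTA = "#984ea3", NTB = "#ce93d8",
           OVERSHOOT_UP = "#e7298a", OVERSHOOT_DOWN = "#e78ac3",
           UNCHANGED = "grey70")
  graphics::plot(dt$x, dt$y, col = pal[as.character(dt$label)], pch = 16,
                 cex = 0.4, xlab = "log2 disease / control",
                 ylab = "log2 treated / control", ...)
  graphics::abline(h = c(-tau, tau), lty = 3)
  graphics::abline(a = 0, b = 1, lty = 2)
  graphics::abline(a = -tau, b = 1, lty = 3)
  graphics::abline(a = tau, b = 1, lty = 3)
  graphics::abline(v = c(-elog2, elog2), lty = 3, col = "grey50")
  invisible(dt)
}
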