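#' Configuration for the count simulator
#'
#' Collects the knobs of the negative-binomial count generator. Genes belong
#' to one of five archetypes describing how the disease (BDL) and the drug
#' move their mean expression relative to sham:
#'
#' * `RESCUED` — deregulated by BDL; under the drug the mean is moved back
#'   toward sham by the stage's full attenuation factor.
#' * `PARTIAL` — as above, but only half of the stage's attenuation is
#'   applied (a partial return).
#' * `REFRACTORY` — deregulated by BDL, unchanged by the drug.
#' * `DRUG_ONLY` — unaffected by BDL, shifted only in the treated arm.
#' * `NULL` — no true effect anywhere.
#'
#' The stage attenuation multiplies the rescue displacement: on the log2
#' scale, `treated = BDL + attenuation * (sham - BDL)` for `RESCUED` genes
#' (half that attenuation for `PARTIAL`). The default schedule decreases
#' from stage 1 to stage 4, emulating the loss of therapeutic efficacy when
#' treatment starts at a later disease stage.
#'
#' @param n_genes Number of genes, default 12000.
#' @param n_per_group Replicates per group (kept with the config for
#'   reference; the design passed to [simulate_counts()] governs), default 5.
#' @param baseline_mean_log2_range Range of per-gene baseline mean expression
#'   on the log2 count scale, default `c(4, 12)` (mean counts 16–4096,
#'   typical of filtered bulk RNA-seq genes).
#' @param dispersion_range Range for the per-gene NB dispersion, drawn
#'   log-uniformly; default `c(0.01, 0.1)`, typical gene-wise dispersions
#'   for bulk tissue RNA-seq.
#' @param archetype_fractions Named proportions over
#'   `RESCUED, PARTIAL, REFRACTORY, DRUG_ONLY, NULL`; must be non-negative
#'   and sum to 1.
#' @param bdl_effect_log2_range Range of the absolute BDL effect |log2 FC|
#'   for deregulated archetypes, default `c(1, 5)`.
#' @param rescue_attenuation Per-stage multiplier in `[0, 1]` applied to the
#'   rescue displacement; default `c(S1 = 0.9, S2 = 0.7, S3 = 0.5, S4 = 0.3)`
#'   (non-increasing).
#' @param library_size_mean,library_size_cv Log-normal law of realized
#'   library sizes around the design's expected value; defaults `1e6` and
#'   `0.25`.
#' @param seed Integer seed; the same config and seed give bit-identical
#'   output.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 12000L,
                       n_per_group = 5L,
                       baseline_mean_log2_range = c(4, 12),
                       dispersion_range = c(0.01, 0.1),
                       archetype_fractions = c(RESCUED = 0.10, PARTIAL = 0.05,
                                               REFRACTORY = 0.05, DRUG_ONLY = 0.02,
                                               "NULL" = 0.78),
                       bdl_effect_log2_range = c(1, 5),
                       rescue_attenuation = c(S1 = 0.9, S2 = 0.7, S3 = 0.5, S4 = 0.3),
                       library_size_mean = 1e6,
                       library_size_cv = 0.25,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != as.integer(n_genes))
    stopf("'n_genes' must be a positive integer")
  if (!setequal(names(archetype_fractions), gene_archetypes()))
    stopf("'archetype_fractions' must be named over: %s",
          paste(gene_archetypes(), collapse = ", "))
  archetype_fractions <- archetype_fractions[gene_archetypes()]
  if (any(archetype_fractions < 0) ||
      abs(sum(archetype_fractions) - 1) > 1e-8)
    stopf("'archetype_fractions' must be non-negative and sum to 1")
  if (any(dispersion_range <= 0))
    stopf("'dispersion_range' must be positive")
  if (any(rescue_attenuation < 0) || any(rescue_attenuation > 1))
    stopf("'rescue_attenuation' must lie in [0, 1]")
  if (is.unsorted(rev(rescue_attenuation)))
    warnf("'rescue_attenuation' is not non-increasing across stages; stage monotonicity of the rescue is not guaranteed")
  structure(list(
    n_genes = as.integer(n_genes),
    n_per_group = as.integer(n_per_group),
    baseline_mean_log2_range = baseline_mean_log2_range,
    dispersion_range = dispersion_range,
    archetype_fractions = archetype_fractions,
    bdl_effect_log2_range = bdl_effect_log2_range,
    rescue_attenuation = rescue_attenuation,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic archetype allocation: floor counts, remainder to the largest
# fractional parts, genes assigned in blocks
allocate_archetypes <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(fractions), times = base)
}

#' Simulate a negative-binomial count matrix with known gene archetypes
#'
#' Draws a gene-by-sample integer count matrix for the given design together
#' with a per-gene, per-stage truth table of archetypes and true effects.
#' Counts are NB-distributed with per-gene dispersion; per-sample library
#' sizes are drawn log-normally around the design's expected value so that
#' normalization is exercised. All randomness is governed by `cfg$seed`:
#' the same design and config reproduce the matrix bit-exactly.
#'
#' @param design A sample table from [make_design()].
#' @param cfg A [sim_config()].
#'
#' @return A list with elements
#'   * `counts` — integer matrix, genes x samples, dimnames set;
#'   * `truth` — `data.frame` with `gene_id`, `stage`, `archetype`,
#'     `true_log2fc_bdl` (BDL vs sham) and `true_log2fc_trt`
#'     (treated vs sham), one row per gene per stage (`NULL` genes have
#'     both effects 0);
#'   * `design` — the input design with realized `library_size` factors
#'     recorded in column `size_factor_true`.
#' @examples
#' d <- make_design(stages = "S1", n_per_group = 3)
#' sim <- simulate_counts(d, sim_config(n_genes = 100, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(design, cfg = sim_config()) {
  check_design(design)
  if (!inherits(cfg, "sim_config")) stopf("'cfg' must come from sim_config()")
  stages <- unique(design$stage)
  if (!all(stages %in% names(cfg$rescue_attenuation)))
    stopf("'rescue_attenuation' lacks stage(s): %s",
          paste(setdiff(stages, names(cfg$rescue_attenuation)), collapse = ", "))

  set.seed(cfg$seed)
  ng <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(ng))

  base_log2 <- stats::runif(ng, cfg$baseline_mean_log2_range[1],
                            cfg$baseline_mean_log2_range[2])
  lo <- log(cfg$dispersion_range[1]); hi <- log(cfg$dispersion_range[2])
  dispersion <- exp(stats::runif(ng, lo, hi))
  archetype <- allocate_archetypes(ng, cfg$archetype_fractions)

  sign_g <- sample(c(-1, 1), ng, replace = TRUE)
  magnitude <- stats::runif(ng, cfg$bdl_effect_log2_range[1],
                            cfg$bdl_effect_log2_range[2])
  drug_shift <- sign_g * magnitude   # used by DRUG_ONLY genes

  bdl_affected <- archetype %in% c("RESCUED", "PARTIAL", "REFRACTORY")
  lfc_bdl <- ifelse(bdl_affected, sign_g * magnitude, 0)

  # per-stage treated effect (vs sham) on the log2 scale
  trt_lfc <- function(stage) {
    a <- cfg$rescue_attenuation[[stage]]
    out <- numeric(ng)
    out[archetype == "RESCUED"]    <- (1 - a)       * lfc_bdl[archetype == "RESCUED"]
    out[archetype == "PARTIAL"]    <- (1 - 0.5 * a) * lfc_bdl[archetype == "PARTIAL"]
    out[archetype == "REFRACTORY"] <- lfc_bdl[archetype == "REFRACTORY"]
    out[archetype == "DRUG_ONLY"]  <- drug_shift[archetype == "DRUG_ONLY"]
    out
  }

  ns <- nrow(design)
  lib <- design$library_size *
    stats::rlnorm(ns, meanlog = -0.5 * log(1 + cfg$library_size_cv^2),
                  sdlog = sqrt(log(1 + cfg$library_size_cv^2)))
  sf_true <- lib / cfg$library_size_mean

  counts <- matrix(0L, nrow = ng, ncol = ns,
                   dimnames = list(gene_id, design$sample_id))
  trt_by_stage <- lapply(stats::setNames(stages, stages), trt_lfc)
  for (j in seq_len(ns)) {
    arm <- design$arm[j]; stage <- design$stage[j]
    lfc <- switch(arm,
                  SHAM_VEH = 0,
                  BDL_VEH = lfc_bdl,
                  BDL_TRT = trt_by_stage[[stage]],
                  stopf("unknown arm '%s' in design", arm))
    mu <- 2^(base_log2 + lfc) * sf_true[j]
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }
  storage.mode(counts) <- "integer"

  truth <- do.call(rbind, lapply(stages, function(s) data.frame(
    gene_id = gene_id, stage = s, archetype = archetype,
    true_log2fc_bdl = lfc_bdl, true_log2fc_trt = trt_by_stage[[s]],
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL

  design$size_factor_true <- sf_true
  list(counts = counts, truth = truth, design = design)
}

#' Simulate stratified diameter measurements with a dilated minority
#'
#' Draws per-stratum diameter measurements (micrometres) from a
#' two-component log-normal mixture: a base component and a minority
#' "dilated" component whose log-mean is shifted upward, emulating
#' abnormally wide structures such as dilated bile canaliculi. A truth flag
#' marks dilated-component membership so detection rules can be scored.
#'
#' @param strata Character vector of stratum labels (one experimental group
#'   per treatment-by-stage combination).
#' @param n_per_stratum Measurements per stratum (recycled), at least 1.
#' @param meanlog,sdlog Base log-normal parameters; `sdlog` must be
#'   positive. Defaults `log(1)` and `0.25` give a sham-like ~1 micron
#'   diameter distribution.
#' @param dilated_fraction Probability that a measurement comes from the
#'   dilated component, in `[0, 1)`; recycled across strata.
#' @param dilated_shift Upward shift of `meanlog` for the dilated component
#'   (log scale), recycled; default `log(3)`.
#' @param seed Integer seed; same arguments and seed give identical values.
#'
#' @return A `data.frame` with columns `value` (positive), `stratum`, and
#'   the logical truth flag `dilated`.
#' @export
simulate_diameters <- function(strata, n_per_stratum,
                               meanlog = 0, sdlog = 0.25,
                               dilated_fraction = 0, dilated_shift = log(3),
                               seed = 1L) {
  if (length(strata) == 0L) stopf("'strata' must be non-empty")
  if (any(n_per_stratum < 1)) stopf("'n_per_stratum' must be >= 1")
  if (any(sdlog <= 0)) stopf("'sdlog' must be positive")
  if (any(dilated_fraction < 0) || any(dilated_fraction >= 1))
    stopf("'dilated_fraction' must lie in [0, 1)")
  k <- length(strata)
  n_per_stratum <- rep_len(as.integer(n_per_stratum), k)
  dilated_fraction <- rep_len(dilated_fraction, k)
  dilated_shift <- rep_len(dilated_shift, k)
  meanlog <- rep_len(meanlog, k)
  sdlog <- rep_len(sdlog, k)

  set.seed(as.integer(seed))
  parts <- lapply(seq_len(k), function(i) {
    n <- n_per_stratum[i]
    dil <- stats::runif(n) < dilated_fraction[i]
    val <- stats::rlnorm(n, meanlog = meanlog[i] + dilated_shift[i] * dil,
                         sdlog = sdlog[i])
    data.frame(value = val, stratum = strata[i], dilated = dil,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
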