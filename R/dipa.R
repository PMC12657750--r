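#' Assign one gene to a DiPa pattern group
#'
#' Scalar classification rule of the DiPa geometry. `x` is the log2 ratio
#' disease-vs-control, `y` the log2 ratio treated-disease-vs-control,
#' `dereg` the volcano status of the x contrast, and `tau` the half-width of
#' the "normal expression range" band (also used as the half-width of the
#' diagonal band).
#'
#' For a gene upregulated by the disease (`dereg = "UP"`):
#' * `|y| < tau` — back in the normal band: fully rescued, `P1A`;
#' * `y <= -tau` — pushed past the band to the other side: `OVERSHOOT_DOWN`;
#' * `tau <= y <= x - tau` — moved at least `tau` back toward normal but
#'   still elevated: partially rescued, `P2A`;
#' * `y > x - tau` — on or beyond the diagonal (unaffected or worsened by
#'   the drug): not treatable, `NTA`.
#'
#' The mirror rule applies for `dereg = "DOWN"` (`P1B`, `OVERSHOOT_UP`,
#' `P2B`, `NTB`). Genes not deregulated by the disease are `P3A`/`P3B` when
#' the drug alone moves them significantly beyond `tau` (per `y_sig`), else
#' `UNCHANGED`. Boundary values belong to the more-rescued group.
#'
#' @param x,y Finite log2 ratios (scalars).
#' @param dereg `"UP"`, `"DOWN"` or `"NONE"`.
#' @param y_sig Logical; whether the y contrast is significantly deregulated
#'   (consulted only when `dereg = "NONE"`).
#' @param tau Positive band half-width on the log2 scale; default
#'   `log2(1.5)`.
#' @return A single pattern label, one of [pattern_levels()].
#' @examples
#' assign_pattern(3, 0, "UP")            # "P1A": back in the normal band
#' assign_pattern(4, 2, "UP")            # "P2A": part-way back
#' assign_pattern(3, 3, "UP")            # "NTA": on the diagonal
#' @export
assign_pattern <- function(x, y, dereg, y_sig = FALSE, tau = default_tau()) {
  if (!is.finite(x) || !is.finite(y)) stopf("'x' and 'y' must be finite")
  if (tau <= 0) stopf("'tau' must be > 0")
  dereg <- match.arg(dereg, c("UP", "DOWN", "NONE"))
  if (dereg == "UP") {
    if (abs(y) < tau) "P1A"
    else if (y <= -tau) "OVERSHOOT_DOWN"
    else if (y <= x - tau) "P2A"
    else "NTA"
  } else if (dereg == "DOWN") {
    if (abs(y) < tau) "P1B"
    else if (y >= tau) "OVERSHOOT_UP"
    else if (y >= x + tau) "P2B"
    else "NTB"
  } else {
    if (isTRUE(y_sig) && y >= tau) "P3A"
    else if (isTRUE(y_sig) && y <= -tau) "P3B"
    else "UNCHANGED"
  }
}

# vectorized labeling used by build_dipa_table(); an independent code path
# from the scalar assign_pattern()
label_patterns <- function(x, y, dereg, y_sig, tau) {
  lab <- rep("UNCHANGED", length(x))
  up <- dereg == "UP"; down <- dereg == "DOWN"; none <- dereg == "NONE"
  lab[up]   <- "NTA"
  lab[up & y <= x - tau] <- "P2A"
  lab[up & y <= -tau]    <- "OVERSHOOT_DOWN"
  lab[up & abs(y) < tau] <- "P1A"
  lab[down] <- "NTB"
  lab[down & y >= x + tau] <- "P2B"
  lab[down & y >= tau]     <- "OVERSHOOT_UP"
  lab[down & abs(y) < tau] <- "P1B"
  lab[none & y_sig & y >= tau]  <- "P3A"
  lab[none & y_sig & y <= -tau] <- "P3B"
  factor(lab, levels = pattern_levels())
}

#' Build a DiPa table from two contrasts
#'
#' Joins the disease contrast (x axis: disease + vehicle vs control) and the
#' treated contrast (y axis: disease + drug vs control) on their common gene
#' universe, derives the x-axis volcano status and the y-axis significance,
#' assigns every gene its DiPa pattern label, and flags the extreme region
#' (genes deregulated at least `extreme_fold`-fold by the disease).
#'
#' @param cx,cy Contrast results from [test_contrast()] for the x and y
#'   ratios. Their gene universes are intersected with a warning if they
#'   differ; disjoint universes are an error.
#' @param tau Log2 band half-width, default `log2(1.5)`.
#' @param alpha Significance level for the volcano calls, default 0.05.
#' @param use P-value column for the volcano calls (see
#'   [classify_volcano()]).
#' @param extreme_fold Linear fold-change bound of the extreme region,
#'   default 17.
#' @return A `data.frame` of class `"dipa_table"` with columns `gene_id`,
#'   `x`, `y`, `dereg`, `y_sig`, `label`, `extreme`, plus the thresholds in
#'   attributes `tau`, `alpha`, `extreme_log2`.
#' @export
build_dipa_table <- function(cx, cy, tau = default_tau(), alpha = 0.05,
                             use = c("p_adj", "p_raw"), extreme_fold = 17) {
  use <- match.arg(use)
  if (extreme_fold <= 1) stopf("'extreme_fold' must be > 1")
  common <- intersect(cx$gene_id, cy$gene_id)
  if (length(common) == 0L) stopf("contrasts share no genes")
  if (length(common) < max(nrow(cx), nrow(cy)))
    warnf("gene universes differ; using the %d shared genes", length(common))
  cx <- cx[match(common, cx$gene_id), , drop = FALSE]
  cy <- cy[match(common, cy$gene_id), , drop = FALSE]

  vx <- classify_volcano(cx, tau = tau, alpha = alpha, use = use)
  vy <- classify_volcano(cy, tau = tau, alpha = alpha, use = use)
  dereg <- c(up = "UP", down = "DOWN", ns = "NONE")[as.character(vx$labels)]
  y_sig <- vy$labels != "ns"

  elog2 <- log2(extreme_fold)
  out <- data.frame(
    gene_id = common,
    x = cx$log2fc, y = cy$log2fc,
    dereg = factor(unname(dereg), levels = c("UP", "DOWN", "NONE")),
    y_sig = unname(y_sig),
    label = label_patterns(cx$log2fc, cy$log2fc, dereg, y_sig, tau),
    extreme = unname(dereg != "NONE" & abs(cx$log2fc) >= elog2),
    stringsAsFactors = FALSE
  )
  attr(out, "tau") <- tau
  attr(out, "alpha") <- alpha
  attr(out, "extreme_log2") <- elog2
  class(out) <- c("dipa_table", class(out))
  out
}

#' Genes in the extreme deregulation region
#'
#' Returns the ids of genes deregulated by the disease with
#' `|x| >= extreme_log2`, i.e. at least a 17-fold change under the default
#' threshold `log2(17) ~ 4.09`.
#'
#' @param dt A [build_dipa_table()] result (or any data.frame with `x` and
#'   `dereg`).
#' @param extreme_log2 Positive log2 bound; defaults to the table's own
#'   threshold, else `log2(17)`.
#' @return Character vector of gene ids.
#' @export
extreme_subset <- function(dt, extreme_log2 = NULL) {
  extreme_log2 <- extreme_log2 %||% attr(dt, "extreme_log2") %||% default_extreme_log2()
  if (extreme_log2 <= 0) stopf("'extreme_log2' must be > 0")
  dt$gene_id[dt$dereg != "NONE" & abs(dt$x) >= extreme_log2]
}

#' Rescue percentage from deregulated-gene counts
#'
#' The fraction of disease-deregulated genes no longer deregulated under
#' treatment, as a percentage:
#' `100 * (1 - n_treated / n_vehicle)`, rounded to one decimal. Negative
#' when treatment deregulates more genes than vehicle. Undefined (NA) when
#' the vehicle count is zero.
#'
#' @param n_vehicle,n_treated Deregulated-gene counts (one direction) under
#'   vehicle and under treatment; vectorized.
#' @return Numeric percentage(s), one decimal.
#' @examples
#' rescue_percentage(3522, 372)   # 89.4
#' @export
rescue_percentage <- function(n_vehicle, n_treated) {
  if (any(n_treated < 0, na.rm = TRUE)) stopf("'n_treated' must be >= 0")
  if (any(n_vehicle < 0, na.rm = TRUE)) stopf("'n_vehicle' must be >= 0")
  out <- ifelse(n_vehicle > 0, round(100 * (1 - n_treated / n_vehicle), 1),
                NA_real_)
  if (any(n_vehicle == 0, na.rm = TRUE))
    warnf("rescue percentage undefined where n_vehicle = 0; returning NA")
  out
}

#' Per-direction rescue summary from two volcano summaries
#'
#' Compares the deregulated-gene counts of the vehicle contrast against the
#' treated contrast, per direction, yielding the UP and DOWN rescue
#' percentages for one organ and stage. Both summaries must come from the
#' same gene universe and thresholds.
#'
#' @param volc_vehicle,volc_treated `volcano_summary` objects (the
#'   `summary` element of [classify_volcano()]).
#' @param organ,stage Labels carried into the output.
#' @return A `data.frame` with one row per direction (`UP`, `DOWN`):
#'   `organ`, `stage`, `direction`, `n_dereg_vehicle`, `n_dereg_treated`,
#'   `rescue_pct`.
#' @export
rescue_summary <- function(volc_vehicle, volc_treated, organ = NA, stage = NA) {
  for (v in list(volc_vehicle, volc_treated))
    if (!inherits(v, "volcano_summary"))
      stopf("inputs must be 'volcano_summary' objects")
  if (!isTRUE(all.equal(volc_vehicle$fc_threshold, volc_treated$fc_threshold)) ||
      !isTRUE(all.equal(volc_vehicle$alpha, volc_treated$alpha)))
    stopf("volcano summaries use different thresholds")
  if (volc_vehicle$n_tested != volc_treated$n_tested)
    stopf("volcano summaries cover different gene universes (%d vs %d genes)",
          volc_vehicle$n_tested, volc_treated$n_tested)
  nv <- c(UP = volc_vehicle$n_up, DOWN = volc_vehicle$n_down)
  nt <- c(UP = volc_treated$n_up, DOWN = volc_treated$n_down)
  data.frame(
    organ = organ, stage = stage, direction = names(nv),
    n_dereg_vehicle = unname(nv), n_dereg_treated = unname(nt),
    rescue_pct = unname(rescue_percentage(nv, nt)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pattern-group sizes of a DiPa table
#'
#' @param dt A [build_dipa_table()] result.
#' @return Named integer vector over [pattern_levels()]; sums to the
#'   universe size.
#' @export
pattern_sizes <- function(dt) {
  tab <- table(factor(dt$label, levels = pattern_levels()))
  stats::setNames(as.integer(tab), names(tab))
}
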