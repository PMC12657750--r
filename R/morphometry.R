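#' Tukey upper fence of a reference distribution
#'
#' Computes `Q3 + 1.5 * (Q3 - Q1)` from a reference sample (typically the
#' sham control stratum); measurements exceeding this fence are called
#' abnormal. Quartiles use linear interpolation (quantile type 7) by
#' default.
#'
#' @param reference Numeric vector of at least 4 reference measurements.
#' @param type Quantile type passed to [stats::quantile()], default 7.
#' @return A list of class `"fence_spec"` with `q1`, `q3`, `upper_fence`.
#' @examples
#' tukey_fence(c(1, 1, 2, 2))$upper_fence   # 3.5
#' @export
tukey_fence <- function(reference, type = 7L) {
  reference <- as.numeric(reference)
  if (length(reference) < 4L || anyNA(reference))
    stopf("'reference' needs >= 4 non-missing values")
  q <- stats::quantile(reference, c(0.25, 0.75), type = type, names = FALSE)
  structure(list(q1 = q[1], q3 = q[2],
                 upper_fence = q[2] + 1.5 * (q[2] - q[1])),
            class = "fence_spec")
}

#' @export
print.fence_spec <- function(x, ...) {
  cat(sprintf("Tukey fence: Q1 = %.4g, Q3 = %.4g, upper fence = %.4g\n",
              x$q1, x$q3, x$upper_fence))
  invisible(x)
}

#' Abnormally wide measurements relative to a fence
#'
#' Selects measurements strictly exceeding the reference fence ("abnormal")
#' and reports the abnormal fraction per stratum.
#'
#' @param ds Diameter set: `data.frame` with `value` and `stratum` columns
#'   (see [simulate_diameters()]).
#' @param fence A [tukey_fence()] result (computed on the designated
#'   reference stratum).
#' @return A list with `subset` (the abnormal rows of `ds`) and `fraction`
#'   (named per-stratum fraction in `[0, 1]`).
#' @export
abnormal_subset <- function(ds, fence) {
  check_diameters(ds)
  if (!inherits(fence, "fence_spec")) stopf("'fence' must come from tukey_fence()")
  keep <- ds$value > fence$upper_fence
  frac <- tapply(keep, ds$stratum, mean)
  list(subset = ds[keep, , drop = FALSE],
       fraction = stats::setNames(as.numeric(frac), names(frac)))
}

#' Per-stratum diameter summaries
#'
#' Count, mean and standard deviation of the measurements in each stratum,
#' either over all values (`mode = "all"`) or restricted to the abnormal
#' subset above a fence (`mode = "abnormal"`). A stratum emptied by the
#' filter is reported with `n = 0` and missing mean/sd rather than dropped.
#'
#' @param ds Diameter set (`value`, `stratum`).
#' @param mode `"all"` or `"abnormal"`.
#' @param fence Required for `mode = "abnormal"`.
#' @return `data.frame` with `stratum`, `n`, `mean`, `sd`.
#' @export
summarize_diameters <- function(ds, mode = c("all", "abnormal"), fence = NULL) {
  mode <- match.arg(mode)
  check_diameters(ds)
  strata <- unique(ds$stratum)
  if (mode == "abnormal") {
    if (is.null(fence)) stopf("mode = 'abnormal' requires a fence")
    ds <- abnormal_subset(ds, fence)$subset
  }
  rows <- lapply(strata, function(s) {
    v <- ds$value[ds$stratum == s]
    data.frame(stratum = s, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else if (length(v) == 1L) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified subsampling stability of diameter statistics
#'
#' For each stratum and each requested subset size, draws one seeded
#' subsample without replacement and reports the percentage change of the
#' subsample mean and standard deviation against the full stratum:
#' `100 * |subsample stat - full stat| / |full stat|`. Per-size maxima
#' across strata summarize the worst case. This mirrors the practice of
#' analyzing a fixed number of measurements per experimental group
#' (stratum) when the raw measurement count is very large, checking how
#' small the fixed number can be before the group statistics drift.
#'
#' @param ds Diameter set (`value`, `stratum`).
#' @param subset_sizes Integer vector of subsample sizes, each at most the
#'   size of every stratum (e.g. `10^6` down to `10^3` by factors of ten).
#' @param seed Integer seed; one draw per (stratum, size), derived
#'   deterministically from `seed`.
#' @return A list of class `"subsample_stability"` with
#'   `per_stratum` (`data.frame`: `stratum`, `subset_size`,
#'   `pct_change_mean`, `pct_change_sd`), `per_size_max` (`data.frame` of
#'   per-size maxima across strata), `subset_sizes`, `seed`.
#' @export
subsample_stability <- function(ds, subset_sizes, seed = 1L) {
  check_diameters(ds)
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes < 1L)) stopf("'subset_sizes' must be >= 1")
  strata <- unique(ds$stratum)
  values <- split(ds$value, factor(ds$stratum, levels = strata))
  for (s in strata)
    if (any(subset_sizes > length(values[[s]])))
      stopf("subset size %d exceeds stratum '%s' (n = %d)",
            max(subset_sizes), s, length(values[[s]]))

  rows <- vector("list", length(strata) * length(subset_sizes))
  k <- 0L
  for (si in seq_along(strata)) {
    v <- values[[si]]
    full_mean <- mean(v); full_sd <- stats::sd(v)
    for (zi in seq_along(subset_sizes)) {
      # independent deterministic stream per (stratum, size)
      set.seed((as.integer(seed) + 7919L * si + 104729L * zi) %% .Machine$integer.max)
      sub <- v[sample.int(length(v), subset_sizes[zi])]
      k <- k + 1L
      rows[[k]] <- data.frame(
        stratum = strata[si], subset_size = subset_sizes[zi],
        pct_change_mean = 100 * abs(mean(sub) - full_mean) / abs(full_mean),
        pct_change_sd = 100 * abs(stats::sd(sub) - full_sd) / abs(full_sd),
        stringsAsFactors = FALSE)
    }
  }
  per_stratum <- do.call(rbind, rows)
  rownames(per_stratum) <- NULL
  per_size_max <- do.call(rbind, lapply(subset_sizes, function(z) {
    sub <- per_stratum[per_stratum$subset_size == z, , drop = FALSE]
    data.frame(subset_size = z,
               max_pct_change_mean = max(sub$pct_change_mean),
               max_pct_change_sd = max(sub$pct_change_sd))
  }))
  structure(list(per_stratum = per_stratum, per_size_max = per_size_max,
                 subset_sizes = subset_sizes, seed = as.integer(seed)),
            class = "subsample_stability")
}

#' @export
print.subsample_stability <- function(x, ...) {
  cat("stratified subsampling stability (max % change across strata):\n")
  print(x$per_size_max, row.names = FALSE)
  invisible(x)
}

check_diameters <- function(ds) {
  if (!is.data.frame(ds) || !all(c("value", "stratum") %in% names(ds)))
    stopf("'ds' must be a data.frame with columns 'value' and 'stratum'")
  if (any(ds$value <= 0)) stopf("diameter values must be positive")
  invisible(ds)
}
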