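#' Build a full factorial sample design
#'
#' Lays out one row per biological replicate for every arm-by-stage cell of
#' the experiment: three arms (sham + vehicle, BDL + vehicle, BDL + drug)
#' crossed with up to four treatment-initiation stages, for one organ. The
#' study design this emulates uses n = 5 mice per group.
#'
#' @param stages Character vector of stage labels, a subset of
#'   [dipa_stages()]. Order is kept.
#' @param arms Character vector of arm labels, a subset of [dipa_arms()].
#' @param n_per_group Replicates per (arm, stage) cell; at least 2, default 5.
#' @param organ `"KIDNEY"` or `"LIVER"`.
#' @param library_size Expected total counts per sample (positive), default
#'   `1e6`. Realized library sizes are drawn around this value by
#'   [simulate_counts()].
#'
#' @return A `data.frame` with columns `sample_id`, `arm`, `stage`, `organ`,
#'   `library_size`, ordered by stage, then arm, then replicate; one row per
#'   sample, `sample_id` unique.
#' @examples
#' d <- make_design()
#' nrow(d)     # 60 samples: 4 stages x 3 arms x 5 replicates
#' @export
make_design <- function(stages = dipa_stages(), arms = dipa_arms(),
                        n_per_group = 5L, organ = c("KIDNEY", "LIVER"),
                        library_size = 1e6) {
  organ <- match.arg(organ)
  if (length(stages) == 0L || length(arms) == 0L)
    stopf("'stages' and 'arms' must be non-empty")
  if (!all(stages %in% dipa_stages()))
    stopf("unknown stage label(s): %s",
          paste(setdiff(stages, dipa_stages()), collapse = ", "))
  if (!all(arms %in% dipa_arms()))
    stopf("unknown arm label(s): %s",
          paste(setdiff(arms, dipa_arms()), collapse = ", "))
  if (anyDuplicated(stages) || anyDuplicated(arms))
    stopf("'stages' and 'arms' must not contain duplicates")
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L)
    stopf("'n_per_group' must be an integer >= 2 (group variances are undefined at n = 1)")
  if (!is.numeric(library_size) || library_size <= 0)
    stopf("'library_size' must be a positive number")

  grid <- expand.grid(rep = seq_len(n_per_group), arm = arms, stage = stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%s_r%d", organ, grid$arm, grid$stage, grid$rep),
    arm = grid$arm,
    stage = grid$stage,
    organ = organ,
    library_size = library_size,
    stringsAsFactors = FALSE
  )
}

# validate a SampleTable-shaped data.frame; returns it invisibly
check_design <- function(design) {
  need <- c("sample_id", "arm", "stage")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stopf("'design' must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stopf("duplicate sample_id in design")
  invisible(design)
}
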