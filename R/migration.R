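#' Cross-stage migration of pattern groups
#'
#' Cross-tabulates the DiPa pattern labels of the genes shared by two
#' stages: entry (origin label, destination label) counts how many genes
#' moved from one pattern group at the origin stage to another at the
#' destination stage. Genes present in only one table are excluded from the
#' matrix and reported separately.
#'
#' @param dt_origin,dt_dest DiPa tables (see [build_dipa_table()]) for the
#'   origin and destination stages.
#' @param origin_stage,dest_stage Stage labels carried into the result.
#' @return An object of class `"migration_matrix"`: a list with `counts`
#'   (origin x destination integer matrix over [pattern_levels()]),
#'   `universe_size`, `origin_stage`, `dest_stage`, and the ids left out on
#'   either side (`origin_only`, `dest_only`).
#' @export
migration_matrix <- function(dt_origin, dt_dest,
                             origin_stage = NA, dest_stage = NA) {
  common <- intersect(dt_origin$gene_id, dt_dest$gene_id)
  if (length(common) == 0L) stopf("the two tables share no genes")
  lo <- factor(dt_origin$label[match(common, dt_origin$gene_id)],
               levels = pattern_levels())
  ld <- factor(dt_dest$label[match(common, dt_dest$gene_id)],
               levels = pattern_levels())
  counts <- table(origin = lo, destination = ld)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(
    counts = counts,
    universe_size = length(common),
    origin_stage = origin_stage,
    dest_stage = dest_stage,
    origin_only = setdiff(dt_origin$gene_id, common),
    dest_only = setdiff(dt_dest$gene_id, common)
  ), class = "migration_matrix")
}

#' @export
print.migration_matrix <- function(x, ...) {
  cat(sprintf("migration %s -> %s over %d shared genes\n",
              x$origin_stage, x$dest_stage, x$universe_size))
  nz <- rowSums(x$counts) > 0 | colSums(x$counts) > 0
  print(x$counts[rowSums(x$counts) > 0, nz, drop = FALSE])
  invisible(x)
}

#' Conservation check of a migration matrix
#'
#' Verifies that genes are neither lost nor double-counted: every row sum
#' must equal the corresponding origin group size and the grand total must
#' equal the universe size.
#'
#' @param mm A [migration_matrix()] result.
#' @param origin_sizes Named integer vector of origin group sizes on the
#'   same universe (e.g. from [pattern_sizes()] restricted to the shared
#'   genes). Missing labels are treated as size 0.
#' @return A list with `pass` (logical), `discrepancies` (`data.frame` of
#'   labels whose row sum differs from the declared size, with the
#'   difference), and `total_ok` for the grand-total check.
#' @examples
#' # the accounting printed for stage-1 group 1a at stage 4:
#' # 1657 + 470 + 215 genes must cover the 2342 origin genes
#' @export
check_conservation <- function(mm, origin_sizes) {
  if (!inherits(mm, "migration_matrix"))
    stopf("'mm' must be a migration_matrix")
  sizes <- stats::setNames(rep(0L, nrow(mm$counts)), rownames(mm$counts))
  if (length(origin_sizes)) {
    if (is.null(names(origin_sizes)))
      stopf("'origin_sizes' must be named by pattern label")
    unknown <- setdiff(names(origin_sizes), names(sizes))
    if (length(unknown))
      stopf("unknown pattern label(s) in origin_sizes: %s",
            paste(unknown, collapse = ", "))
    sizes[names(origin_sizes)] <- as.integer(origin_sizes)
  }
  rs <- rowSums(mm$counts)
  diff <- rs - sizes
  disc <- data.frame(label = names(diff)[diff != 0],
                     row_sum = unname(rs[diff != 0]),
                     origin_size = unname(sizes[diff != 0]),
                     discrepancy = unname(diff[diff != 0]),
                     stringsAsFactors = FALSE)
  total_ok <- sum(mm$counts) == mm$universe_size
  list(pass = nrow(disc) == 0L && total_ok,
       discrepancies = disc,
       total_ok = total_ok,
       universe_size = mm$universe_size,
       grand_total = sum(mm$counts))
}
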