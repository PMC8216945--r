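#' Classify scaffolds by homology to an annotated reference
#'
#' Votes on each scaffold's origin from tabular similarity hits (BLAST
#' outfmt-6-like or PAF-like: scaffold, target chromosome, identity, aligned
#' bases) against a related species' assembly whose Y chromosome is known.
#' Hits below `min_identity` are discarded; aligned bases are summed per
#' target chromosome; a scaffold is called Y when the Y-target total is the
#' strict maximum and covers at least `min_cov_fraction` of the scaffold.
#' Ties never call Y (conservative), and a scaffold with no hits gets
#' `no-call`.
#'
#' @param hits `data.frame` with columns `scaffold_id`, `target_chrom`,
#'   `identity` (fraction), `aligned_bases` (bp).
#' @param scaffold_lengths named numeric vector of scaffold lengths; names
#'   define the scaffold universe (scaffolds without hits are `no-call`).
#' @param min_identity minimum per-hit identity (default 0.8).
#' @param min_cov_fraction minimum Y-aligned fraction of the scaffold length
#'   (default 0.5).
#' @param y_targets target chromosome name(s) counted as Y (default "Y").
#' @return character vector over `Y`, `not-Y`, `no-call`, named by scaffold.
#' @export
classify_homology <- function(hits, scaffold_lengths, min_identity = 0.8,
                              min_cov_fraction = 0.5, y_targets = "Y") {
  need <- c("scaffold_id", "target_chrom", "identity", "aligned_bases")
  stopifnot(all(need %in% names(hits)))
  if (nrow(hits) > 0 &&
      any(hits$aligned_bases >
          scaffold_lengths[hits$scaffold_id], na.rm = TRUE)) {
    stop("a hit aligns more bases than its scaffold length", call. = FALSE)
  }
  out <- setNames(rep("no-call", length(scaffold_lengths)),
                  names(scaffold_lengths))
  hits <- hits[hits$identity >= min_identity &
                 hits$scaffold_id %in% names(scaffold_lengths), , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  agg <- stats::aggregate(aligned_bases ~ scaffold_id + target_chrom,
                          data = hits, FUN = sum)
  for (sid in unique(agg$scaffold_id)) {
    a <- agg[agg$scaffold_id == sid, ]
    y_sum <- sum(a$aligned_bases[a$target_chrom %in% y_targets])
    other_max <- suppressWarnings(
      max(a$aligned_bases[!(a$target_chrom %in% y_targets)], -Inf))
    is_y <- y_sum > other_max &&
      y_sum >= min_cov_fraction * scaffold_lengths[[sid]]
    out[sid] <- if (is_y) "Y" else "not-Y"
  }
  out
}
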