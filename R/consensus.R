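#' Integrate AD, YGS and homology calls by intersection and union
#'
#' Combines the three per-scaffold Y calls into one table: a scaffold is in
#' the intersection when all three methods call it Y (the high-confidence
#' set) and in the union when any does (the inclusive set handed to
#' scaffolding). The three inputs must cover the same scaffold universe.
#'
#' @param ad_calls character vector from [classify_ad()] /
#'   [classify_ad_profile()] (Y counts as a Y vote).
#' @param ygs_calls character vector from [classify_ygs()].
#' @param hom_calls character vector from [classify_homology()].
#' @return `data.frame` of class `consensus_table` with per-scaffold logical
#'   flags `ad`, `ygs`, `homology`, `in_intersection`, `in_union`, plus a
#'   `counts` attribute (per-method totals, pairwise overlaps, intersection
#'   and union sizes).
#' @export
consensus_calls <- function(ad_calls, ygs_calls, hom_calls) {
  ids <- names(ad_calls)
  if (is.null(ids) || !setequal(ids, names(ygs_calls)) ||
      !setequal(ids, names(hom_calls))) {
    stop("the three call sets must be named over the same scaffolds",
         call. = FALSE)
  }
  ad <- unname(ad_calls[ids] == "Y")
  ygs <- unname(ygs_calls[ids] == "Y")
  hom <- unname(hom_calls[ids] == "Y")
  out <- data.frame(scaffold_id = ids, ad = ad, ygs = ygs, homology = hom,
                    in_intersection = ad & ygs & hom,
                    in_union = ad | ygs | hom,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    ad = sum(ad), ygs = sum(ygs), homology = sum(hom),
    ad_ygs = sum(ad & ygs), ad_homology = sum(ad & hom),
    ygs_homology = sum(ygs & hom),
    intersection = sum(out$in_intersection), union = sum(out$in_union))
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' @export
print.consensus_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Consensus over", nrow(x), "scaffolds:\n")
  cat(sprintf("  AD: %d  YGS: %d  homology: %d\n",
              cnt[["ad"]], cnt[["ygs"]], cnt[["homology"]]))
  cat(sprintf("  intersection: %d  union: %d\n",
              cnt[["intersection"]], cnt[["union"]]))
  invisible(x)
}

#' Write the union-set scaffolds as FASTA
#'
#' @param consensus a `consensus_table`.
#' @param genome an `msy_genome` (or named character vector of sequences).
#' @param path output FASTA path.
#' @param set `"union"` (default) or `"intersection"`.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, genome, path,
                                  set = c("union", "intersection")) {
  set <- match.arg(set)
  seqs <- if (inherits(genome, "msy_genome")) genome$sequences else genome
  keep <- consensus$scaffold_id[
    if (set == "union") consensus$in_union else consensus$in_intersection]
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs[keep]),
                              filepath = path)
  invisible(path)
}
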