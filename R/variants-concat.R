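#' Concatenate haploid SNP genotypes into a sequence alignment
#'
#' Turns filtered haploid SNP records into one alignment column per site, in
#' (chrom, pos) order, one sequence per sample: allele index 0 becomes the
#' REF base, 1 the first ALT base, and missing calls become N. The
#' concatenated alignment replaces the full sequence as input to
#' phylogenetic and skyline analyses; permuting scaffold order permutes
#' columns only, so per-sample base multisets and pairwise Hamming distances
#' are unchanged — scaffold order and orientation cannot affect downstream
#' results.
#'
#' @param tbl a `variant_table` of records that passed the cascade.
#' @param sample_order optional character vector ordering the output
#'   sequences (default: column order of the genotype matrix).
#' @return character matrix (samples x sites) of bases, with duplicated
#'   sites rejected.
#' @export
concat_snps <- function(tbl, sample_order = NULL) {
  s <- tbl$sites
  key <- paste(s$chrom, s$pos)
  if (anyDuplicated(key)) stop("duplicated site in input", call. = FALSE)
  samples <- colnames(tbl$gt)
  if (is.null(sample_order)) sample_order <- samples
  stopifnot(setequal(sample_order, samples))
  o <- order(s$chrom, s$pos)
  n_sites <- nrow(s)
  out <- matrix("N", length(sample_order), n_sites,
                dimnames = list(sample_order,
                                if (n_sites) key[o] else NULL))
  if (n_sites == 0L) return(out)
  alt1 <- vapply(strsplit(s$alt, ",", fixed = TRUE), `[`, character(1), 1L)
  for (ci in seq_len(n_sites)) {
    i <- o[ci]
    g <- tbl$gt[i, sample_order]
    col <- rep("N", length(g))
    col[g == "0"] <- s$ref[i]
    col[g == "1"] <- alt1[i]
    out[, ci] <- col
  }
  out
}

#' Write a concatenated SNP alignment as FASTA
#'
#' @param aln character matrix from [concat_snps()] (samples x sites).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_snp_alignment <- function(aln, path) {
  seqs <- apply(aln, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, rownames(aln))), filepath = path)
  invisible(path)
}
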