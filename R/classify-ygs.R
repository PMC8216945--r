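#' Build a k-mer dictionary from reads
#'
#' Collects the canonical 31-mers (by default) occurring at least `min_count`
#' times in a read set. The count floor suppresses k-mers created by
#' sequencing errors, which are overwhelmingly singletons at usual depths.
#'
#' @param reads character vector of read sequences.
#' @param k odd k-mer length >= 11 (default 31).
#' @param min_count minimum number of occurrences for inclusion (default 2).
#' @return character vector of canonical k-mers (the dictionary).
#' @export
kmer_dictionary <- function(reads, k = 31L, min_count = 2L) {
  stopifnot(k %% 2L == 1L, k >= 11L, min_count >= 1L)
  cnt <- count_kmers(reads, k)
  cnt$kmer[cnt$N >= min_count]
}

#' Single-copy (nonrepetitive) k-mers per scaffold
#'
#' The informative unit of YGS-style classification: canonical k-mers that
#' occur exactly once across the whole query scaffold pool (default) or
#' within each scaffold (`scope = "per_scaffold"`). K-mers containing N are
#' excluded. A scaffold shorter than `k` yields an empty set.
#'
#' @param sequences named character vector of scaffold sequences, or an
#'   `msy_genome`.
#' @param k odd k-mer length (default 31).
#' @param scope `"pool"` counts occurrences over all scaffolds;
#'   `"per_scaffold"` within each scaffold only.
#' @return named list of character vectors, one per scaffold.
#' @export
single_copy_kmers <- function(sequences, k = 31L,
                              scope = c("pool", "per_scaffold")) {
  scope <- match.arg(scope)
  if (inherits(sequences, "msy_genome")) sequences <- sequences$sequences
  per_scaf <- lapply(sequences, function(s) unique(canonical_kmers(s, k)))
  if (scope == "per_scaffold") {
    counts <- lapply(sequences, function(s) {
      cnt <- count_kmers(s, k)
      cnt$kmer[cnt$N == 1L]
    })
    return(counts)
  }
  pool <- count_kmers(unname(sequences), k)
  single <- pool$kmer[pool$N == 1L]
  lapply(per_scaf, function(km) km[km %in% single])
}

#' YGS profile of scaffolds against sexed read dictionaries
#'
#' For each scaffold, the percentage of its single-copy k-mers found in the
#' female and male read dictionaries. Y-linked sequence is absent from the
#' female genome, so its single-copy k-mers go unmatched by female reads
#' while matching male reads almost completely. Scaffolds with no
#' single-copy k-mers have an undefined profile (`NA`).
#'
#' @param scaffold_kmers named list from [single_copy_kmers()].
#' @param female_dict,male_dict k-mer dictionaries from [kmer_dictionary()].
#' @return `data.frame` with columns `scaffold_id`, `n_single_copy_kmers`,
#'   `pct_matched_female`, `pct_matched_male`, `pct_unmatched_female`.
#' @export
ygs_profile <- function(scaffold_kmers, female_dict, male_dict) {
  n <- lengths(scaffold_kmers)
  pf <- pm <- rep(NA_real_, length(scaffold_kmers))
  ok <- n > 0L
  pf[ok] <- vapply(scaffold_kmers[ok], function(km) {
    100 * sum(km %in% female_dict) / length(km)
  }, numeric(1))
  pm[ok] <- vapply(scaffold_kmers[ok], function(km) {
    100 * sum(km %in% male_dict) / length(km)
  }, numeric(1))
  data.frame(scaffold_id = names(scaffold_kmers),
             n_single_copy_kmers = unname(n),
             pct_matched_female = unname(pf),
             pct_matched_male = unname(pm),
             pct_unmatched_female = unname(100 - pf),
             stringsAsFactors = FALSE)
}

#' Classify scaffolds by YGS profile
#'
#' A scaffold is called Y when its single-copy k-mers match the male read
#' dictionary at a rate above `male_min` percent and the female dictionary
#' below `female_max` percent. (The equivalent statement on the
#' female-unmatched axis is `pct_unmatched_female > 100 - female_max`.)
#' Scaffolds with an undefined profile are `undefined`.
#'
#' @param profile a `data.frame` from [ygs_profile()].
#' @param male_min male matched-percentage floor, exclusive (default 90).
#' @param female_max female matched-percentage ceiling, exclusive
#'   (default 10).
#' @return character vector over `Y`, `not-Y`, `undefined`, named by
#'   scaffold.
#' @export
classify_ygs <- function(profile, male_min = 90, female_max = 10) {
  call <- ifelse(is.na(profile$pct_matched_female), "undefined",
                 ifelse(profile$pct_matched_male > male_min &
                        profile$pct_matched_female < female_max,
                        "Y", "not-Y"))
  setNames(call, profile$scaffold_id)
}
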