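#' Derive male-specific seed regions from sexed coverage
#'
#' Given per-position read depths of known-male and known-female samples over
#' a Y-candidate scaffold, extracts the maximal runs where every male sample
#' is covered (depth >= `min_male_depth`) and every female sample is
#' effectively empty (depth <= `max_female_depth`), keeping runs of at least
#' `min_run_len` bp. The concatenated runs form the male seed sequence set
#' against which unsexed samples' mapping rates are computed.
#'
#' @param male_depth,female_depth numeric vectors or matrices (positions x
#'   samples) of per-position depth over the same scaffold coordinates, all
#'   positions present (zeros included).
#' @param scaffold_id scaffold name used in the output intervals.
#' @param min_male_depth minimum depth every male must reach (default 3).
#' @param max_female_depth maximum depth any female may show (default 0).
#' @param min_run_len minimum run length in bp (default 500).
#' @return a `data.frame` of intervals (`scaffold`, `start`, `end`; 0-based
#'   half-open) with attribute `total_len`. Empty, with a warning, when no
#'   run qualifies.
#' @export
derive_seed_regions <- function(male_depth, female_depth, scaffold_id = "scaffold",
                                min_male_depth = 3, max_female_depth = 0,
                                min_run_len = 500L) {
  male_depth <- as.matrix(male_depth)
  female_depth <- as.matrix(female_depth)
  if (nrow(male_depth) != nrow(female_depth)) {
    stop("male and female depth arrays must cover the same positions",
         call. = FALSE)
  }
  ok <- apply(male_depth >= min_male_depth, 1L, all) &
    apply(female_depth <= max_female_depth, 1L, all)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_len
  out <- data.frame(scaffold = rep(scaffold_id, sum(keep)),
                    start = starts[keep] - 1L, end = ends[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    warning("no run satisfies the seed-region criteria", call. = FALSE)
  }
  attr(out, "total_len") <- sum(out$end - out$start)
  out
}

#' Write seed regions as BED
#'
#' @param regions result of [derive_seed_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seed_bed <- function(regions, path) {
  write.table(regions[, c("scaffold", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mapping rate of a sample against the seed sequences
#'
#' @param mapped_reads number of reads mapping to the male seed sequences.
#' @param total_reads total reads of the sample; must be positive.
#' @return the mapping rate as a percentage, `100 * mapped / total`.
#' @export
mapping_rate <- function(mapped_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive", call. = FALSE)
  100 * mapped_reads / total_reads
}

#' Sex-calling thresholds on the seed mapping rate
#'
#' Defaults reproduce the validated separation on a goat panel: every known
#' male mapped at a rate above 0.04% while every known female mapped at
#' 0.00%, so rates above `male_min` are called male, rates at or below
#' `female_max` female, and anything in between ambiguous (such samples are
#' excluded from downstream analysis rather than guessed).
#'
#' @param male_min lower bound (exclusive) of the male mapping rate, in
#'   percent.
#' @param female_max upper bound (inclusive) of the female mapping rate, in
#'   percent; must be below `male_min`.
#' @return an object of class `sex_thresholds`.
#' @export
sex_thresholds <- function(male_min = 0.04, female_max = 0.00) {
  stopifnot(female_max < male_min)
  structure(list(male_min = male_min, female_max = female_max),
            class = "sex_thresholds")
}

#' Call sample sex from a seed mapping rate
#'
#' @param rate mapping rate(s) in percent.
#' @param thresholds a [sex_thresholds()].
#' @return character vector over `male`, `female`, `ambiguous`.
#' @export
call_sex <- function(rate, thresholds = sex_thresholds()) {
  stopifnot(inherits(thresholds, "sex_thresholds"),
            all(rate >= 0), all(rate <= 100))
  ifelse(rate > thresholds$male_min, "male",
         ifelse(rate <= thresholds$female_max, "female", "ambiguous"))
}

#' Test separation of male and female mapping rates
#'
#' Two-sample Welch t-test on the seed mapping rates of known-sex samples,
#' used to validate that the thresholds separate the sexes. When both groups
#' are degenerate (zero variance), the p-value is 1 if the means are equal
#' and 0 otherwise (perfect separation of constants).
#'
#' @param rates_male,rates_female numeric vectors of mapping rates, each of
#'   length >= 2.
#' @return the p-value.
#' @export
threshold_separation_test <- function(rates_male, rates_female) {
  stopifnot(length(rates_male) >= 2L, length(rates_female) >= 2L)
  v1 <- stats::var(rates_male)
  v2 <- stats::var(rates_female)
  if (v1 == 0 && v2 == 0) {
    return(if (mean(rates_male) == mean(rates_female)) 1 else 0)
  }
  t.test(rates_male, rates_female, var.equal = FALSE)$p.value
}

#' Count reads hitting the seed sequences (k-mer pseudo-mapper)
#'
#' A lightweight stand-in for an aligner in simulated end-to-end runs: a read
#' is counted as mapped when it shares at least one canonical k-mer with the
#' seed sequences. With k = 31 a spurious hit requires an exact 31-bp match,
#' so reads of a female sample essentially never hit male-specific seeds.
#'
#' @param reads character vector of read sequences.
#' @param seeds character vector of seed sequences.
#' @param k k-mer length (default 31).
#' @return the number of reads with at least one seed k-mer hit.
#' @export
count_seed_hits <- function(reads, seeds, k = 31L) {
  if (length(reads) == 0L) return(0L)
  seed_km <- unique(canonical_kmers(seeds, k))
  kml <- lapply(reads, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else substring(s, 1:(L - k + 1L), k:L)
  })
  idx <- rep(seq_along(reads), lengths(kml))
  km <- unlist(kml, use.names = FALSE)
  keep <- !grepl("N", km, fixed = TRUE)
  km <- km[keep]; idx <- idx[keep]
  if (length(km) == 0L) return(0L)
  rc <- reverse_complement(km)
  canon <- ifelse(km <= rc, km, rc)
  length(unique(idx[canon %in% seed_km]))
}
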