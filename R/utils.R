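#' @importFrom stats optim rbinom rlnorm rpois runif setNames t.test
#' @importFrom utils combn head tail write.table
NULL

.datatable.aware <- TRUE

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# state afterwards. All generators funnel through this so that a spec + seed
# is a pure function.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Extract canonical k-mers from sequences
#'
#' Slides a window of width `k` over each sequence and returns every k-mer in
#' canonical form (the lexicographically smaller of the k-mer and its reverse
#' complement). K-mers containing an ambiguous base (N) are dropped, as is
#' standard for k-mer dictionaries.
#'
#' @param seqs character vector of nucleotide sequences (A/C/G/T/N).
#' @param k odd k-mer length, default 31.
#' @return character vector of canonical k-mers, one entry per window
#'   (duplicates retained so callers can count occurrences).
#' @export
canonical_kmers <- function(seqs, k = 31L) {
  stopifnot(k >= 1L)
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  km <- unlist(out, use.names = FALSE)
  if (length(km) == 0L) return(character(0))
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  ifelse(km <= rc, km, rc)
}

# Count canonical k-mers; returns a data.table with columns kmer, N.
count_kmers <- function(seqs, k = 31L) {
  km <- canonical_kmers(seqs, k)
  if (length(km) == 0L) {
    return(data.table::data.table(kmer = character(0), N = integer(0)))
  }
  dt <- data.table::data.table(kmer = km)
  dt[, list(N = .N), by = "kmer"]
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Copy-number of a scaffold origin for a given sex, per haploid genome pair:
# autosomes 2/2, X 2/1 (female/male), Y 0/1.
copy_number <- function(origin, sex) {
  sex <- match.arg(sex, c("female", "male"))
  cn <- switch(sex,
    female = c(A = 2, X = 2, Y = 0),
    male   = c(A = 2, X = 1, Y = 1)
  )
  unname(cn[origin])
}
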