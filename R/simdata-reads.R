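#' Sample sequencing reads from a synthetic genome
#'
#' Draws single-end reads uniformly along each scaffold, weighted by the
#' scaffold's copy number for the requested sex (so a female sample yields no
#' reads from Y scaffolds and twice the X reads of a male). Read strands are
#' random and per-base substitution errors are introduced at `error_rate`.
#' X-homology leakage needs no special handling at read level: reads from the
#' X source of a copied block share its sequence up to the block's per-base
#' identity, which is exactly how female reads come to match Y k-mers.
#'
#' @param genome an `msy_genome`.
#' @param sex `"female"` or `"male"`.
#' @param depth target x-coverage of a two-copy scaffold (a one-copy scaffold
#'   receives half of it).
#' @param read_len read length in bp; must not exceed the shortest scaffold.
#' @param error_rate per-base substitution probability.
#' @param seed random seed.
#' @param fastq optional path; when given, reads are also written as FASTQ.
#' @return a named character vector of read sequences with a `meta` attribute
#'   (`data.frame` of scaffold, 1-based start, strand) recording the true
#'   provenance of every read.
#' @export
sim_reads <- function(genome, sex = c("female", "male"), depth = 10,
                      read_len = 100L, error_rate = 0.01, seed = 1L,
                      fastq = NULL) {
  stopifnot(inherits(genome, "msy_genome"), depth > 0,
            error_rate >= 0, error_rate <= 1)
  sex <- match.arg(sex)
  sc <- genome$scaffolds
  # the placed-X segment backing an X-homologous Y block is part of every
  # individual's genome even though it is not a query scaffold
  if (!is.null(genome$placed_x)) {
    sc <- rbind(sc, data.frame(id = names(genome$placed_x),
                               true_origin = "X",
                               length = nchar(genome$placed_x),
                               stringsAsFactors = FALSE))
  }
  seqs <- c(genome$sequences, genome$placed_x)
  if (read_len > min(sc$length)) {
    stop("read_len exceeds the shortest scaffold length", call. = FALSE)
  }
  cn <- copy_number(sc$true_origin, sex)
  with_seed(seed, {
    n_reads <- round(depth * cn / 2 * sc$length / read_len)
    keep <- which(n_reads > 0)
    pieces <- lapply(keep, function(i) {
      starts <- sample(sc$length[i] - read_len + 1L, n_reads[i], replace = TRUE)
      s <- substring(seqs[[sc$id[i]]], starts,
                     starts + read_len - 1L)
      data.frame(scaffold = sc$id[i], start = starts, seq = s,
                 stringsAsFactors = FALSE)
    })
    meta <- do.call(rbind, pieces)
    if (is.null(meta) || nrow(meta) == 0L) {
      reads <- character(0)
      meta <- data.frame(scaffold = character(0), start = integer(0),
                         strand = character(0))
    } else {
      strand <- sample(c("+", "-"), nrow(meta), replace = TRUE)
      reads <- meta$seq
      neg <- strand == "-"
      if (any(neg)) reads[neg] <- reverse_complement(reads[neg])
      if (error_rate > 0) {
        n_err <- rbinom(length(reads), read_len, error_rate)
        for (j in which(n_err > 0L)) {
          pos <- sample(read_len, n_err[j])
          cur <- substring(reads[j], pos, pos)
          new <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))
          for (t in seq_along(pos)) substr(reads[j], pos[t], pos[t]) <- new[t]
        }
      }
      meta <- data.frame(scaffold = meta$scaffold, start = meta$start,
                         strand = strand, stringsAsFactors = FALSE)
    }
    names(reads) <- sprintf("read_%s_%06d", sex, seq_along(reads))
    if (!is.null(fastq)) write_fastq(reads, fastq)
    attr(reads, "meta") <- meta
    reads
  })
}

#' Write reads as FASTQ
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(dss, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Per-position read coverage of one scaffold
#'
#' Reconstructs the depth at every position of a scaffold from the read
#' provenance recorded by [sim_reads()].
#'
#' @param reads result of [sim_reads()].
#' @param scaffold_id scaffold to profile.
#' @param scaffold_len its length in bp.
#' @param read_len read length used in the simulation.
#' @return integer vector of depth at positions 1..scaffold_len.
#' @export
position_depth <- function(reads, scaffold_id, scaffold_len, read_len = 100L) {
  meta <- attr(reads, "meta")
  stopifnot(!is.null(meta))
  starts <- meta$start[meta$scaffold == scaffold_id]
  cov <- integer(scaffold_len)
  if (length(starts) > 0) {
    d <- integer(scaffold_len + 1L)
    for (s in starts) {
      d[s] <- d[s] + 1L
      d[min(s + read_len, scaffold_len + 1L)] <-
        d[min(s + read_len, scaffold_len + 1L)] - 1L
    }
    cov <- cumsum(d[seq_len(scaffold_len)])
  }
  cov
}
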