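#' Specification for a synthetic genome of labelled scaffolds
#'
#' Describes a small genome whose scaffolds have a known chromosomal origin
#' (autosome, X or Y), optionally with one Y scaffold carrying a block copied
#' from an X scaffold at a given per-base identity. Such X-transposed blocks
#' are the reason read-depth classification of Y scaffolds needs a relaxed
#' cutoff: real Y chromosomes contain regions of ~99% identity to the X, onto
#' which female reads map.
#'
#' @param n_auto,n_x,n_y numbers of autosomal, X-linked and Y-linked
#'   scaffolds (all >= 0).
#' @param len_range length-2 integer vector, scaffold lengths are drawn
#'   uniformly from this range (bp).
#' @param xy_homology_fraction fraction (0-1) of one Y scaffold copied from
#'   an X scaffold. 0 disables the homologous block.
#' @param xy_identity per-base identity (0-1) of the copied block.
#' @param gc GC content of the random background sequence.
#' @param seed random seed; the same spec and seed give byte-identical output.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_auto = 5L, n_x = 3L, n_y = 3L,
                        len_range = c(2000L, 4000L),
                        xy_homology_fraction = 0, xy_identity = 0.99,
                        gc = 0.42, seed = 1L) {
  stopifnot(n_auto >= 0, n_x >= 0, n_y >= 0,
            length(len_range) == 2L, len_range[1] >= 1,
            len_range[2] >= len_range[1],
            xy_homology_fraction >= 0, xy_homology_fraction <= 1,
            xy_identity >= 0, xy_identity <= 1,
            gc > 0, gc < 1)
  if (xy_homology_fraction > 0 && (n_x < 1L || n_y < 1L)) {
    stop("xy_homology_fraction > 0 requires at least one X and one Y scaffold",
         call. = FALSE)
  }
  structure(list(n_auto = as.integer(n_auto), n_x = as.integer(n_x),
                 n_y = as.integer(n_y), len_range = as.integer(len_range),
                 xy_homology_fraction = xy_homology_fraction,
                 xy_identity = xy_identity, gc = gc, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome of labelled scaffolds
#'
#' Draws random scaffolds according to a [genome_spec()]. When
#' `xy_homology_fraction > 0`, the first Y scaffold receives a block copied
#' from the first X scaffold, degraded to `xy_identity` by random base
#' substitutions, mimicking an X-transposed region of the Y.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `msy_genome`: a list with `sequences` (named
#'   character vector of the unplaced query scaffolds), `scaffolds`
#'   (data.frame of id, true_origin, length), `homology` (NULL, or a list
#'   describing the copied block with 0-based half-open coordinates on the
#'   Y scaffold) and `placed_x` (NULL, or the pristine X-chromosome segment
#'   the block was copied from; part of every individual's genome but not of
#'   the query pool).
#' @export
sim_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    origins <- rep(c("A", "X", "Y"), c(spec$n_auto, spec$n_x, spec$n_y))
    n <- length(origins)
    ids <- sprintf("scaffold_%s_%02d", origins,
                   unlist(lapply(c(spec$n_auto, spec$n_x, spec$n_y), seq_len)))
    lens <- if (n > 0) {
      sample(seq(spec$len_range[1], spec$len_range[2]), n, replace = TRUE)
    } else integer(0)
    seqs <- vapply(lens, random_dna, character(1), gc = spec$gc)
    names(seqs) <- ids
    hom <- NULL
    placed_x <- NULL
    if (spec$xy_homology_fraction > 0) {
      # The X counterpart of an X-transposed Y block lives on the *placed* X
      # chromosome, not among the unplaced query scaffolds; it is carried
      # separately so reads cover it while the k-mer query pool does not
      # contain it.
      y_id <- ids[origins == "Y"][1L]
      y_len <- lens[match(y_id, ids)]
      block_len <- max(1L, round(spec$xy_homology_fraction * y_len))
      source_seq <- random_dna(block_len, gc = spec$gc)
      block <- source_seq
      # degrade the Y copy to the requested identity by random substitutions
      n_mut <- rbinom(1L, block_len, 1 - spec$xy_identity)
      if (n_mut > 0L) {
        pos <- sample(block_len, n_mut)
        cur <- substring(block, pos, pos)
        new <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
        for (i in seq_along(pos)) substr(block, pos[i], pos[i]) <- new[i]
      }
      y_start <- sample(y_len - block_len + 1L, 1L)
      y_seq <- seqs[[y_id]]
      substr(y_seq, y_start, y_start + block_len - 1L) <- block
      seqs[[y_id]] <- y_seq
      placed_x <- c(chrX_placed_segment = source_seq)
      hom <- list(y_scaffold = y_id, x_scaffold = "chrX_placed_segment",
                  y_start = y_start - 1L, y_end = y_start - 1L + block_len,
                  block_len = block_len, identity = spec$xy_identity,
                  fraction = spec$xy_homology_fraction)
    }
    structure(list(
      sequences = seqs,
      scaffolds = data.frame(id = ids, true_origin = origins,
                             length = lens, stringsAsFactors = FALSE),
      homology = hom,
      placed_x = placed_x,
      spec = spec
    ), class = "msy_genome")
  })
}

#' @export
print.msy_genome <- function(x, ...) {
  tab <- table(x$scaffolds$true_origin)
  cat("Synthetic genome:", nrow(x$scaffolds), "scaffolds (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "),",
      sum(x$scaffolds$length), "bp total\n")
  if (!is.null(x$homology)) {
    cat(sprintf("X-homologous block: %s[%d,%d) copied from %s at %.3f identity\n",
                x$homology$y_scaffold, x$homology$y_start, x$homology$y_end,
                x$homology$x_scaffold, x$homology$identity))
  }
  invisible(x)
}

#' Write scaffolds to a FASTA file
#'
#' @param genome an `msy_genome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "msy_genome"))
  dss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
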