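#' Simulate sexed per-scaffold read depths
#'
#' Emulates the mean mapped read depth a whole-genome library of a given sex
#' would produce on each scaffold, without running an aligner. The expected
#' mean depth of a scaffold is `target_depth * copy_number / 2`, where the
#' copy number is 2 for autosomes (both sexes), 2/1 for X (female/male) and
#' 0/1 for Y. An X-homologous block on a Y scaffold additionally receives
#' female depth `target_depth / 2 * xy_identity` over the block (cross-mapping
#' of female X reads onto the near-identical Y copy), so the scaffold-mean
#' female depth of the homologous Y scaffold is
#' `target_depth / 2 * fraction * identity`.
#'
#' Depth noise is modelled as a scaffold-intrinsic multiplicative lognormal
#' mappability factor (mean 1, coefficient of variation `noise_cv`). The
#' factor is a function of the seed and the scaffold only, not of the sample
#' sex: mappability and GC bias affect every library aligned to a scaffold in
#' the same way, which is why depth *ratios* between samples are so much
#' better behaved than raw depths. Simulating both sexes with the same seed
#' therefore reproduces the shared bias; different seeds give independent
#' factors.
#'
#' @param genome an `msy_genome` from [sim_genome()].
#' @param sex `"female"` or `"male"`.
#' @param target_depth expected depth (x-coverage) of a two-copy scaffold.
#' @param noise_cv coefficient of variation of the lognormal mappability
#'   factor; 0 disables noise.
#' @param seed random seed.
#' @param read_len nominal read length used to convert depth to a total
#'   mapped-read count for normalisation.
#' @return a `data.frame` with columns `scaffold_id`, `length`, `mean_depth`
#'   and `total_mapped_reads` (the same total on every row), with attributes
#'   `sex` and `target_depth`.
#' @export
sim_depths <- function(genome, sex = c("female", "male"), target_depth = 30,
                       noise_cv = 0.1, seed = 1L, read_len = 100L) {
  stopifnot(inherits(genome, "msy_genome"), target_depth > 0, noise_cv >= 0)
  sex <- match.arg(sex)
  sc <- genome$scaffolds
  cn <- copy_number(sc$true_origin, sex)
  mean_depth <- target_depth * cn / 2
  if (sex == "female" && !is.null(genome$homology)) {
    h <- genome$homology
    i <- match(h$y_scaffold, sc$id)
    leak <- (target_depth / 2) * h$identity * h$block_len / sc$length[i]
    mean_depth[i] <- mean_depth[i] + leak
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- with_seed(seed,
                     rlnorm(nrow(sc), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    mean_depth <- mean_depth * fac
  }
  # library size: a whole-genome library sequenced to target_depth on the
  # two-copy loci contributes reads in proportion to depth x genome size;
  # equal target depths give equal totals, so norm cancels library size only
  total_reads <- max(1L, round(target_depth * sum(sc$length) / read_len))
  out <- data.frame(scaffold_id = sc$id, length = sc$length,
                    mean_depth = mean_depth,
                    total_mapped_reads = total_reads,
                    stringsAsFactors = FALSE)
  attr(out, "sex") <- sex
  attr(out, "target_depth") <- target_depth
  out
}

#' Combine female and male depth tables into a depth profile
#'
#' Builds the per-scaffold profile consumed by [ad_ratio()]: the female and
#' male mean depths (over all positions, zeros included) and the two
#' libraries' total mapped-read counts used for normalisation.
#'
#' @param female,male depth tables as produced by [sim_depths()] or read with
#'   [read_depth_table()]; both must cover the same scaffolds.
#' @return a `data.frame` with columns `scaffold_id`, `length`,
#'   `mean_depth_female`, `mean_depth_male` and attributes
#'   `total_reads_female`, `total_reads_male`.
#' @export
depth_profile <- function(female, male) {
  need <- c("scaffold_id", "length", "mean_depth", "total_mapped_reads")
  stopifnot(all(need %in% names(female)), all(need %in% names(male)))
  if (!setequal(female$scaffold_id, male$scaffold_id)) {
    stop("female and male depth tables cover different scaffolds", call. = FALSE)
  }
  m <- male[match(female$scaffold_id, male$scaffold_id), ]
  tot_f <- female$total_mapped_reads[1L]
  tot_m <- m$total_mapped_reads[1L]
  stopifnot(tot_f > 0, tot_m > 0)
  out <- data.frame(scaffold_id = female$scaffold_id,
                    length = female$length,
                    mean_depth_female = female$mean_depth,
                    mean_depth_male = m$mean_depth,
                    stringsAsFactors = FALSE)
  attr(out, "total_reads_female") <- tot_f
  attr(out, "total_reads_male") <- tot_m
  out
}

#' Read or write a per-scaffold depth table
#'
#' Tab-separated with header `scaffold_id length mean_depth
#' total_mapped_reads`.
#'
#' @param path file path.
#' @return for the reader, the depth table as a `data.frame`.
#' @export
read_depth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_depth_table
#' @param depths a depth table.
#' @export
write_depth_table <- function(depths, path) {
  write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
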