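#' Specification for a simulated haploid VCF
#'
#' Describes a VCF of Y-chromosome SNP calls with a known number of records
#' seeded to violate each stage of the quality cascade: the six hard-filter
#' annotations (QD, MQRankSum, FS, ReadPosRankSum, MQ, SOR), multiallelic
#' sites, low minor-allele-frequency sites, low call-rate sites, and sites
#' that also appear on a female-observed exclusion list. Seeded violation
#' sites are mutually disjoint, so the number of surviving records is known
#' by construction.
#'
#' @param n_sites number of VCF records.
#' @param n_samples number of (haploid) samples; at least 8, and at least 21
#'   when MAF violations are requested (a minor-allele count of 1 must be
#'   able to fall below 5%).
#' @param ploidy 1 (Y mode) or 2; only haploid genotypes are simulated.
#' @param maf_range clean sites draw their minor-allele frequency uniformly
#'   from this range (then realised as an exact allele count).
#' @param missing_rate per-genotype missing probability at clean sites,
#'   truncated so clean sites always keep call rate >= 90%.
#' @param n_violations named integer vector; recognised names are
#'   `QD`, `MQRankSum`, `FS`, `ReadPosRankSum`, `MQ`, `SOR`,
#'   `multiallelic`, `maf`, `call_rate`. Omitted names count 0.
#' @param n_female_leak_sites number of otherwise-clean sites also placed on
#'   the female-observed exclusion list.
#' @param absent_info_rate probability that a clean site omits its rank-sum
#'   annotations (absent annotations must not trigger a hard filter).
#' @param seed random seed.
#' @return an object of class `vcf_sim_spec`.
#' @export
vcf_sim_spec <- function(n_sites = 100L, n_samples = 24L, ploidy = 1L,
                         maf_range = c(0.05, 0.5), missing_rate = 0.02,
                         n_violations = integer(0), n_female_leak_sites = 0L,
                         absent_info_rate = 0.1, seed = 1L) {
  known <- c("QD", "MQRankSum", "FS", "ReadPosRankSum", "MQ", "SOR",
             "multiallelic", "maf", "call_rate")
  v <- setNames(integer(length(known)), known)
  if (length(n_violations)) {
    bad <- setdiff(names(n_violations), known)
    if (length(bad)) stop("unknown filter name(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    v[names(n_violations)] <- as.integer(n_violations)
  }
  stopifnot(n_sites >= 0, n_samples >= 8L, ploidy %in% c(1L, 2L),
            all(v >= 0), n_female_leak_sites >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (v[["maf"]] > 0 && n_samples < 21L) {
    stop("MAF violations require at least 21 samples", call. = FALSE)
  }
  if (sum(v) + n_female_leak_sites > n_sites) {
    stop("more seeded violations than sites", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_samples = as.integer(n_samples), ploidy = as.integer(ploidy),
                 maf_range = maf_range, missing_rate = missing_rate,
                 n_violations = v,
                 n_female_leak_sites = as.integer(n_female_leak_sites),
                 absent_info_rate = absent_info_rate, seed = as.integer(seed)),
            class = "vcf_sim_spec")
}

# draw a clean genotype column set for one site: biallelic, MAF >= 0.05,
# call rate >= 90%
.sim_clean_gt <- function(n, maf_range, missing_rate) {
  max_miss <- floor(0.1 * n)
  n_miss <- min(rbinom(1L, n, missing_rate), max_miss)
  m <- n - n_miss
  k_lo <- max(1L, ceiling(0.05 * m))
  k <- round(runif(1L, maf_range[1], maf_range[2]) * m)
  k <- min(max(k, k_lo), m - k_lo)
  gt <- c(rep("1", k), rep("0", m - k), rep(".", n_miss))
  sample(gt)
}

#' Simulate a haploid VCF with seeded filter violations
#'
#' Realises a [vcf_sim_spec()]: clean records pass every stage of the filter
#' cascade; each seeded record violates exactly one stage. The expected
#' survivor count is `n_sites` minus all seeded records (hard-filter,
#' multiallelic, MAF, call-rate, and female-leak sites), known by
#' construction.
#'
#' @param spec a [vcf_sim_spec()].
#' @return a list of class `vcf_sim`: `sites` (data.frame with chrom, pos,
#'   ref, alt and the six INFO annotations, NA = absent), `gt` (character
#'   matrix sites x samples with entries "0", "1", "2", "."),
#'   `exclusion_sites` (data.frame chrom/pos of female-observed sites),
#'   `expected_survivors`, `seeded` (list of row indices per category) and
#'   `spec`.
#' @export
sim_vcf <- function(spec) {
  stopifnot(inherits(spec, "vcf_sim_spec"))
  n <- spec$n_sites
  ns <- spec$n_samples
  with_seed(spec$seed, {
    chrom <- sample(c("Y_scaffold_1", "Y_scaffold_2"), n, replace = TRUE)
    pos <- integer(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample(1e6L, length(idx)))
    }
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1))

    # clean INFO annotations, comfortably inside the pass region
    info <- data.frame(
      QD = runif(n, 5, 30), MQRankSum = runif(n, -3, 3),
      FS = runif(n, 0, 20), ReadPosRankSum = runif(n, -3, 3),
      MQ = runif(n, 50, 60), SOR = runif(n, 0.5, 2.5))

    gt <- matrix("0", n, ns,
                 dimnames = list(NULL, sprintf("sample%03d", seq_len(ns))))
    for (i in seq_len(n)) {
      gt[i, ] <- .sim_clean_gt(ns, spec$maf_range, spec$missing_rate)
    }

    # assign disjoint seeded categories to shuffled rows
    v <- spec$n_violations
    cats <- c(names(v)[v > 0], if (spec$n_female_leak_sites > 0) "female_leak")
    counts <- c(v[v > 0], if (spec$n_female_leak_sites > 0)
      c(female_leak = spec$n_female_leak_sites))
    rows <- sample(n, sum(counts))
    seeded <- split(rows, rep(cats, counts))

    fail_draw <- list(
      QD = function(k) runif(k, 0, 1.9),
      MQRankSum = function(k) runif(k, -20, -12.6),
      FS = function(k) runif(k, 60.1, 120),
      ReadPosRankSum = function(k) runif(k, -15, -8.1),
      MQ = function(k) runif(k, 10, 39.9),
      SOR = function(k) runif(k, 3.1, 6))
    for (f in intersect(names(seeded), names(fail_draw))) {
      info[seeded[[f]], f] <- fail_draw[[f]](length(seeded[[f]]))
    }
    if (!is.null(seeded$multiallelic)) {
      for (i in seeded$multiallelic) {
        alt2 <- sample(setdiff(DNA_BASES, c(ref[i], alt[i])), 1L)
        alt[i] <- paste(alt[i], alt2, sep = ",")
        g <- gt[i, ]
        # take second-alt carriers from the reference calls so that all three
        # alleles stay observed and the site is genuinely triallelic
        zeros <- which(g == "0")
        n2 <- min(max(1L, sum(g != ".") %/% 5L), length(zeros) - 1L)
        g[sample(zeros, n2)] <- "2"
        gt[i, ] <- g
      }
    }
    if (!is.null(seeded$maf)) {
      for (i in seeded$maf) {
        k <- sample(max(1L, ceiling(0.05 * ns) - 1L), 1L)
        gt[i, ] <- sample(c(rep("1", k), rep("0", ns - k)))
      }
    }
    if (!is.null(seeded$call_rate)) {
      for (i in seeded$call_rate) {
        n_miss <- floor(0.1 * ns) + 1L
        m <- ns - n_miss
        k <- max(1L, ceiling(0.05 * m))
        gt[i, ] <- sample(c(rep("1", k), rep("0", m - k), rep(".", n_miss)))
      }
    }

    # clean sites occasionally lack their rank-sum annotations
    clean <- setdiff(seq_len(n), unlist(seeded))
    if (spec$absent_info_rate > 0 && length(clean)) {
      drop <- clean[runif(length(clean)) < spec$absent_info_rate]
      info$MQRankSum[drop] <- NA_real_
      info$ReadPosRankSum[drop] <- NA_real_
    }

    leak <- seeded$female_leak
    exclusion <- data.frame(chrom = chrom[leak], pos = pos[leak],
                            stringsAsFactors = FALSE)
    sites <- cbind(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                              stringsAsFactors = FALSE), info)
    structure(list(sites = sites, gt = gt, exclusion_sites = exclusion,
                   expected_survivors = n - sum(counts),
                   seeded = seeded, spec = spec),
              class = "vcf_sim")
  })
}

#' Write a simulated VCF (v4.2) and its female-site exclusion list
#'
#' @param sim a `vcf_sim` from [sim_vcf()].
#' @param path output VCF path.
#' @param exclusion_path optional path for the two-column (chrom, pos)
#'   exclusion list.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sim, path, exclusion_path = NULL) {
  stopifnot(inherits(sim, "vcf_sim"))
  s <- sim$sites
  info_fields <- c("QD", "MQRankSum", "FS", "ReadPosRankSum", "MQ", "SOR")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=1000000>", unique(s$chrom)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_fields, info_fields),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(sim$gt)), collapse = "\t"))
  info_str <- vapply(seq_len(nrow(s)), function(i) {
    vals <- unlist(s[i, info_fields])
    ok <- !is.na(vals)
    paste(sprintf("%s=%.4g", info_fields[ok], vals[ok]), collapse = ";")
  }, character(1))
  info_str[info_str == ""] <- "."
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info_str,
                "GT", apply(sim$gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  if (!is.null(exclusion_path)) {
    write.table(sim$exclusion_sites, exclusion_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
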