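#' Default thresholds of the Y-SNP quality cascade
#'
#' Hard-filter thresholds follow the standard GATK-style expression
#' `QD < 2.0 || MQRankSum < -12.5 || FS > 60.0 || ReadPosRankSum < -8.0 ||
#' MQ < 40.0 || SOR > 3.0` (strict inequalities: a record sitting exactly on
#' a threshold passes). Site filters keep biallelic SNPs with minor allele
#' frequency >= `maf_min` and call rate >= `call_rate_min`, both inclusive.
#'
#' @param qd_min,mqranksum_min,fs_max,readpos_min,mq_min,sor_max hard-filter
#'   thresholds.
#' @param maf_min minimum minor allele frequency among non-missing calls
#'   (default 0.05, inclusive).
#' @param call_rate_min minimum non-missing fraction (default 0.90,
#'   inclusive).
#' @param biallelic_only keep only sites with exactly two observed alleles.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(qd_min = 2.0, mqranksum_min = -12.5, fs_max = 60.0,
                        readpos_min = -8.0, mq_min = 40.0, sor_max = 3.0,
                        maf_min = 0.05, call_rate_min = 0.90,
                        biallelic_only = TRUE) {
  vals <- c(qd_min, mqranksum_min, fs_max, readpos_min, mq_min, sor_max,
            maf_min, call_rate_min)
  stopifnot(all(is.finite(vals)))
  structure(list(qd_min = qd_min, mqranksum_min = mqranksum_min,
                 fs_max = fs_max, readpos_min = readpos_min, mq_min = mq_min,
                 sor_max = sor_max, maf_min = maf_min,
                 call_rate_min = call_rate_min,
                 biallelic_only = biallelic_only),
            class = "filter_spec")
}

#' Read a VCF into the variant-table representation
#'
#' Parses a VCF (v4.2) into the structure the filter cascade operates on:
#' a `sites` data.frame carrying the six hard-filter annotations (NA when
#' absent) and a haploid genotype matrix of allele indices
#' ("0", "1", "2", ".").
#'
#' @param path VCF file path.
#' @return list of class `variant_table` with elements `sites` and `gt`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info_fields <- c("QD", "MQRankSum", "FS", "ReadPosRankSum", "MQ", "SOR")
  info <- lapply(info_fields, function(f) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f)))
  })
  names(info) <- info_fields
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "."
  sites <- cbind(
    data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               ref = fix[, "REF"], alt = fix[, "ALT"],
               stringsAsFactors = FALSE),
    as.data.frame(info))
  rownames(sites) <- NULL
  dimnames(gt) <- list(NULL, colnames(gt))
  structure(list(sites = sites, gt = gt), class = "variant_table")
}

#' Coerce a simulated VCF to a variant table
#'
#' @param sim a `vcf_sim` from [sim_vcf()].
#' @return a `variant_table` (no file round-trip).
#' @export
as_variant_table <- function(sim) {
  stopifnot(inherits(sim, "vcf_sim"))
  structure(list(sites = sim$sites, gt = sim$gt), class = "variant_table")
}

#' Apply the hard filters to variant records
#'
#' A record fails when any annotation violates its threshold (strict
#' inequalities). An absent annotation never triggers its condition — the
#' rank-sum tests are undefined for sites without heterozygous evidence, and
#' skipping them is the conventional semantics of this filter. The reasons
#' column lists every violated field.
#'
#' @param tbl a `variant_table`.
#' @param spec a [filter_spec()].
#' @return `data.frame` with columns `pass` (logical) and `reasons`
#'   (comma-separated violated fields, "" when passing).
#' @export
hard_filter <- function(tbl, spec = filter_spec()) {
  s <- tbl$sites
  viol <- cbind(
    QD = !is.na(s$QD) & s$QD < spec$qd_min,
    MQRankSum = !is.na(s$MQRankSum) & s$MQRankSum < spec$mqranksum_min,
    FS = !is.na(s$FS) & s$FS > spec$fs_max,
    ReadPosRankSum = !is.na(s$ReadPosRankSum) &
      s$ReadPosRankSum < spec$readpos_min,
    MQ = !is.na(s$MQ) & s$MQ < spec$mq_min,
    SOR = !is.na(s$SOR) & s$SOR > spec$sor_max)
  reasons <- apply(viol, 1L, function(x) paste(colnames(viol)[x], collapse = ","))
  data.frame(pass = rowSums(viol) == 0L, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Remove sites observed in female samples
#'
#' A haploid Y call at a site where female samples also show variation marks
#' an ambiguous or misassembled region; such sites are removed by exact
#' (chrom, pos) match. The operation is idempotent.
#'
#' @param tbl a `variant_table`.
#' @param female_sites `data.frame` with columns `chrom` and `pos`.
#' @return the filtered `variant_table`, with attribute `n_removed`.
#' @export
exclude_female_sites <- function(tbl, female_sites) {
  key <- paste(tbl$sites$chrom, tbl$sites$pos)
  bad <- key %in% paste(female_sites$chrom, female_sites$pos)
  out <- structure(list(sites = tbl$sites[!bad, , drop = FALSE],
                        gt = tbl$gt[!bad, , drop = FALSE]),
                   class = "variant_table")
  attr(out, "n_removed") <- sum(bad)
  out
}

# per-site summaries of a haploid genotype matrix
.site_gt_stats <- function(gt) {
  n <- ncol(gt)
  t(apply(gt, 1L, function(g) {
    obs <- g[g != "."]
    alleles <- unique(obs)
    counts <- table(obs)
    maf <- if (length(alleles) < 2L || length(obs) == 0L) 0 else
      min(counts) / length(obs)
    c(n_alleles = length(alleles), call_rate = length(obs) / n, maf = maf)
  }))
}

#' Biallelic / MAF / call-rate site filters
#'
#' Keeps sites with exactly two observed alleles, minor allele frequency at
#' least `maf_min` among non-missing haploid calls, and a non-missing
#' fraction of at least `call_rate_min` (both bounds inclusive).
#'
#' @param tbl a `variant_table`.
#' @param spec a [filter_spec()].
#' @return logical vector, `TRUE` for kept sites.
#' @export
site_filters <- function(tbl, spec = filter_spec()) {
  st <- .site_gt_stats(tbl$gt)
  keep <- st[, "call_rate"] >= spec$call_rate_min &
    st[, "maf"] >= spec$maf_min
  if (spec$biallelic_only) keep <- keep & st[, "n_alleles"] == 2L
  unname(keep)
}

#' Run the full Y-SNP quality cascade
#'
#' Hard filters, then female-site exclusion, then the biallelic/MAF/call-rate
#' site filters. The hard and site filters act on disjoint record features,
#' so their order does not change the surviving set.
#'
#' @param tbl a `variant_table`.
#' @param female_sites optional `data.frame` (chrom, pos) of female-observed
#'   sites.
#' @param spec a [filter_spec()].
#' @return list with `survivors` (a `variant_table`), and `counts`
#'   (named vector: input, fail_hard, fail_female, fail_site, survivors).
#' @export
filter_cascade <- function(tbl, female_sites = NULL, spec = filter_spec()) {
  n0 <- nrow(tbl$sites)
  hf <- hard_filter(tbl, spec)
  tbl1 <- structure(list(sites = tbl$sites[hf$pass, , drop = FALSE],
                         gt = tbl$gt[hf$pass, , drop = FALSE]),
                    class = "variant_table")
  n_fem <- 0L
  if (!is.null(female_sites) && nrow(female_sites) > 0L) {
    tbl1 <- exclude_female_sites(tbl1, female_sites)
    n_fem <- attr(tbl1, "n_removed")
  }
  keep <- site_filters(tbl1, spec)
  out <- structure(list(sites = tbl1$sites[keep, , drop = FALSE],
                        gt = tbl1$gt[keep, , drop = FALSE]),
                   class = "variant_table")
  list(survivors = out,
       counts = c(input = n0, fail_hard = sum(!hf$pass), fail_female = n_fem,
                  fail_site = sum(!keep), survivors = nrow(out$sites)))
}
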