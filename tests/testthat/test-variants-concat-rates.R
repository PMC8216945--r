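make_tbl <- function(sites, gt) {
  structure(list(sites = sites, gt = gt), class = "variant_table")
}

test_that("concatenation transcribes genotypes into bases in site order", {
  s <- data.frame(chrom = c("sc2", "sc1"), pos = c(10L, 5L),
                  ref = c("A", "C"), alt = c("G", "T"),
                  QD = 10, MQRankSum = 0, FS = 1, ReadPosRankSum = 0,
                  MQ = 55, SOR = 1, stringsAsFactors = FALSE)
  gt <- matrix(c("0", "1", ".",
                 "1", "0", "1"), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("sa", "sb", "sc")))
  aln <- concat_snps(make_tbl(s, gt))
  # sc1:5 sorts before sc2:10
  expect_equal(dim(aln), c(3L, 2L))
  expect_equal(unname(aln["sa", ]), c("T", "A"))
  expect_equal(unname(aln["sb", ]), c("C", "G"))
  expect_equal(unname(aln["sc", ]), c("T", "N"))

  # empty input gives an empty alignment with all samples
  aln0 <- concat_snps(make_tbl(s[0, ], gt[0, , drop = FALSE]))
  expect_equal(dim(aln0), c(3L, 0L))

  s2 <- s; s2$chrom <- "sc1"; s2$pos <- c(5L, 5L)
  expect_error(concat_snps(make_tbl(s2, gt)), "duplicated")
})

test_that("pairwise Hamming distances are invariant under scaffold reordering", {
  spec <- vcf_sim_spec(n_sites = 40L, n_samples = 12L, seed = 8L)
  sim <- sim_vcf(spec)
  tbl <- as_variant_table(sim)
  aln <- concat_snps(tbl)
  # relabel the scaffolds so their sort order flips, then rebuild
  s2 <- tbl$sites
  s2$chrom <- ifelse(s2$chrom == "Y_scaffold_1", "Z_scaffold_9", s2$chrom)
  aln2 <- concat_snps(make_tbl(s2, tbl$gt))
  ham <- function(a) outer(seq_len(nrow(a)), seq_len(nrow(a)),
                           Vectorize(function(i, j) sum(a[i, ] != a[j, ])))
  expect_equal(ham(aln), ham(aln2))
  # per-sample base multisets unchanged
  for (i in seq_len(nrow(aln))) {
    expect_equal(sort(aln[i, ]), sort(aln2[i, ]), ignore_attr = TRUE)
  }
  fa <- tempfile(fileext = ".fa")
  write_snp_alignment(aln, fa)
  out <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(out), nrow(aln))
  expect_equal(unname(Biostrings::width(out)), rep(ncol(aln), nrow(aln)))
})

test_that("the Y per-year rate follows the male-bias formula", {
  expect_equal(y_rate_per_year(rate_spec(1.3e-8, 2.0, 2)), 8.67e-9,
               tolerance = 5e-4)
  expect_equal(y_rate_per_year(rate_spec(1.3e-8, 1, 2)), 1.3e-8 / 2)
  # alpha -> Inf approaches twice the autosomal per-year rate
  expect_equal(y_rate_per_year(rate_spec(1.3e-8, 1e9, 2)), 2 * 1.3e-8 / 2,
               tolerance = 1e-6)
  # monotone increasing in alpha
  rates <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
    y_rate_per_year(rate_spec(alpha = a))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_error(rate_spec(gen_time = 0))
})

test_that("concatenated-SNP rescaling multiplies by monitored bases per column", {
  expect_equal(rescale_rate_for_concat(1e-9, 1000, 10), 1e-7)
  expect_equal(rescale_rate_for_concat(3.3e-9, 500, 500), 3.3e-9)
  rep <- rate_report(rate_spec(seq_len = 5.69e6, n_snp = 6914))
  expect_equal(unname(rep["concat_rate_per_year"]), 7.14e-6, tolerance = 0.01)
})
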