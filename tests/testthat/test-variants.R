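make_tbl <- function(sites, gt) {
  structure(list(sites = sites, gt = gt), class = "variant_table")
}

clean_site <- function(n = 1) {
  data.frame(chrom = "Y_scaffold_1", pos = seq_len(n) * 100L, ref = "A",
             alt = "G", QD = 10, MQRankSum = 0, FS = 1, ReadPosRankSum = 0,
             MQ = 55, SOR = 1, stringsAsFactors = FALSE)
}

test_that("hard filters fail only strict threshold violations and report reasons", {
  s <- clean_site(3)
  s$QD[2] <- 1.0
  # record 3 sits exactly on every threshold: passes (strict inequalities)
  s$QD[3] <- 2.0; s$MQRankSum[3] <- -12.5; s$FS[3] <- 60.0
  s$ReadPosRankSum[3] <- -8.0; s$MQ[3] <- 40.0; s$SOR[3] <- 3.0
  gt <- matrix("0", 3, 10)
  hf <- hard_filter(make_tbl(s, gt))
  expect_equal(hf$pass, c(TRUE, FALSE, TRUE))
  expect_equal(hf$reasons[2], "QD")

  # multiple violations list all fields
  s$MQ[2] <- 10
  hf2 <- hard_filter(make_tbl(s, gt))
  expect_equal(hf2$reasons[2], "QD,MQ")

  # absent annotations never trigger
  s3 <- clean_site(1)
  s3$MQRankSum <- NA_real_; s3$ReadPosRankSum <- NA_real_
  expect_true(hard_filter(make_tbl(s3, matrix("0", 1, 10)))$pass)
})

test_that("female-site exclusion is exact and idempotent", {
  s <- clean_site(4)
  gt <- matrix("0", 4, 6)
  tbl <- make_tbl(s, gt)
  expect_equal(nrow(exclude_female_sites(tbl, s[0, c("chrom", "pos")])$sites), 4L)
  all_gone <- exclude_female_sites(tbl, s[, c("chrom", "pos")])
  expect_equal(nrow(all_gone$sites), 0L)

  excl <- s[2, c("chrom", "pos")]
  once <- exclude_female_sites(tbl, excl)
  twice <- exclude_female_sites(once, excl)
  expect_equal(attr(once, "n_removed"), 1L)
  expect_equal(attr(twice, "n_removed"), 0L)
  expect_identical(once$sites, twice$sites)
})

test_that("site filters apply biallelic, MAF and call-rate rules with stated inclusivity", {
  s <- clean_site(4)
  gt <- matrix("0", 4, 96, dimnames = list(NULL, sprintf("s%d", 1:96)))
  gt[1, 1:4] <- "1"                       # MAF 4/96 < 0.05 -> removed
  gt[2, 1:5] <- "1"                       # MAF 5/96 >= 0.05 -> kept
  gt[3, 1:20] <- "1"; gt[3, 21:22] <- "2" # triallelic -> removed
  gt[4, 1:20] <- "1"
  keep <- site_filters(make_tbl(s, gt))
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))

  # exactly 10% missing keeps the site (call rate >= 90% inclusive)
  gt2 <- matrix("0", 2, 40)
  gt2[1, 1:4] <- "."; gt2[1, 5:20] <- "1"
  gt2[2, 1:5] <- "."; gt2[2, 6:20] <- "1"   # 12.5% missing -> removed
  keep2 <- site_filters(make_tbl(clean_site(2), gt2))
  expect_equal(keep2, c(TRUE, FALSE))

  # MAF exactly at 0.05 is kept
  gt3 <- matrix("0", 1, 20); gt3[1, 1] <- "1"
  expect_true(site_filters(make_tbl(clean_site(1), gt3)))
})

test_that("the cascade is order-independent across its disjoint stages", {
  spec <- vcf_sim_spec(n_sites = 60L, n_samples = 24L,
                       n_violations = c(QD = 6L, FS = 4L, maf = 3L,
                                        call_rate = 3L, multiallelic = 2L),
                       n_female_leak_sites = 4L, seed = 21L)
  sim <- sim_vcf(spec)
  tbl <- as_variant_table(sim)
  fs <- filter_spec()

  # hard then site
  hf <- hard_filter(tbl, fs)
  t1 <- make_tbl(tbl$sites[hf$pass, ], tbl$gt[hf$pass, , drop = FALSE])
  k1 <- site_filters(t1, fs)
  surv_a <- paste(t1$sites$chrom[k1], t1$sites$pos[k1])

  # site then hard
  k2 <- site_filters(tbl, fs)
  t2 <- make_tbl(tbl$sites[k2, ], tbl$gt[k2, , drop = FALSE])
  hf2 <- hard_filter(t2, fs)
  surv_b <- paste(t2$sites$chrom[hf2$pass], t2$sites$pos[hf2$pass])

  expect_setequal(surv_a, surv_b)
})

test_that("survivor counts match the per-record replay oracle on random specs", {
  set.seed(77)
  for (i in 1:25) {
    spec <- vcf_sim_spec(
      n_sites = sample(20:60, 1), n_samples = sample(c(24L, 30L, 48L), 1),
      missing_rate = runif(1, 0, 0.05),
      n_violations = c(QD = sample(0:3, 1), MQRankSum = sample(0:2, 1),
                       FS = sample(0:2, 1), ReadPosRankSum = sample(0:2, 1),
                       MQ = sample(0:2, 1), SOR = sample(0:2, 1),
                       maf = sample(0:2, 1), call_rate = sample(0:2, 1),
                       multiallelic = sample(0:2, 1)),
      n_female_leak_sites = sample(0:3, 1), seed = 1000L + i)
    sim <- sim_vcf(spec)
    res <- filter_cascade(as_variant_table(sim), sim$exclusion_sites)
    oracle <- oracle_cascade_survivors(sim$sites, sim$gt, sim$exclusion_sites,
                                       filter_spec())
    expect_equal(unname(res$counts["survivors"]), sim$expected_survivors)
    expect_equal(oracle, sim$expected_survivors)
  }
})
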