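make_profile <- function(f_depth, m_depth, tot_f = 1e6, tot_m = 1e6,
                         len = 5000L) {
  out <- data.frame(scaffold_id = sprintf("s%02d", seq_along(f_depth)),
                    length = rep(len, length(f_depth)),
                    mean_depth_female = f_depth, mean_depth_male = m_depth,
                    stringsAsFactors = FALSE)
  attr(out, "total_reads_female") <- tot_f
  attr(out, "total_reads_male") <- tot_m
  out
}

test_that("AD ratio arithmetic and the undefined case", {
  pr <- make_profile(c(15, 0, 20), c(30, 20, 10))
  ad <- ad_ratio(pr)
  expect_equal(unname(ad), c(0.5, 0, 2.0))
  pr2 <- make_profile(5, 0)
  expect_true(is.na(ad_ratio(pr2)))
  expect_equal(unname(classify_ad(ad_ratio(pr2))), "unassigned")
})

test_that("classification windows match their bounds", {
  cfg <- ad_config()
  expect_equal(unname(classify_ad(c(0.39, 1.0, 0.5, 2.0, 1.6, 2.4, 0.4, 0.6,
                                    1.4), cfg)),
               c("Y", "A", "unassigned", "X", "X", "unassigned", "unassigned",
                 "unassigned", "unassigned"))
  expect_error(ad_config(y_max = 0.7))
})

test_that("AD is invariant to rescaling one library", {
  pr <- make_profile(c(15, 30, 60), c(30, 30, 30))
  ad0 <- ad_ratio(pr)
  for (c_scale in c(0.1, 3, 42)) {
    pr2 <- pr
    pr2$mean_depth_female <- pr$mean_depth_female * c_scale
    attr(pr2, "total_reads_female") <-
      attr(pr, "total_reads_female") * c_scale
    expect_equal(ad_ratio(pr2), ad0, tolerance = 1e-12)
  }
})

test_that("short scaffolds are left unassigned by the profile classifier", {
  pr <- make_profile(c(0, 0), c(30, 30), len = 5000L)
  pr$length <- c(5000L, 500L)
  res <- classify_ad_profile(pr, ad_config(min_scaffold_len = 1000L))
  expect_equal(res$call, c("Y", "unassigned"))
})

test_that("noise-free simulated depths classify perfectly and the homolog rises monotonically", {
  g <- fixture_genome_plain()
  pr <- depth_profile(sim_depths(g, "female", 30, 0, seed = 1),
                      sim_depths(g, "male", 30, 0, seed = 1))
  res <- classify_ad_profile(pr)
  expect_identical(res$call, g$scaffolds$true_origin)

  ads <- vapply(c(0.1, 0.3, 0.5, 0.8), function(f) {
    gh <- sim_genome(genome_spec(n_auto = 1L, n_x = 1L, n_y = 1L,
                                 xy_homology_fraction = f, seed = 21L))
    pr <- depth_profile(sim_depths(gh, "female", 30, 0, seed = 1),
                        sim_depths(gh, "male", 30, 0, seed = 1))
    ad_ratio(pr)[[gh$homology$y_scaffold]]
  }, numeric(1))
  expect_true(all(diff(ads) > 0))
  expect_lt(ads[2], 0.4)   # fraction 0.3 still called Y at the relaxed cutoff
  expect_gt(ads[4], 0.4)   # large transposed fraction escapes even 0.4
})
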