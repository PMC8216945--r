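test_that("noise-free depths follow the copy-number law", {
  g <- fixture_genome_plain()
  f <- sim_depths(g, "female", target_depth = 30, noise_cv = 0, seed = 1)
  m <- sim_depths(g, "male", target_depth = 30, noise_cv = 0, seed = 1)
  org <- g$scaffolds$true_origin
  expect_equal(f$mean_depth[org == "A"], rep(30, sum(org == "A")))
  expect_equal(m$mean_depth[org == "A"], rep(30, sum(org == "A")))
  expect_equal(f$mean_depth[org == "X"], rep(30, sum(org == "X")))
  expect_equal(m$mean_depth[org == "X"], rep(15, sum(org == "X")))
  expect_equal(f$mean_depth[org == "Y"], rep(0, sum(org == "Y")))
  expect_equal(m$mean_depth[org == "Y"], rep(15, sum(org == "Y")))
})

test_that("X-homologous Y block leaks female depth in proportion to identity", {
  g <- fixture_genome_hom()
  f <- sim_depths(g, "female", target_depth = 30, noise_cv = 0, seed = 1)
  h <- g$homology
  i <- match(h$y_scaffold, f$scaffold_id)
  len <- f$length[i]
  expect_equal(f$mean_depth[i], 15 * 0.99 * h$block_len / len, tolerance = 1e-12)
  other_y <- f$scaffold_id %in%
    g$scaffolds$id[g$scaffolds$true_origin == "Y"] & f$scaffold_id != h$y_scaffold
  expect_equal(f$mean_depth[other_y], rep(0, sum(other_y)))
})

test_that("lognormal mappability noise has mean one (Monte Carlo at n = 1000)", {
  g <- sim_genome(genome_spec(n_auto = 1000L, n_x = 0L, n_y = 0L,
                              len_range = c(100L, 200L), seed = 2L))
  d <- sim_depths(g, "male", target_depth = 30, noise_cv = 0.1, seed = 9)
  expect_equal(mean(d$mean_depth), 30, tolerance = 0.01)
  expect_equal(sd(d$mean_depth) / mean(d$mean_depth), 0.1, tolerance = 0.15)
})

test_that("the mappability factor is scaffold-intrinsic: same seed cancels in the ratio", {
  g <- fixture_genome_plain()
  f <- sim_depths(g, "female", 30, noise_cv = 0.2, seed = 5)
  m <- sim_depths(g, "male", 30, noise_cv = 0.2, seed = 5)
  org <- g$scaffolds$true_origin
  expect_equal(f$mean_depth[org == "A"] / m$mean_depth[org == "A"],
               rep(1, sum(org == "A")), tolerance = 1e-12)
  expect_equal(f$mean_depth[org == "X"] / m$mean_depth[org == "X"],
               rep(2, sum(org == "X")), tolerance = 1e-12)
  # different seeds draw different factors
  m2 <- sim_depths(g, "male", 30, noise_cv = 0.2, seed = 6)
  expect_false(isTRUE(all.equal(m$mean_depth, m2$mean_depth)))
})

test_that("depth tables round-trip through the TSV format", {
  g <- fixture_genome_plain()
  d <- sim_depths(g, "male", 30, 0.1, seed = 4)
  p <- tempfile(fileext = ".tsv")
  write_depth_table(d, p)
  d2 <- read_depth_table(p)
  expect_equal(d2$mean_depth, d$mean_depth, tolerance = 1e-6)
  expect_identical(d2$scaffold_id, d$scaffold_id)
})
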