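test_that("seed regions cover a fully male-specific scaffold end to end", {
  L <- 268000L
  male <- matrix(10, L, 2)
  female <- matrix(0, L, 2)
  reg <- derive_seed_regions(male, female, "sry_scaffold", min_run_len = 100L)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, L)
  expect_equal(attr(reg, "total_len"), 268000L)
})

test_that("seed regions honour run-length and coverage constraints", {
  expect_warning(
    reg0 <- derive_seed_regions(rep(0, 1000), rep(0, 1000), min_run_len = 100L),
    "no run")
  expect_equal(nrow(reg0), 0L)

  # alternating 50-bp male-covered blocks never reach a 100-bp run
  male <- rep(rep(c(10, 0), each = 50), 10)
  female <- rep(0, 1000)
  expect_warning(reg <- derive_seed_regions(male, female, min_run_len = 100L))
  expect_equal(nrow(reg), 0L)

  # any female coverage above the ceiling excludes the position
  male2 <- rep(10, 2000)
  female2 <- c(rep(0, 1000), rep(1, 1000))
  reg2 <- derive_seed_regions(male2, female2, min_run_len = 100L,
                              max_female_depth = 0)
  expect_equal(reg2$start, 0L)
  expect_equal(reg2$end, 1000L)
})

test_that("mapping rate is a percentage with a guarded denominator", {
  expect_equal(mapping_rate(0, 1e6), 0)
  expect_equal(mapping_rate(400, 1e6), 0.04)
  expect_equal(mapping_rate(5, 10), 50)
  expect_error(mapping_rate(1, 0), "positive")
})

test_that("sex calls follow the thresholds and are monotone in the rate", {
  th <- sex_thresholds()
  expect_equal(call_sex(0.10, th), "male")
  expect_equal(call_sex(0.00, th), "female")
  expect_equal(call_sex(0.02, th), "ambiguous")
  expect_equal(call_sex(0.04, th), "ambiguous")  # strictly greater than 0.04
  rates <- seq(0, 1, by = 0.005)
  calls <- call_sex(rates, th)
  rank <- c(female = 1, ambiguous = 2, male = 3)[calls]
  expect_true(all(diff(rank) >= 0))
  expect_error(sex_thresholds(male_min = 0.01, female_max = 0.02))
})

test_that("the separation t-test behaves at degeneracies and separates groups", {
  expect_equal(threshold_separation_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(threshold_separation_test(rep(0.05, 10), rep(0, 10)), 0)
  m <- c(0.050, 0.052, 0.049, 0.051)
  f <- c(0.000, 0.001, 0.000, 0.001)
  p <- threshold_separation_test(m, f)
  # Welch statistic computed from first principles
  t_stat <- (mean(m) - mean(f)) / sqrt(var(m) / 4 + var(f) / 4)
  df <- (var(m) / 4 + var(f) / 4)^2 /
    ((var(m) / 4)^2 / 3 + (var(f) / 4)^2 / 3)
  expect_equal(p, 2 * pt(-abs(t_stat), df), tolerance = 1e-12)
  expect_lt(p, 1e-3)
  # exchangeable within groups
  expect_equal(threshold_separation_test(rev(m), f), p)
})

test_that("simulated samples are sexed without error from reads alone", {
  g <- fixture_genome_plain()
  y_ids <- g$scaffolds$id[g$scaffolds$true_origin == "Y"]
  seeds <- g$sequences[y_ids]
  for (s in 1:3) {
    mr <- sim_reads(g, "male", depth = 10, error_rate = 0.01, seed = 100 + s)
    fr <- sim_reads(g, "female", depth = 10, error_rate = 0.01, seed = 200 + s)
    rate_m <- mapping_rate(count_seed_hits(mr, seeds), length(mr))
    rate_f <- mapping_rate(count_seed_hits(fr, seeds), length(fr))
    expect_equal(call_sex(rate_m), "male")
    expect_equal(call_sex(rate_f), "female")
  }
})
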