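test_that("a metric line of three markers orders correctly", {
  D <- matrix(c(0, 10, 20,
                10, 0, 10,
                20, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mo <- rh_order_markers(c("A", "B", "C"), D)
  expect_true(identical(mo$order, c("A", "B", "C")) ||
                identical(mo$order, c("C", "B", "A")))
  expect_equal(mo$objective, 20)
  expect_true(mo$optimal)
})

test_that("heuristic ordering equals the exhaustive optimum on 8 markers", {
  set.seed(23)
  for (rep in 1:5) {
    pts <- sort(runif(8, 0, 100))
    ids <- sprintf("m%d", 1:8)
    D <- abs(outer(pts, pts, "-")) + matrix(runif(64, 0, 2), 8, 8)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- list(ids, ids)
    ex <- rh_order_markers(ids, D)                      # exhaustive
    he <- rh_order_markers(ids, D, exhaustive_max = 0L) # forced heuristic
    expect_true(ex$optimal)
    expect_false(he$optimal)
    expect_equal(he$objective, ex$objective, tolerance = 1e-9)
  }
})

test_that("error-free simulated groups recover the true order up to reversal", {
  for (s in 1:5) {
    pan <- sim_rh_panel(rh_panel_spec(list(cumsum(c(0, rep(0.15, 7)))),
                                      n_hybrids = 93L, retention = 0.3,
                                      seed = 40L + s))
    tpm <- rh_two_point_matrix(pan$calls)
    mo <- rh_order_markers(rownames(pan$calls), tpm$distance)
    truth <- pan$truth$groups[[1]]
    expect_true(identical(mo$order, truth) ||
                  identical(mo$order, rev(truth)))
  }
})

test_that("obligate breaks count H/A transitions, skipping ambiguity", {
  calls <- rbind(m1 = c("H", "H", "A"),
                 m2 = c("A", "?", "A"),
                 m3 = c("H", "A", "A"))
  colnames(calls) <- c("h1", "h2", "h3")
  br <- rh_obligate_breaks(c("m1", "m2", "m3"), calls)
  expect_equal(as.vector(br), c(2L, 1L, 0L))
  expect_equal(attr(br, "total"), 3L)

  # all-H hybrid has zero breaks
  allh <- matrix("H", 3, 1, dimnames = list(c("m1", "m2", "m3"), "h"))
  expect_equal(as.vector(rh_obligate_breaks(c("m1", "m2", "m3"), allh)), 0L)

  # random instances agree with a direct scan
  set.seed(5)
  for (i in 1:20) {
    cm <- matrix(sample(c("H", "A", "?"), 60, TRUE, prob = c(0.3, 0.6, 0.1)),
                 6, 10, dimnames = list(sprintf("m%d", 1:6), NULL))
    ord <- sample(rownames(cm))
    br <- rh_obligate_breaks(ord, cm)
    oracle <- vapply(seq_len(10), function(h) {
      v <- cm[ord, h]; v <- v[v != "?"]
      if (length(v) < 2) 0L else sum(v[-1] != v[-length(v)])
    }, integer(1))
    expect_equal(as.vector(br), oracle)
  }
})

test_that("grouping at threshold 0 connects everything; disconnected data errors", {
  pan <- sim_rh_panel(rh_panel_spec(list(cumsum(c(0, rep(0.1, 4)))),
                                    n_hybrids = 93L, retention = 0.3,
                                    seed = 77L))
  lg <- rh_linkage_groups(pan$calls, lod_threshold = 0)
  expect_equal(length(lg$groups), 1L)
  expect_length(lg$groups[[1]], 5L)

  D <- matrix(NA_real_, 3, 3, dimnames = list(c("a","b","c"), c("a","b","c")))
  diag(D) <- 0; D["a","b"] <- D["b","a"] <- 5
  expect_error(rh_order_markers(c("a", "b", "c"), D), "missing distances")
})

test_that("ordering objective is reversal-invariant and beats plain nearest-neighbour", {
  set.seed(61)
  pts <- sort(runif(12, 0, 100))
  ids <- sprintf("m%02d", 1:12)
  D <- abs(outer(pts, pts, "-")) + matrix(runif(144, 0, 3), 12, 12)
  D <- (D + t(D)) / 2; diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  mo <- rh_order_markers(ids, D, exhaustive_max = 0L)
  path_len <- function(p) sum(D[cbind(p[-length(p)], p[-1])])
  expect_equal(path_len(mo$order), path_len(rev(mo$order)))
  # greedy nearest-neighbour from marker 1, no polishing
  nn <- ids[1]; left <- setdiff(ids, nn)
  while (length(left)) {
    nxt <- left[which.min(D[nn[length(nn)], left])]
    nn <- c(nn, nxt); left <- setdiff(left, nxt)
  }
  expect_lte(mo$objective, path_len(nn) + 1e-9)
})
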