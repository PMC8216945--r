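# Shared fixtures, built in code at test time.

# small genome with an X-homologous Y block (half the scaffold, 99% identity)
fixture_genome_hom <- function(seed = 7L) {
  sim_genome(genome_spec(n_auto = 3L, n_x = 2L, n_y = 3L,
                         len_range = c(2000L, 4000L),
                         xy_homology_fraction = 0.5, xy_identity = 0.99,
                         seed = seed))
}

fixture_genome_plain <- function(seed = 3L) {
  sim_genome(genome_spec(n_auto = 3L, n_x = 2L, n_y = 2L,
                         len_range = c(1500L, 2500L), seed = seed))
}

# independent brute-force canonical k-mer oracle (chartr-based, no package
# internals)
oracle_kmers <- function(seqs, k) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in 1:(L - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("N", km, fixed = TRUE)) next
      rc <- revcomp(km)
      out <- c(out, if (km <= rc) km else rc)
    }
  }
  out
}

# brute-force N-ladder oracle: cumulative scan on the sorted lengths
oracle_nladder <- function(lengths, level) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= level / 100 * total) return(c(n = s[i], l = i))
  }
}

# grid-search oracle for the two-point MLE; step gives the resolution
oracle_twopoint <- function(counts, step = 1e-3) {
  th <- seq(0, 1, by = step)
  r <- seq(0, 1, by = step)
  p11 <- outer(th, r, function(t, rr) (1 - t) * rr + t * rr^2)
  p10 <- outer(th, r, function(t, rr) t * rr * (1 - rr))
  p00 <- outer(th, r, function(t, rr) (1 - t) * (1 - rr) + t * (1 - rr)^2)
  safe_log <- function(p) ifelse(p > 0, log(p), -Inf)
  ll <- 0
  if (counts[["n11"]] > 0) ll <- ll + counts[["n11"]] * safe_log(p11)
  if (counts[["n10"]] + counts[["n01"]] > 0) {
    ll <- ll + (counts[["n10"]] + counts[["n01"]]) * safe_log(p10)
  }
  if (counts[["n00"]] > 0) ll <- ll + counts[["n00"]] * safe_log(p00)
  best <- arrayInd(which.max(ll), dim(ll))
  # unlinked maximum over r at theta = 1 (last row of the grid)
  ll_unl <- max(ll[length(th), ])
  list(theta = th[best[1]], r = r[best[2]],
       lod = max(0, (max(ll) - ll_unl) / log(10)))
}

# per-record replay of the full filter cascade, independent of the package's
# vectorised implementation
oracle_cascade_survivors <- function(sites, gt, exclusion, spec) {
  surv <- 0L
  excl_key <- paste(exclusion$chrom, exclusion$pos)
  for (i in seq_len(nrow(sites))) {
    rec <- sites[i, ]
    fail <- FALSE
    if (!is.na(rec$QD) && rec$QD < spec$qd_min) fail <- TRUE
    if (!is.na(rec$MQRankSum) && rec$MQRankSum < spec$mqranksum_min) fail <- TRUE
    if (!is.na(rec$FS) && rec$FS > spec$fs_max) fail <- TRUE
    if (!is.na(rec$ReadPosRankSum) && rec$ReadPosRankSum < spec$readpos_min) fail <- TRUE
    if (!is.na(rec$MQ) && rec$MQ < spec$mq_min) fail <- TRUE
    if (!is.na(rec$SOR) && rec$SOR > spec$sor_max) fail <- TRUE
    if (paste(rec$chrom, rec$pos) %in% excl_key) fail <- TRUE
    g <- gt[i, ]
    obs <- g[g != "."]
    if (length(obs) / length(g) < spec$call_rate_min) fail <- TRUE
    if (length(unique(obs)) != 2) fail <- TRUE
    else {
      cnt <- table(obs)
      if (min(cnt) / length(obs) < spec$maf_min) fail <- TRUE
    }
    if (!fail) surv <- surv + 1L
  }
  surv
}
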