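# Haploid equal-retention two-point model for radiation hybrids.
# Joint call probabilities for two markers at breakage probability theta and
# retention probability r:
#   P(H,H) = (1-theta) r + theta r^2
#   P(H,A) = P(A,H) = theta r (1-r)
#   P(A,A) = (1-theta)(1-r) + theta (1-r)^2
# The unlinked submodel is theta = 1 (independent retention).

.rh_counts <- function(vi, vj) {
  inf <- vi != "?" & vj != "?"
  vi <- vi[inf]; vj <- vj[inf]
  c(n11 = sum(vi == "H" & vj == "H"),
    n10 = sum(vi == "H" & vj == "A"),
    n01 = sum(vi == "A" & vj == "H"),
    n00 = sum(vi == "A" & vj == "A"))
}

# log-likelihood at (theta, r); counts is the 4-vector from .rh_counts.
# Vectorised over theta/r of equal length.
.rh_loglik <- function(theta, r, counts) {
  p11 <- (1 - theta) * r + theta * r^2
  p10 <- theta * r * (1 - r)
  p00 <- (1 - theta) * (1 - r) + theta * (1 - r)^2
  term <- function(cnt, p) {
    if (cnt == 0L) return(0)
    out <- rep(-Inf, length(p))
    pos <- p > 0
    out[pos] <- cnt * log(p[pos])
    out
  }
  term(counts[["n11"]], p11) +
    term(counts[["n10"]] + counts[["n01"]], p10) +
    term(counts[["n00"]], p00)
}

# maximum log-likelihood of the unlinked (theta = 1) submodel
.rh_loglik_unlinked <- function(counts) {
  nH <- 2 * counts[["n11"]] + counts[["n10"]] + counts[["n01"]]
  nA <- 2 * counts[["n00"]] + counts[["n10"]] + counts[["n01"]]
  n2 <- nH + nA
  r1 <- nH / n2
  (if (nH > 0) nH * log(r1) else 0) + (if (nA > 0) nA * log(1 - r1) else 0)
}

#' Two-point analysis of a radiation-hybrid marker pair
#'
#' Maximum-likelihood estimation of the breakage probability `theta` and
#' retention probability `r` for two H/A/? call vectors under the haploid
#' equal-retention model, with the LOD score of linkage (log10 likelihood
#' ratio of the joint MLE against the unlinked `theta = 1` submodel, so LOD
#' is never negative). Hybrids with an ambiguous call at either marker are
#' dropped. The map distance is `100 * (-ln(1 - theta))` centiRays
#' (infinite at `theta = 1`).
#'
#' @param vi,vj character vectors of H/A/? calls of equal length.
#' @return an object of class `rh_twopoint`: list with `theta`, `r`, `lod`,
#'   `distance` (cR), `n_informative` and `counts`.
#' @export
rh_two_point <- function(vi, vj) {
  stopifnot(length(vi) == length(vj))
  counts <- .rh_counts(vi, vj)
  n <- sum(counts)
  if (n == 0L) stop("no informative hybrids for this pair", call. = FALSE)
  ll_unl <- .rh_loglik_unlinked(counts)

  cand <- list(list(theta = 1, ll = ll_unl,
                    r = (2 * counts[["n11"]] + counts[["n10"]] +
                           counts[["n01"]]) / (2 * n)))
  # theta = 0 is only admissible with no discordant pairs
  if (counts[["n10"]] + counts[["n01"]] == 0L) {
    r0 <- counts[["n11"]] / n
    cand <- c(cand, list(list(theta = 0, r = r0,
                              ll = .rh_loglik(0, r0, counts))))
  }
  # interior optimum: coarse grid start, then quasi-Newton refinement
  th_g <- seq(0.0025, 0.9975, length.out = 150)
  r_g <- seq(0.0025, 0.9975, length.out = 150)
  grid <- expand.grid(theta = th_g, r = r_g)
  ll_g <- .rh_loglik(grid$theta, grid$r, counts)
  best <- which.max(ll_g)
  eps <- 1e-9
  opt <- optim(c(grid$theta[best], grid$r[best]),
               function(p) -.rh_loglik(p[1], p[2], counts),
               method = "L-BFGS-B",
               lower = c(eps, eps), upper = c(1 - eps, 1 - eps),
               control = list(factr = 1e3))
  cand <- c(cand, list(list(theta = opt$par[1], r = opt$par[2],
                            ll = -opt$value)))

  lls <- vapply(cand, `[[`, numeric(1), "ll")
  pick <- cand[[which.max(lls)]]
  # snap to the unlinked boundary when the interior gains nothing
  if (pick$ll <= ll_unl + 1e-9) pick <- cand[[1L]]
  theta <- min(max(pick$theta, 0), 1)
  lod <- max(0, (pick$ll - ll_unl) / log(10))
  if (theta >= 1) lod <- 0
  structure(list(theta = theta, r = pick$r, lod = lod,
                 distance = if (theta >= 1) Inf else
                   max(0, 100 * (-log(1 - theta))),
                 n_informative = n, counts = counts),
            class = "rh_twopoint")
}

#' @export
print.rh_twopoint <- function(x, ...) {
  cat(sprintf("RH two-point: theta = %.4f, r = %.4f, LOD = %.2f, %s cR (n = %d)\n",
              x$theta, x$r, x$lod,
              if (is.finite(x$distance)) sprintf("%.1f", x$distance) else "Inf",
              x$n_informative))
  invisible(x)
}

#' All-pairs two-point statistics for a panel
#'
#' @param calls character matrix of H/A/? calls (markers x hybrids).
#' @return list with `pairs` (data.frame: marker_i, marker_j, theta, r, lod,
#'   distance, n_informative) and symmetric matrices `theta`, `r`, `lod`,
#'   `distance`.
#' @export
rh_two_point_matrix <- function(calls) {
  m <- nrow(calls)
  ids <- rownames(calls)
  stopifnot(m >= 2L, !is.null(ids))
  theta <- r <- lod <- dist <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  diag(theta) <- 0; diag(lod) <- Inf; diag(dist) <- 0
  pairs <- vector("list", m * (m - 1L) / 2L)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      tp <- rh_two_point(calls[i, ], calls[j, ])
      theta[i, j] <- theta[j, i] <- tp$theta
      r[i, j] <- r[j, i] <- tp$r
      lod[i, j] <- lod[j, i] <- tp$lod
      dist[i, j] <- dist[j, i] <- tp$distance
      k <- k + 1L
      pairs[[k]] <- data.frame(marker_i = ids[i], marker_j = ids[j],
                               theta = tp$theta, r = tp$r, lod = tp$lod,
                               distance = tp$distance,
                               n_informative = tp$n_informative,
                               stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, pairs), theta = theta, r = r, lod = lod,
       distance = dist)
}
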