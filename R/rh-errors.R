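# Chained multipoint log-likelihood of one hybrid's calls along a fixed
# order. Transition probabilities between consecutive informative calls use
# the haploid equal-retention model with the combined breakage probability
# of the skipped intervals: theta_comb = 1 - prod(1 - theta_k).
.hybrid_loglik <- function(calls_h, theta_iv, r) {
  inf <- which(calls_h != "?")
  if (length(inf) == 0L) return(0)
  ll <- if (calls_h[inf[1L]] == "H") log(r) else log(1 - r)
  if (length(inf) > 1L) {
    for (t in 2:length(inf)) {
      i <- inf[t - 1L]; j <- inf[t]
      th <- 1 - prod(1 - theta_iv[i:(j - 1L)])
      th <- min(max(th, 1e-6), 1 - 1e-6)
      a <- calls_h[i]; b <- calls_h[j]
      p <- if (a == "H") {
        if (b == "H") (1 - th) + th * r else th * (1 - r)
      } else {
        if (b == "H") th * r else (1 - th) + th * (1 - r)
      }
      ll <- ll + log(p)
    }
  }
  ll
}

#' Flag likely laboratory errors in an RH panel
#'
#' Given a fixed marker order, scores every non-ambiguous call by how much
#' the map's chained multipoint log10-likelihood would improve if that single
#' call were flipped (H <-> A). A genuine call sits consistently with its
#' neighbours, so flipping it loses likelihood; a typo in a tight map creates
#' an improbable double break, and flipping it gains a large factor. Calls
#' gaining at least `log10_threshold` (default 3, a factor of 1000) are
#' flagged. Ambiguous calls are never flagged. The alternative
#' `method = "double_break"` flags calls whose flip removes at least two
#' obligate breaks from the hybrid — the combinatorial reading of the same
#' idea.
#'
#' @param order character vector of marker ids, the map order.
#' @param calls character matrix of H/A/? calls (markers x hybrids).
#' @param log10_threshold minimum log10 likelihood gain to flag (default 3).
#' @param method `"likelihood"` (default) or `"double_break"`.
#' @return `data.frame` with columns `marker`, `hybrid`, `gain`
#'   (log10 units, or breaks removed), possibly empty.
#' @export
rh_flag_errors <- function(order, calls, log10_threshold = 3,
                           method = c("likelihood", "double_break")) {
  method <- match.arg(method)
  stopifnot(all(order %in% rownames(calls)))
  sub <- calls[order, , drop = FALSE]
  n_m <- nrow(sub); n_h <- ncol(sub)
  # per-interval breakage estimates along the order
  theta_iv <- vapply(seq_len(n_m - 1L), function(i) {
    rh_two_point(sub[i, ], sub[i + 1L, ])$theta
  }, numeric(1))
  theta_iv <- pmin(pmax(theta_iv, 1e-6), 1 - 1e-6)
  r_hat <- mean(sub[sub != "?"] == "H")
  r_hat <- min(max(r_hat, 1e-6), 1 - 1e-6)
  flags <- list()
  for (h in seq_len(n_h)) {
    col <- sub[, h]
    if (method == "likelihood") base <- .hybrid_loglik(col, theta_iv, r_hat)
    for (m in seq_len(n_m)) {
      if (col[m] == "?") next
      flip <- col
      flip[m] <- if (col[m] == "H") "A" else "H"
      gain <- if (method == "likelihood") {
        (.hybrid_loglik(flip, theta_iv, r_hat) - base) / log(10)
      } else {
        br <- function(v) { v <- v[v != "?"]
          if (length(v) < 2L) 0L else sum(v[-1L] != v[-length(v)]) }
        br(col) - br(flip)
      }
      thr <- if (method == "likelihood") log10_threshold else 2
      if (gain >= thr) {
        flags[[length(flags) + 1L]] <- data.frame(
          marker = order[m],
          hybrid = colnames(sub)[h] %||% as.character(h),
          gain = gain, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(flags) == 0L) {
    return(data.frame(marker = character(0), hybrid = character(0),
                      gain = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
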