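#' Assembly N-ladder statistics
#'
#' Computes N10..N90 and the corresponding L-counts for a set of scaffold
#' lengths: Nx is the length of the scaffold at which the cumulative sum of
#' lengths, sorted in descending order, first reaches x% of the total; Lx is
#' the number of scaffolds used to reach it. The familiar N50 is the x = 50
#' rung.
#'
#' @param lengths numeric vector of scaffold lengths, all positive.
#' @param levels percentages of the total to ladder over (default
#'   10, 20, ..., 90).
#' @return an object of class `n_ladder`: a `data.frame` with columns
#'   `level`, `n`, `l`, and attributes `total` and `count`.
#' @export
n_ladder <- function(lengths, levels = seq(10L, 90L, 10L)) {
  if (length(lengths) == 0L) stop("no scaffold lengths given", call. = FALSE)
  stopifnot(all(lengths > 0), all(levels > 0), all(levels <= 100))
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  total <- cs[length(cs)]
  idx <- vapply(levels, function(x) {
    which(cs >= x / 100 * total)[1L]
  }, integer(1))
  out <- data.frame(level = levels, n = s[idx], l = idx)
  attr(out, "total") <- total
  attr(out, "count") <- length(lengths)
  class(out) <- c("n_ladder", "data.frame")
  out
}

#' @export
print.n_ladder <- function(x, ...) {
  cat("Assembly of", attr(x, "count"), "scaffolds,",
      format(attr(x, "total"), big.mark = ","), "bp total\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  N%-2d %12s  L%-2d %8d\n", x$level[i],
                format(x$n[i], big.mark = ","), x$level[i], x$l[i]))
  }
  invisible(x)
}
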