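#' Specification for a simulated radiation-hybrid panel
#'
#' Describes the geometry of an RH panel: markers at known physical positions
#' on one or more linkage groups, a number of hybrid clones, a fragment
#' retention probability, a breakage rate, and observation noise. A hybrid's
#' donor chromosome is broken by a Poisson process, so the probability of at
#' least one break between two markers at distance `d` is
#' `theta = 1 - exp(-break_rate * d)`; every resulting fragment is retained
#' independently with probability `r`. Recorded calls are flipped
#' (H <-> A) with probability `error_rate` and masked as ambiguous (`?`) with
#' probability `ambiguous_rate`, missing at random.
#'
#' @param marker_positions list of strictly increasing numeric vectors, one
#'   per linkage group (positions in arbitrary distance units, e.g. Rays
#'   when `break_rate = 1`). A length-1 group is an unlinked singleton.
#' @param n_hybrids number of hybrid clones (the reference goat panel has 93).
#' @param retention fragment retention probability `r`, in (0, 1).
#' @param break_rate expected breaks per unit distance.
#' @param error_rate probability a recorded call is flipped.
#' @param ambiguous_rate probability a call is recorded `?`.
#' @param seed random seed.
#' @return an object of class `rh_panel_spec`.
#' @export
rh_panel_spec <- function(marker_positions, n_hybrids = 93L, retention = 0.3,
                          break_rate = 1, error_rate = 0, ambiguous_rate = 0,
                          seed = 1L) {
  stopifnot(is.list(marker_positions), length(marker_positions) >= 1L,
            n_hybrids >= 1L, retention > 0, retention < 1,
            break_rate >= 0, error_rate >= 0, error_rate <= 1,
            ambiguous_rate >= 0, ambiguous_rate <= 1)
  for (g in marker_positions) {
    if (length(g) > 1L && any(diff(g) <= 0)) {
      stop("marker positions must be strictly increasing within a group",
           call. = FALSE)
    }
  }
  structure(list(marker_positions = marker_positions,
                 n_hybrids = as.integer(n_hybrids), retention = retention,
                 break_rate = break_rate, error_rate = error_rate,
                 ambiguous_rate = ambiguous_rate, seed = as.integer(seed)),
            class = "rh_panel_spec")
}

#' Simulate a radiation-hybrid panel
#'
#' Generates H/A/? call vectors for every marker of an [rh_panel_spec()]
#' under the random-breakage equal-retention model, and returns the ground
#' truth (true order and per-interval breakage probabilities) for recovery
#' tests.
#'
#' @param spec an [rh_panel_spec()].
#' @return a list of class `rh_panel`: `calls` (character matrix, markers x
#'   hybrids, entries H/A/?), `truth` (list with `groups`: marker ids per
#'   group, `theta`: per-interval breakage probabilities per group) and
#'   `spec`.
#' @export
sim_rh_panel <- function(spec) {
  stopifnot(inherits(spec, "rh_panel_spec"))
  with_seed(spec$seed, {
    groups <- lapply(seq_along(spec$marker_positions), function(g) {
      sprintf("g%dm%02d", g, seq_along(spec$marker_positions[[g]]))
    })
    theta <- lapply(spec$marker_positions, function(pos) {
      if (length(pos) < 2L) numeric(0)
      else 1 - exp(-spec$break_rate * diff(pos))
    })
    n_h <- spec$n_hybrids
    rows <- list()
    for (g in seq_along(groups)) {
      n_m <- length(groups[[g]])
      calls <- matrix("A", n_m, n_h)
      th <- theta[[g]]
      for (h in seq_len(n_h)) {
        # fragment index per marker: cumulative count of breaks before it
        breaks <- if (n_m > 1L) runif(n_m - 1L) < th else logical(0)
        frag <- cumsum(c(0L, as.integer(breaks)))
        kept <- runif(max(frag) + 1L) < spec$retention
        calls[, h] <- ifelse(kept[frag + 1L], "H", "A")
      }
      rownames(calls) <- groups[[g]]
      rows[[g]] <- calls
    }
    calls <- do.call(rbind, rows)
    colnames(calls) <- sprintf("hyb%02d", seq_len(n_h))
    if (spec$error_rate > 0) {
      flip <- matrix(runif(length(calls)) < spec$error_rate, nrow(calls))
      calls[flip] <- ifelse(calls[flip] == "H", "A", "H")
    }
    if (spec$ambiguous_rate > 0) {
      calls[matrix(runif(length(calls)) < spec$ambiguous_rate,
                   nrow(calls))] <- "?"
    }
    structure(list(calls = calls,
                   truth = list(groups = groups, theta = theta),
                   spec = spec),
              class = "rh_panel")
  })
}

#' Read or write an RH panel call file
#'
#' Plain text: rows are markers, the first column the marker id, the
#' remaining columns one H/A/? symbol per hybrid clone.
#'
#' @param path file path.
#' @return for the reader, a character matrix of calls (markers x hybrids).
#' @export
read_rh_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1L,
                           sep = "\t", colClasses = "character",
                           check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_rh_panel
#' @param calls character matrix of H/A/? calls.
#' @export
write_rh_panel <- function(calls, path) {
  df <- data.frame(marker = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
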