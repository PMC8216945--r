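#' Linkage groups at a LOD threshold
#'
#' Single-linkage grouping: markers are connected when their two-point LOD
#' reaches the threshold (pairs at `theta = 1` never form an edge), and the
#' connected components of that graph are the linkage groups. Markers in no
#' component of size >= 2 are reported as unlinked singletons.
#'
#' @param calls character matrix of H/A/? calls (markers x hybrids).
#' @param lod_threshold minimum LOD for a linkage edge (default 10).
#' @param pairwise optional precomputed [rh_two_point_matrix()] result.
#' @return list with `groups` (list of marker-id vectors, largest first),
#'   `singletons` (character vector) and `pairwise`.
#' @export
rh_linkage_groups <- function(calls, lod_threshold = 10, pairwise = NULL) {
  stopifnot(nrow(calls) >= 2L)
  if (is.null(pairwise)) pairwise <- rh_two_point_matrix(calls)
  adj <- pairwise$lod >= lod_threshold & pairwise$theta < 1
  diag(adj) <- FALSE
  adj[is.na(adj)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(rownames(calls), comp$membership)
  sizes <- lengths(groups)
  singletons <- unlist(groups[sizes == 1L], use.names = FALSE)
  groups <- groups[sizes >= 2L]
  groups <- groups[order(-lengths(groups))]
  list(groups = unname(groups),
       singletons = if (is.null(singletons)) character(0) else singletons,
       pairwise = pairwise)
}

.path_length <- function(path, D) {
  if (length(path) < 2L) return(0)
  sum(D[cbind(path[-length(path)], path[-1L])])
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .all_perms(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

.two_opt <- function(path, D) {
  n <- length(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        # reverse path[i..j]; for an open path only the two boundary edges
        # change
        old <- new <- 0
        if (i > 1L) {
          old <- old + D[path[i - 1L], path[i]]
          new <- new + D[path[i - 1L], path[j]]
        }
        if (j < n) {
          old <- old + D[path[j], path[j + 1L]]
          new <- new + D[path[i], path[j + 1L]]
        }
        if (new < old - 1e-12) {
          path[i:j] <- path[j:i]
          improved <- TRUE
        }
      }
    }
  }
  path
}

.or_opt <- function(path, D) {
  n <- length(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (seg_len in 1:min(3L, n - 1L)) {
      for (i in 1:(n - seg_len + 1L)) {
        j <- i + seg_len - 1L
        rest <- path[-(i:j)]
        seg <- path[i:j]
        base <- .path_length(path, D)
        for (pos in 0:length(rest)) {
          cand <- append(rest, seg, after = pos)
          if (.path_length(cand, D) < base - 1e-12) {
            path <- cand
            n <- length(path)
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (improved) break
    }
  }
  path
}

#' Order markers of a linkage group (TSP on two-point distances)
#'
#' Finds the marker order minimising the sum of adjacent two-point distances
#' — the open-path travelling-salesman formulation of RH map construction.
#' Groups of up to `exhaustive_max` markers are solved exactly by
#' enumeration; larger groups use the best of multi-start greedy
#' nearest-neighbour tours polished by 2-opt and Or-opt moves until no move
#' improves, deterministic given `seed`. An order and its reverse are
#' equivalent; the returned order is canonicalised so its first marker id
#' sorts before its last.
#'
#' @param markers character vector of marker ids (>= 2).
#' @param distance symmetric distance matrix in cR over at least these
#'   markers; infinite entries (pairs at `theta = 1`) are capped at
#'   `cap_cR`.
#' @param exhaustive_max maximum group size solved by exhaustive search
#'   (default 8).
#' @param n_starts number of nearest-neighbour starts (default 16).
#' @param cap_cR distance ceiling replacing infinite estimates (default 500).
#' @param seed seed for start selection when there are more markers than
#'   starts.
#' @return an object of class `marker_order`: list with `order`,
#'   `objective` (cR), `optimal` (TRUE when exhaustively solved) and
#'   `flipped_equivalent = TRUE`.
#' @export
rh_order_markers <- function(markers, distance, exhaustive_max = 8L,
                             n_starts = 16L, cap_cR = 500, seed = 1L) {
  stopifnot(length(markers) >= 2L,
            all(markers %in% rownames(distance)))
  D <- distance[markers, markers, drop = FALSE]
  if (any(is.na(D))) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("missing distances for pairs: ",
         paste(markers[bad[, 1]], markers[bad[, 2]], sep = "-",
               collapse = ", "), call. = FALSE)
  }
  D[!is.finite(D)] <- cap_cR
  n <- length(markers)
  if (n <= exhaustive_max) {
    perms <- .all_perms(n)
    objs <- vapply(perms, function(p) .path_length(markers[p], D), numeric(1))
    path <- markers[perms[[which.min(objs)]]]
    obj <- min(objs)
    optimal <- TRUE
  } else {
    starts <- if (n <= n_starts) seq_len(n) else
      with_seed(seed, sample(n, n_starts))
    best <- NULL
    for (s in starts) {
      path <- markers[s]
      left <- setdiff(markers, path)
      while (length(left) > 0L) {
        nxt <- left[which.min(D[path[length(path)], left])]
        path <- c(path, nxt)
        left <- setdiff(left, nxt)
      }
      path <- .or_opt(.two_opt(path, D), D)
      obj <- .path_length(path, D)
      if (is.null(best) || obj < best$obj - 1e-12) best <- list(path = path, obj = obj)
    }
    path <- best$path
    obj <- best$obj
    optimal <- FALSE
  }
  if (path[1L] > path[length(path)]) path <- rev(path)
  structure(list(order = path, objective = obj, optimal = optimal,
                 flipped_equivalent = TRUE),
            class = "marker_order")
}

#' @export
print.marker_order <- function(x, ...) {
  cat("Marker order (", if (x$optimal) "exhaustive optimum" else "heuristic",
      "), objective ", sprintf("%.1f", x$objective), " cR:\n  ",
      paste(x$order, collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Obligate breaks of an ordered map
#'
#' Counts, per hybrid, the adjacent H<->A transitions along the given marker
#' order, skipping ambiguous calls — each transition is a chromosome break
#' the map order forces that hybrid to have.
#'
#' @param order character vector of marker ids (an order).
#' @param calls character matrix of H/A/? calls including those markers.
#' @return integer vector of break counts per hybrid, with attribute
#'   `total`.
#' @export
rh_obligate_breaks <- function(order, calls) {
  stopifnot(all(order %in% rownames(calls)))
  sub <- calls[order, , drop = FALSE]
  counts <- apply(sub, 2L, function(col) {
    col <- col[col != "?"]
    if (length(col) < 2L) return(0L)
    sum(col[-1L] != col[-length(col)])
  })
  attr(counts, "total") <- sum(counts)
  counts
}
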