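# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadratic dominance scans, an independent
# recursive path enumerator, and a direct lower-convex-hull sweep in 2-D.

# O(n^2) pairwise non-dominated mask (duplicates collapsed to first)
oracle_pareto_mask <- function(x) {
  n <- nrow(x)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(x[j, ] <= x[i, ]) && any(x[j, ] < x[i, ])) { keep[i] <- FALSE; break }
      if (all(x[j, ] == x[i, ]) && j < i) { keep[i] <- FALSE; break }
    }
  }
  keep
}

# independent recursive simple-path enumerator working on raw edge lists
oracle_enumerate_paths <- function(net, origin, destination) {
  edges <- data.frame(from = net$arcs$from, to = net$arcs$to,
                      stringsAsFactors = FALSE)
  out <- list()
  walk <- function(at, seen, arcrows) {
    if (at == destination) {
      out[[length(out) + 1L]] <<- arcrows
      return(invisible(NULL))
    }
    rows <- which(edges$from == at & !(edges$to %in% seen))
    for (r in rows) walk(edges$to[r], c(seen, edges$to[r]), c(arcrows, r))
  }
  walk(origin, origin, integer(0))
  out
}

oracle_eval <- function(net, arcrows) {
  c(sum(net$arcs$log_risk[arcrows]), sum(net$arcs$mwd[arcrows]),
    sum(net$arcs$elev_cost[arcrows]))
}

# full frontier of a tiny network by enumeration + quadratic filtering
oracle_frontier <- function(net, origin, destination) {
  walks <- oracle_enumerate_paths(net, origin, destination)
  vec <- t(vapply(walks, function(w) oracle_eval(net, w), numeric(3)))
  vec[oracle_pareto_mask(vec), , drop = FALSE]
}

# supported points of a 2-D frontier by direct lower-left convex hull
# (Andrew monotone chain on the sorted frontier, keeping right turns)
oracle_supported_2d <- function(fr) {
  stopifnot(ncol(fr) == 2)
  n <- nrow(fr)
  if (n <= 2) return(rep(TRUE, n))
  ord <- order(fr[, 1], fr[, 2])
  pts <- fr[ord, , drop = FALSE]
  # traversing the lower boundary left to right, genuine vertices make
  # counterclockwise (left) turns; collinear points pop and are re-added
  # below as weakly supported
  hull <- 1L
  for (k in 2:n) {
    while (length(hull) >= 2) {
      a <- pts[hull[length(hull) - 1L], ]
      b <- pts[hull[length(hull)], ]
      c_ <- pts[k, ]
      z <- (b[1] - a[1]) * (c_[2] - b[2]) - (b[2] - a[2]) * (c_[1] - b[1])
      if (z <= 1e-12 * max(1, abs(b[1]), abs(b[2]))) hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, k)
  }
  keep <- rep(FALSE, n)
  keep[ord[hull]] <- TRUE
  # points exactly on a hull facet are weakly supported: add them back
  on_facet <- function(p, a, b) {
    cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    abs(cr) <= 1e-9 * max(1, abs(a[1]), abs(b[2])) &&
      p[1] >= min(a[1], b[1]) - 1e-12 && p[1] <= max(a[1], b[1]) + 1e-12
  }
  hp <- pts[hull, , drop = FALSE]
  for (i in which(!keep)) {
    for (s in seq_len(nrow(hp) - 1L)) {
      if (on_facet(fr[i, ], hp[s, ], hp[s + 1L, ])) { keep[i] <- TRUE; break }
    }
  }
  keep
}

# canonical per-path signatures for set comparison
path_signatures <- function(ps) {
  vapply(ps$paths, function(p) paste(p$nodes, collapse = ">"), character(1))
}

sorted_vectors <- function(m) {
  m <- as.matrix(m)
  m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), , drop = FALSE]
}

expect_same_frontier <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(unname(sorted_vectors(a)), unname(sorted_vectors(b)),
               tolerance = tol)
}
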