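#' Pareto dominance between objective vectors
#'
#' `a` dominates `b` when `a` is no worse in every objective and strictly
#' better in at least one (minimisation). Equal vectors do not dominate each
#' other.
#'
#' @param a,b numeric vectors of equal length
#' @return logical
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop_pp("objective vectors of unequal dimension", "paretopaths_domain")
  all(a <= b) && any(a < b)
}

#' Non-dominated subset of a set of objective vectors
#'
#' Keeps exactly the vectors not dominated by any other; exact duplicates are
#' collapsed to a single representative (the first occurrence).
#'
#' @param x numeric matrix, one objective vector per row
#' @return matrix of the non-dominated rows; attribute `"index"` holds their
#'   row positions in `x`
#' @export
pareto_filter <- function(x) {
  x <- as.matrix(x)
  keep <- pareto_keep(x)
  out <- x[keep, , drop = FALSE]
  attr(out, "index") <- which(keep)
  out
}

# logical mask of non-dominated, duplicate-collapsed rows. Rows are processed
# in lexicographic order so any dominator of row i precedes it in the sweep.
pareto_keep <- function(x) {
  n <- nrow(x)
  if (n == 0L) return(logical(0))
  ord <- do.call(order, c(lapply(seq_len(ncol(x)), function(j) x[, j])))
  keep <- logical(n)
  kept_rows <- matrix(numeric(0), 0, ncol(x))
  for (i in ord) {
    v <- x[i, ]
    dominated <- FALSE
    if (nrow(kept_rows)) {
      le <- kept_rows <= rep(v, each = nrow(kept_rows))
      allle <- rowSums(le) == ncol(x)
      if (any(allle)) {
        eq <- rowSums(kept_rows == rep(v, each = nrow(kept_rows))) == ncol(x)
        dominated <- any(allle)  # earlier lex row <= v; equal rows also drop v
        # (duplicate collapse: the first-kept equal row represents v)
        dominated <- dominated || any(eq)
      }
    }
    if (!dominated) {
      keep[i] <- TRUE
      kept_rows <- rbind(kept_rows, v)
    }
  }
  keep
}

#' Supported / unsupported classification of a Pareto frontier
#'
#' A frontier vector is *supported* when some strictly positive weight vector
#' makes it a minimiser of the weighted-sum scalarisation over the frontier
#' -- equivalently, when it lies on the lower convex envelope of the frontier
#' points. Points in the interior of an envelope facet (weakly supported) are
#' classified supported, since the facet's weight vector attains them.
#' All other frontier vectors are *unsupported*: efficient, but invisible to
#' any weighted-sum solve.
#'
#' The test per point is an exact small linear program (solved by an
#' internal dense two-phase simplex with Bland's rule, so exactly coplanar
#' frontier points cannot cycle it): the point is unsupported iff some convex
#' combination of the other frontier points is componentwise `<=` it and not
#' equal to it.
#'
#' @param x a `pareto_set` or a numeric matrix of mutually non-dominated
#'   objective vectors (rows)
#' @param tol relative tolerance on the strict-improvement test (default 1e-9)
#' @return for a matrix: logical vector, `TRUE` = supported; for a
#'   `pareto_set`: the set with its `supported` flags filled in
#' @export
classify_supported <- function(x, tol = 1e-9) {
  if (inherits(x, "pareto_set")) {
    flags <- classify_supported(x$objectives, tol = tol)
    return(new_pareto_set(x$origin, x$destination, x$paths, supported = flags))
  }
  y <- as.matrix(x)
  m <- nrow(y)
  if (m <= 2L) return(rep(TRUE, m))  # coordinate-wise minima are always supported
  vapply(seq_len(m), function(i) {
    point_supported(y[i, ], y[-i, , drop = FALSE], tol)
  }, logical(1))
}

# LP feasibility: is there lambda >= 0, sum(lambda) = 1, with
# Y'lambda <= y and sum(Y'lambda) < sum(y)? If so, y is above the lower
# convex envelope of the others, i.e. unsupported. Solved in standard form
# with slack variables: [Y' I | y; 1' 0 | 1].
point_supported <- function(y, others, tol = 1e-9) {
  d <- length(y)
  m <- nrow(others)
  A <- rbind(cbind(t(others), diag(d)),
             c(rep(1, m), rep(0, d)))
  b <- c(y, 1)
  obj <- c(rowSums(others), rep(0, d))
  fit <- lp_simplex(A, b, obj)
  if (fit$status != "optimal") return(TRUE)  # no feasible combination
  fit$value >= sum(y) - tol * max(1, abs(sum(y)))
}

#' Exhaustive Pareto frontier by path enumeration
#'
#' Enumerates every simple origin-destination path (depth-first, guarded by
#' `max_paths`), evaluates each, and keeps the non-dominated set. Paths with
#' identical objective vectors are collapsed to the lexicographically
#' smallest node sequence unless `keep_equal_vectors`. Intended as ground
#' truth at toy scale for the scalarisation and labeling algorithms -- its
#' cost is exponential in network size.
#'
#' @param net a [landscape_network()] with derived costs
#' @param origin,destination node ids
#' @param max_paths refuse (with an error stating the count reached) if the
#'   number of simple paths exceeds this guard (default 500)
#' @param classify also run [classify_supported()] (default TRUE)
#' @param keep_equal_vectors retain all distinct arc sequences per objective
#'   vector (default FALSE)
#' @return a `pareto_set`
#' @export
brute_force_pareto <- function(net, origin, destination, max_paths = 500,
                               classify = TRUE, keep_equal_vectors = FALSE) {
  require_costs(net)
  o <- node_index(net, origin)
  d <- node_index(net, destination)
  walks <- enumerate_simple_paths(net, o, d, max_paths)
  obj <- arc_objectives(net)
  paths <- lapply(walks, function(w) {
    v <- if (length(w$arcs)) colSums(obj[w$arcs, , drop = FALSE]) else c(0, 0, 0)
    names(v) <- c("log_risk", "mwd", "elev")
    new_path(origin, destination, net$nodes$id[w$nodes], w$arcs, v)
  })
  finalize_frontier(origin, destination, paths, keep_equal_vectors,
                    classify = classify)
}

# dominance filter + canonical equal-vector handling shared by the oracle and
# the labeling output
finalize_frontier <- function(origin, destination, paths, keep_equal_vectors,
                              classify = FALSE) {
  if (!length(paths))
    return(new_pareto_set(origin, destination, list()))
  vec <- t(vapply(paths, function(p) p$objectives, numeric(3)))
  nd <- nondominated_mask(vec)
  paths <- paths[nd]
  vec <- vec[nd, , drop = FALSE]
  grp <- vector_groups(vec)
  pick <- vapply(split(seq_along(grp), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    seqs <- lapply(paths[idx], function(p) p$nodes)
    idx[lex_min_index(seqs)]
  }, integer(1))
  if (keep_equal_vectors) {
    ord <- order(vec[, 1], vec[, 2], vec[, 3],
                 vapply(seq_along(paths), function(i)
                   paste(paths[[i]]$nodes, collapse = "\r"), character(1)))
    paths <- paths[ord]
  } else {
    pick <- unname(pick)
    ord <- pick[order(vec[pick, 1], vec[pick, 2], vec[pick, 3])]
    paths <- paths[ord]
  }
  ps <- new_pareto_set(origin, destination, paths)
  if (classify) ps <- classify_supported(ps)
  ps
}

# non-dominated rows, duplicates all retained
nondominated_mask <- function(vec) {
  n <- nrow(vec)
  mask <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(vec[j, ], vec[i, ])) { mask[i] <- FALSE; break }
    }
  }
  mask
}

# integer group id per row, grouping exactly-equal vectors
vector_groups <- function(vec) {
  key <- apply(vec, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  match(key, unique(key))
}

# index of the lexicographically smallest character sequence
lex_min_index <- function(seqs) {
  best <- 1L
  for (k in seq_along(seqs)[-1]) {
    if (seq_lt(seqs[[k]], seqs[[best]])) best <- k
  }
  best
}

seq_lt <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# all simple o->d walks as lists of node-index and arc-index sequences
enumerate_simple_paths <- function(net, o, d, max_paths) {
  found <- list()
  count <- 0L
  visited <- logical(nrow(net$nodes))
  node_stack <- integer(0)
  arc_stack <- integer(0)

  recurse <- function(i) {
    visited[i] <<- TRUE
    node_stack <<- c(node_stack, i)
    if (i == d) {
      count <<- count + 1L
      if (count > max_paths)
        stop_pp(paste0("simple-path count exceeds guard (", max_paths, ")"),
                "paretopaths_path_guard")
      found[[count]] <<- list(nodes = node_stack, arcs = arc_stack)
    } else {
      for (a in net$.adj[[i]]) {
        j <- net$arcs$.to_idx[a]
        if (!visited[j]) {
          arc_stack <<- c(arc_stack, a)
          recurse(j)
          arc_stack <<- arc_stack[-length(arc_stack)]
        }
      }
    }
    visited[i] <<- FALSE
    node_stack <<- node_stack[-length(node_stack)]
  }
  recurse(o)
  found
}
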