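# Internal normalization shared by NISE and MONISE.
#
# The three objectives live on very different numeric scales (cumulative
# log-risk is O(0.1), moisture-weighted distance can be O(1e4)), so weight
# vectors are applied in a normalized objective space: each objective is
# divided by the spread of the single-objective optima for the OD pair.
# Positive per-objective rescaling maps weighted-sum optima onto
# weighted-sum optima, so the supported set is unchanged; only the
# parametrisation of the weights is.
objective_scales <- function(net, origin, destination) {
  Y <- t(vapply(1:3, function(l) {
    w <- numeric(3); w[l] <- 1
    solve_weighted(net, origin, destination, w)$objectives
  }, numeric(3)))
  s <- apply(Y, 2, function(col) {
    r <- max(col) - min(col)
    if (r > 1e-12 * max(1, max(abs(col)))) r else max(1, abs(col))
  })
  as.numeric(s)
}

# solve with a weight vector expressed in normalized objective space
solve_scaled <- function(net, origin, destination, w_norm, scales,
                         provenance = NULL) {
  w <- w_norm / scales
  solve_weighted(net, origin, destination,
                 weight_vector(w / sum(w), provenance))
}

#' Biobjective non-inferior set estimation (NISE)
#'
#' Finds every supported efficient solution for a chosen pair of the three
#' objectives. The two anchor solutions (each minimising one objective of the
#' pair, with a small weight `delta` on the other to avoid weakly efficient
#' optima) bound the frontier; then, recursively, for each adjacent pair of
#' frontier points the scalarised problem is solved with weights proportional
#' to the segment's inward normal. A solution strictly below the segment's
#' weighted level (by more than a relative `eps`) is a new supported point
#' and splits the segment in two; otherwise the segment is a confirmed facet
#' of the lower convex envelope and the recursion stops.
#'
#' Weights are applied in a normalized objective space (see the methods
#' vignette); the objective left out of the pair receives weight zero, so the
#' returned solutions are efficient with respect to the pair (projections
#' are deduplicated on the pair's coordinates).
#'
#' @param net a [landscape_network()] with derived costs
#' @param origin,destination node ids
#' @param objectives integer pair from `{1, 2, 3}` selecting the two
#'   objectives (default `c(1, 2)`: risk and moisture-weighted distance)
#' @param delta anchor / zero-normal perturbation weight (default 1e-4)
#' @param eps relative facet-confirmation tolerance (default 1e-9)
#' @return a `pareto_set` of supported solutions (all flagged supported),
#'   sorted by the first objective of the pair; attribute `"n_solves"` counts
#'   scalar solves
#' @export
nise_biobjective <- function(net, origin, destination, objectives = c(1, 2),
                             delta = 1e-4, eps = 1e-9) {
  objectives <- as.integer(objectives)
  if (length(objectives) != 2L || anyDuplicated(objectives) ||
      !all(objectives %in% 1:3))
    stop_pp("objectives must be two distinct indices in 1:3",
            "paretopaths_domain")
  p <- objectives[1]; q <- objectives[2]
  scales <- objective_scales(net, origin, destination)
  n_solves <- 3L  # scale probes

  solve_pair <- function(wp, wq) {
    w <- numeric(3)
    w[p] <- wp; w[q] <- wq
    n_solves <<- n_solves + 1L
    solve_scaled(net, origin, destination, w, scales)
  }
  proj <- function(path) path$objectives[c(p, q)] / scales[c(p, q)]

  ya_path <- solve_pair(1 - delta, delta)   # anchor: min objective p
  yb_path <- solve_pair(delta, 1 - delta)   # anchor: min objective q

  sols <- list(ya_path)
  vecs <- matrix(proj(ya_path), 1, 2)
  if (!vec_close(proj(ya_path), proj(yb_path))) {
    sols <- c(sols, list(yb_path))
    vecs <- rbind(vecs, proj(yb_path))
  }

  if (nrow(vecs) == 2L) {
    # depth-first segment refinement between adjacent frontier points
    explore <- function(ya, yb) {
      w2 <- c(ya[2] - yb[2], yb[1] - ya[1])  # inward normal of the segment
      if (any(w2 <= 0)) return(invisible(NULL))
      w2 <- w2 / sum(w2)
      if (any(w2 < 1e-12)) {
        # near-axis-parallel facet: nudge toward the simplex interior
        w2 <- pmax(w2, delta)
        w2 <- w2 / sum(w2)
      }
      path <- solve_pair(w2[1], w2[2])
      y <- proj(path)
      level <- min(sum(w2 * ya), sum(w2 * yb))
      if (sum(w2 * y) >= level - eps * max(1, abs(level)))
        return(invisible(NULL))
      if (match_row(y, vecs) > 0L) return(invisible(NULL))
      sols[[length(sols) + 1L]] <<- path
      vecs <<- rbind(vecs, y)
      explore(ya, y)
      explore(y, yb)
    }
    explore(proj(ya_path), proj(yb_path))
  }

  ord <- order(vecs[, 1], vecs[, 2])
  ps <- new_pareto_set(origin, destination, sols[ord],
                       supported = rep(TRUE, length(sols)))
  attr(ps, "objective_pair") <- objectives
  attr(ps, "n_solves") <- n_solves
  ps
}
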