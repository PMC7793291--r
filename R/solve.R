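#' Weight vector for scalarised solves
#'
#' @param w numeric length-3, nonnegative, summing to 1 (tolerance 1e-9)
#' @param provenance optional tag ("anchor", "plane-normal", ...)
#' @return validated numeric weight vector with attribute `provenance`
#' @export
weight_vector <- function(w, provenance = NULL) {
  w <- as.numeric(w)
  if (length(w) != 3L || any(!is.finite(w)))
    stop_pp("weight vector must be three finite numbers", "paretopaths_domain")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_pp("weights must be nonnegative and sum to 1 (tolerance 1e-9)",
            "paretopaths_domain")
  if (!is.null(provenance)) attr(w, "provenance") <- provenance
  w
}

#' Weighted single-objective least-cost path
#'
#' Solves the scalarised problem `min w1*f1 + w2*f2 + w3*f3` over all
#' origin-destination paths, where `f1` is cumulative log-risk, `f2`
#' cumulative moisture-weighted distance and `f3` cumulative elevation cost.
#' With all arc costs nonnegative the continuous relaxation of the
#' arc-selection formulation is integral, so a label-setting (Dijkstra)
#' search on the scalarised arc cost solves it exactly. Ties between
#' equal-cost paths are broken lexicographically by the objective triple
#' `(f1, f2, f3)` and then by predecessor arc index, so the returned path is
#' deterministic.
#'
#' @param net a [landscape_network()] with derived costs
#' @param origin,destination node ids (`origin != destination`)
#' @param w weights; see [weight_vector()]
#' @return a `habitat_path` minimising the scalarised cost
#' @export
solve_weighted <- function(net, origin, destination, w) {
  require_costs(net)
  w <- weight_vector(w, attr(w, "provenance"))
  o <- node_index(net, origin)
  d <- node_index(net, destination)
  if (o == d) stop_pp("origin equals destination", "paretopaths_domain")
  res <- dijkstra_scalar(net, o, w, target = d)
  if (is.na(res$pred_arc[d]) && !res$done[d])
    stop_pp(paste0("no path from ", origin, " to ", destination),
            "paretopaths_no_path")
  backtrack_dijkstra(net, res, origin, destination, d, w)
}

#' Anchor solution for one objective
#'
#' Minimises objective `l` while giving the two other objectives a small
#' positive weight `delta` (weights `1 - 2*delta` on `l`, `delta` elsewhere),
#' so that among the minimisers of objective `l` an efficient -- not merely
#' weakly efficient -- path is returned.
#'
#' @param net a [landscape_network()] with derived costs
#' @param origin,destination node ids
#' @param objective which objective to anchor, 1 (risk), 2 (moisture-weighted
#'   distance) or 3 (elevation cost)
#' @param delta small positive tie-breaking weight, `0 < delta < 1/3`
#'   (default 1e-4)
#' @return a `habitat_path`
#' @export
solve_anchor <- function(net, origin, destination, objective, delta = 1e-4) {
  if (!(objective %in% 1:3))
    stop_pp("objective must be 1, 2 or 3", "paretopaths_domain")
  if (!(delta > 0 && delta < 1/3))
    stop_pp("delta must lie in (0, 1/3)", "paretopaths_domain")
  w <- rep(delta, 3)
  w[objective] <- 1 - 2 * delta
  solve_weighted(net, origin, destination, weight_vector(w, "anchor"))
}

# Dijkstra on the scalarised arc cost with deterministic tie-breaks.
# Returns dist, accumulated objective triples, predecessor arcs, done mask.
dijkstra_scalar <- function(net, o, w, target = NULL) {
  n <- nrow(net$nodes)
  obj <- arc_objectives(net)
  cost <- as.numeric(obj %*% w)
  dist <- rep(Inf, n)
  f <- matrix(Inf, n, 3)
  pred_arc <- rep(NA_integer_, n)
  done <- logical(n)
  dist[o] <- 0
  f[o, ] <- 0

  to_idx <- net$arcs$.to_idx
  for (iter in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    # min scalar cost; ties by lexicographic objective triple, then index
    i <- cand[order(dist[cand], f[cand, 1], f[cand, 2], f[cand, 3], cand)[1]]
    done[i] <- TRUE
    if (!is.null(target) && i == target) break
    for (a in net$.adj[[i]]) {
      j <- to_idx[a]
      if (done[j]) next  # never re-enter a finalized node (zero-cost cycles)
      nd <- dist[i] + cost[a]
      if (nd < dist[j]) {
        better <- TRUE
      } else if (nd == dist[j]) {
        nf <- f[i, ] + obj[a, ]
        cmp <- lex_cmp(nf, f[j, ])
        better <- cmp < 0 ||
          (cmp == 0 && (is.na(pred_arc[j]) || a < pred_arc[j]))
      } else better <- FALSE
      if (better) {
        dist[j] <- nd
        f[j, ] <- f[i, ] + obj[a, ]
        pred_arc[j] <- a
      }
    }
  }
  list(dist = dist, f = f, pred_arc = pred_arc, done = done)
}

lex_cmp <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

backtrack_dijkstra <- function(net, res, origin, destination, d, w) {
  arcs <- integer(0)
  i <- d
  from_idx <- net$arcs$.from_idx
  while (!is.na(res$pred_arc[i])) {
    a <- res$pred_arc[i]
    arcs <- c(a, arcs)
    i <- from_idx[a]
  }
  if (net$nodes$id[i] != origin)
    stop_pp(paste0("no path from ", origin, " to ", destination),
            "paretopaths_no_path")
  node_seq <- c(origin, net$nodes$id[net$arcs$.to_idx[arcs]])
  v <- res$f[d, ]
  names(v) <- c("log_risk", "mwd", "elev")
  new_path(origin, destination, node_seq, arcs, v, weight = as.numeric(w))
}
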