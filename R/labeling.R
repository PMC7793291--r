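#' Merge a candidate label into a non-dominated label set
#'
#' The filtering step of the multi-criteria labeling algorithm: the candidate
#' objective triple is inserted iff no existing label dominates it and (when
#' `dedupe_equal`) no existing label equals it; any existing labels the
#' candidate dominates are removed.
#'
#' @param existing numeric matrix of mutually non-dominated label triples
#'   (possibly 0 rows)
#' @param candidate numeric triple
#' @param dedupe_equal drop a candidate whose triple already occurs
#'   (default TRUE). With `FALSE`, equal triples coexist, which is what the
#'   full path enumeration uses to keep alternative routes of equal cost.
#' @return list with `labels` (updated matrix), `changed` (logical), and
#'   `kept` (was the candidate inserted)
#' @export
merge_labels <- function(existing, candidate, dedupe_equal = TRUE) {
  existing <- as.matrix(existing)
  if (nrow(existing)) {
    for (r in seq_len(nrow(existing))) {
      e <- existing[r, ]
      if (all(e <= candidate) && (any(e < candidate))) {
        return(list(labels = existing, changed = FALSE, kept = FALSE))
      }
      if (dedupe_equal && all(e == candidate))
        return(list(labels = existing, changed = FALSE, kept = FALSE))
    }
    dom <- vapply(seq_len(nrow(existing)), function(r)
      dominates(candidate, existing[r, ]), logical(1))
    existing <- existing[!dom, , drop = FALSE]
  }
  list(labels = rbind(existing, candidate, deparse.level = 0),
       changed = TRUE, kept = TRUE)
}

#' All non-dominated least-cost paths from one origin
#'
#' Multi-criteria label-correcting search (Bellman-Ford style with FIFO
#' reconsideration) computing, for every destination, the complete set of
#' efficient paths -- supported and unsupported -- under the three additive
#' objectives. Each node accumulates a set of labels
#' `(g1, g2, g3, pred_node, pred_label)`; extending a label along an arc adds
#' the arc's objective triple, strictly dominated labels are pruned on
#' insertion, and a node whose label set changed is queued for
#' reconsideration. Labels whose path would revisit a node are discarded, so
#' the search enumerates simple paths only and terminates even across
#' zero-cost wetland-internal cycles. Backtracking through the predecessor
#' references reconstructs every surviving path.
#'
#' Labels with exactly equal objective triples but different routes are all
#' retained during the search; by default the reported set collapses each
#' distinct objective vector to its lexicographically smallest node sequence
#' (`keep_equal_vectors = TRUE` reports every route).
#'
#' @param net a [landscape_network()] with derived costs
#' @param origin origin node id
#' @param destinations node ids to report (default: representative nodes of
#'   all wetlands other than the origin's; all other nodes if the network has
#'   no wetlands)
#' @param keep_equal_vectors report all routes per objective vector
#' @param classify run [classify_supported()] on each destination's frontier
#'   (default FALSE)
#' @param max_labels guard on the total number of labels (default 1e6)
#' @return named list of `pareto_set`, one per destination (empty set for
#'   unreachable destinations)
#' @export
label_all <- function(net, origin, destinations = NULL,
                      keep_equal_vectors = FALSE, classify = FALSE,
                      max_labels = 1e6) {
  require_costs(net)
  o <- node_index(net, origin)
  if (is.null(destinations)) {
    reps <- wetland_representatives(net)
    if (length(reps)) {
      ow <- net$nodes$wetland_id[o]
      destinations <- reps[is.na(ow) | names(reps) != ow]
    } else {
      destinations <- setdiff(net$nodes$id, origin)
    }
  }
  destinations <- unname(as.character(destinations))
  d_idx <- node_index(net, destinations)

  n <- nrow(net$nodes)
  obj <- arc_objectives(net)
  to_idx <- net$arcs$.to_idx

  G <- vector("list", n)        # k x 3 objective accumulators per node
  PRED <- vector("list", n)     # k x 2 (pred node, pred label row)
  alive <- vector("list", n)
  n_ext <- integer(n)           # labels of this node already extended
  for (i in seq_len(n)) {
    G[[i]] <- matrix(numeric(0), 0, 3)
    PRED[[i]] <- matrix(integer(0), 0, 2)
    alive[[i]] <- logical(0)
  }
  G[[o]] <- matrix(0, 1, 3)
  PRED[[o]] <- matrix(NA_integer_, 1, 2)
  alive[[o]] <- TRUE

  queue <- c(o)
  in_q <- logical(n)
  in_q[o] <- TRUE
  total_labels <- 1L

  # nodes on the path ending at label (i, li)
  path_nodes <- function(i, li) {
    out <- i
    while (!is.na(PRED[[i]][li, 1])) {
      p <- PRED[[i]][li, ]
      i <- p[1]; li <- p[2]
      out <- c(out, i)
    }
    out
  }

  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    in_q[i] <- FALSE
    k <- nrow(G[[i]])
    if (n_ext[i] >= k) next
    new_rows <- (n_ext[i] + 1L):k
    n_ext[i] <- k
    for (a in net$.adj[[i]]) {
      j <- to_idx[a]
      t3 <- obj[a, ]
      for (li in new_rows) {
        if (!alive[[i]][li]) next
        # simple-path restriction: do not revisit j
        if (j %in% path_nodes(i, li)) next
        cand <- G[[i]][li, ] + t3
        gj <- G[[j]]
        aj <- alive[[j]]
        # prune iff strictly dominated by a living label at j
        skip <- FALSE
        if (nrow(gj)) {
          for (r in which(aj)) {
            e <- gj[r, ]
            if (all(e <= cand) && any(e < cand)) { skip <- TRUE; break }
          }
        }
        if (skip) next
        # kill living labels the candidate strictly dominates
        if (nrow(gj)) {
          for (r in which(aj)) {
            e <- gj[r, ]
            if (all(cand <= e) && any(cand < e)) alive[[j]][r] <- FALSE
          }
        }
        G[[j]] <- rbind(G[[j]], cand, deparse.level = 0)
        PRED[[j]] <- rbind(PRED[[j]], c(i, li), deparse.level = 0)
        alive[[j]] <- c(alive[[j]], TRUE)
        total_labels <- total_labels + 1L
        if (total_labels > max_labels)
          stop_pp(paste0("label count exceeds guard (", max_labels, ")"),
                  "paretopaths_label_guard")
        if (!in_q[j]) { queue <- c(queue, j); in_q[j] <- TRUE }
      }
    }
  }

  # Stage C: backtrack every surviving label at each destination
  arc_of <- arc_lookup(net)
  out <- vector("list", length(d_idx))
  names(out) <- destinations
  for (k in seq_along(d_idx)) {
    d <- d_idx[k]
    live <- which(alive[[d]])
    paths <- lapply(live, function(li) {
      nd <- rev(path_nodes(d, li))
      arcs <- arc_of[cbind(nd[-length(nd)], nd[-1])]
      v <- G[[d]][li, ]
      names(v) <- c("log_risk", "mwd", "elev")
      new_path(origin, destinations[k], net$nodes$id[nd], arcs, v)
    })
    out[[k]] <- finalize_frontier(origin, destinations[k], paths,
                                  keep_equal_vectors, classify = classify)
  }
  out
}

# dense (from_idx, to_idx) -> arc row lookup
arc_lookup <- function(net) {
  n <- nrow(net$nodes)
  m <- matrix(NA_integer_, n, n)
  m[cbind(net$arcs$.from_idx, net$arcs$.to_idx)] <- seq_len(nrow(net$arcs))
  m
}
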