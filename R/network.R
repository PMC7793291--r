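#' Attributed landscape network
#'
#' Builds the directed, attributed graph on which all path analyses operate.
#' Nodes carry planar coordinates, elevation and (optionally) a wetland
#' membership; arcs carry a length, a land-cover class and -- either supplied
#' directly or filled in by [derive_costs()] -- the three per-arc objective
#' attributes: additive log-risk of traversal failure, moisture-weighted
#' distance, and elevation-change cost. Undirected field adjacencies must be
#' represented as two directed arcs because the elevation cost is
#' direction-dependent.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `elevation`; optional
#'   `land_cover`, `twi`, `wetland_id` (NA for non-habitat nodes),
#'   `is_entrance`.
#' @param arcs data.frame with columns `from`, `to`, `length`; optional
#'   `land_cover`, `moisture`, `risk`, `log_risk`, `mwd`, `elev_cost`.
#' @param validate check structural invariants (referential integrity,
#'   nonnegative lengths, risks below 1). Default `TRUE`.
#' @return object of class `landscape_network`: a list with elements `nodes`,
#'   `arcs`, `wetlands` (data.frame of habitat ids with node membership) and
#'   internal adjacency indices.
#' @export
landscape_network <- function(nodes, arcs, validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)

  need_n <- c("id", "x", "y", "elevation")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss))
    stop_pp(paste0("node table lacks column(s): ", paste(miss, collapse = ", ")),
            "paretopaths_validation")
  need_a <- c("from", "to", "length")
  miss <- setdiff(need_a, names(arcs))
  if (length(miss))
    stop_pp(paste0("arc table lacks column(s): ", paste(miss, collapse = ", ")),
            "paretopaths_validation")

  nodes$id <- as.character(nodes$id)
  arcs$from <- as.character(arcs$from)
  arcs$to <- as.character(arcs$to)
  if (is.null(nodes$wetland_id)) nodes$wetland_id <- NA_character_
  nodes$wetland_id <- as.character(nodes$wetland_id)
  if (is.null(nodes$is_entrance)) nodes$is_entrance <- !is.na(nodes$wetland_id)
  for (col in c("land_cover", "moisture", "risk", "log_risk", "mwd", "elev_cost"))
    if (is.null(arcs[[col]])) arcs[[col]] <- NA
  if (is.null(arcs$base_risk)) arcs$base_risk <- NA_real_

  if (validate) {
    if (anyDuplicated(nodes$id))
      stop_pp(paste0("duplicate node id(s): ",
                     paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")),
              "paretopaths_validation")
    if (any(!is.finite(nodes$elevation)))
      stop_pp("non-finite node elevations", "paretopaths_validation")
    bad <- which(!(arcs$from %in% nodes$id) | !(arcs$to %in% nodes$id))
    if (length(bad))
      stop_pp(paste0("arc(s) reference missing node(s), rows: ",
                     paste(utils::head(bad, 10), collapse = ", "),
                     " (", arcs$from[bad[1]], " -> ", arcs$to[bad[1]], ")"),
              "paretopaths_validation")
    if (any(arcs$length < 0, na.rm = TRUE))
      stop_pp(paste0("negative arc length(s), rows: ",
                     paste(which(arcs$length < 0), collapse = ", ")),
              "paretopaths_validation")
    if (any(arcs$risk >= 1, na.rm = TRUE))
      stop_pp(paste0("arc risk >= 1 (log transform undefined), rows: ",
                     paste(which(arcs$risk >= 1), collapse = ", ")),
              "paretopaths_validation")
    key <- paste(arcs$from, arcs$to, sep = "\r")
    if (anyDuplicated(key))
      stop_pp("duplicate directed arc(s); at most one arc per ordered node pair",
              "paretopaths_validation")
  }

  # wetland membership: arcs whose two endpoints share a habitat polygon are
  # internal and carry zero cost after derivation
  widx <- match(arcs$from, nodes$id)
  wjdx <- match(arcs$to, nodes$id)
  wi <- nodes$wetland_id[widx]
  wj <- nodes$wetland_id[wjdx]
  arcs$wetland_internal <- !is.na(wi) & !is.na(wj) & wi == wj

  wl <- unique(nodes$wetland_id[!is.na(nodes$wetland_id)])
  wetlands <- data.frame(wetland_id = wl, stringsAsFactors = FALSE)
  wetlands$nodes <- lapply(wl, function(w) nodes$id[!is.na(nodes$wetland_id) &
                                                      nodes$wetland_id == w])

  net <- structure(list(nodes = nodes, arcs = arcs, wetlands = wetlands),
                   class = "landscape_network")
  net <- reindex_network(net)
  net
}

# adjacency cache: arc rows grouped by origin node index
reindex_network <- function(net) {
  n <- nrow(net$nodes)
  fi <- match(net$arcs$from, net$nodes$id)
  ti <- match(net$arcs$to, net$nodes$id)
  net$arcs$.from_idx <- fi
  net$arcs$.to_idx <- ti
  adj <- vector("list", n)
  sp <- split(seq_len(nrow(net$arcs)), factor(fi, levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- sp[[i]]
  net$.adj <- adj
  net
}

#' @export
print.landscape_network <- function(x, ...) {
  cat("landscape_network:", nrow(x$nodes), "nodes,", nrow(x$arcs),
      "directed arcs,", nrow(x$wetlands), "wetlands\n")
  if (has_costs(x)) {
    cat("objective attributes derived (log_risk, mwd, elev_cost)\n")
  } else {
    cat("raw attributes only; run derive_costs() before solving\n")
  }
  invisible(x)
}

#' @export
summary.landscape_network <- function(object, ...) {
  a <- object$arcs[!object$arcs$wetland_internal, , drop = FALSE]
  stats <- function(v) c(mean = mean(v), sd = stats::sd(v),
                         min = min(v), max = max(v))
  out <- list(n_nodes = nrow(object$nodes), n_arcs = nrow(object$arcs),
              n_wetlands = nrow(object$wetlands))
  if (nrow(a) && all(!is.na(a$length))) out$length <- stats(a$length)
  if (has_costs(object)) {
    out$risk <- stats(a$risk)
    out$mwd <- stats(a$mwd)
    out$elev_cost <- stats(a$elev_cost)
  }
  class(out) <- "summary.landscape_network"
  out
}

#' @export
print.summary.landscape_network <- function(x, ...) {
  cat("landscape network:", x$n_nodes, "nodes /", x$n_arcs, "arcs /",
      x$n_wetlands, "wetlands\n")
  for (nm in c("length", "risk", "mwd", "elev_cost"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-10s mean %.4g sd %.4g min %.4g max %.4g\n", nm,
                  x[[nm]]["mean"], x[[nm]]["sd"], x[[nm]]["min"], x[[nm]]["max"]))
  invisible(x)
}

has_costs <- function(net) {
  all(c("log_risk", "mwd", "elev_cost") %in% names(net$arcs)) &&
    !anyNA(net$arcs$log_risk) && !anyNA(net$arcs$mwd) && !anyNA(net$arcs$elev_cost)
}

require_costs <- function(net) {
  if (!has_costs(net))
    stop_pp("network has no derived objective attributes; run derive_costs()",
            "paretopaths_validation")
  invisible(net)
}

node_index <- function(net, id) {
  i <- match(id, net$nodes$id)
  if (anyNA(i))
    stop_pp(paste0("unknown node id(s): ", paste(id[is.na(i)], collapse = ", ")),
            "paretopaths_validation")
  i
}

# per-arc objective triple matrix (rows aligned with net$arcs)
arc_objectives <- function(net) {
  cbind(log_risk = net$arcs$log_risk, mwd = net$arcs$mwd,
        elev = net$arcs$elev_cost)
}

#' Representative habitat nodes
#'
#' One node id per wetland, used as the origin/destination of inter-habitat
#' analyses. Because arcs internal to a habitat polygon carry zero cost, the
#' choice of representative does not change any path's objective vector; the
#' first entrance node (falling back to the first member node) is used.
#'
#' @param net a [landscape_network()]
#' @return named character vector, names = wetland ids
#' @export
wetland_representatives <- function(net) {
  if (nrow(net$wetlands) == 0L) return(character(0))
  out <- vapply(seq_len(nrow(net$wetlands)), function(k) {
    ids <- net$wetlands$nodes[[k]]
    ent <- ids[net$nodes$is_entrance[match(ids, net$nodes$id)]]
    if (length(ent)) ent[1] else ids[1]
  }, character(1))
  names(out) <- net$wetlands$wetland_id
  out
}

# ---------------------------------------------------------------------------
# paths

new_path <- function(origin, destination, node_seq, arc_idx, objectives,
                     supported = NA, weight = NULL) {
  structure(list(origin = origin, destination = destination,
                 nodes = node_seq, arcs = arc_idx,
                 objectives = objectives, supported = supported,
                 weight = weight),
            class = "habitat_path")
}

#' @export
print.habitat_path <- function(x, ...) {
  cat("habitat path ", x$origin, " -> ", x$destination, " (",
      length(x$arcs), " arcs)\n", sep = "")
  cat("  route: ", paste(x$nodes, collapse = " > "), "\n", sep = "")
  cat(sprintf("  log-risk %.6g (failure prob %.4g), moisture-weighted distance %.6g, elevation cost %.6g\n",
              x$objectives[1], failure_probability(x$objectives[1]),
              x$objectives[2], x$objectives[3]))
  if (!is.na(x$supported))
    cat("  ", if (x$supported) "supported" else "unsupported",
        " efficient solution\n", sep = "")
  invisible(x)
}

#' Evaluate a path's objective vector
#'
#' Sums the three per-arc objective attributes over a connected walk from the
#' path's origin to its destination: cumulative log-risk (additive form of the
#' traversal-failure probability), cumulative moisture-weighted distance, and
#' cumulative elevation cost. The empty path (origin equal to destination)
#' evaluates to the zero vector.
#'
#' @param path a `habitat_path`, or a list with elements `origin`,
#'   `destination` and `arcs` (row indices into `network$arcs`)
#' @param network a [landscape_network()] with derived costs
#' @return named numeric triple `(log_risk, mwd, elev)`
#' @export
evaluate_path <- function(path, network) {
  require_costs(network)
  idx <- path$arcs
  obj <- c(log_risk = 0, mwd = 0, elev = 0)
  if (length(idx) == 0L) {
    if (!identical(path$origin, path$destination))
      stop_pp("empty arc list but origin != destination", "paretopaths_structure")
    return(obj)
  }
  a <- network$arcs[idx, , drop = FALSE]
  if (a$from[1] != path$origin)
    stop_pp(paste0("path does not start at its origin (first arc leaves ",
                   a$from[1], ")"), "paretopaths_structure")
  if (a$to[nrow(a)] != path$destination)
    stop_pp(paste0("path does not end at its destination (last arc enters ",
                   a$to[nrow(a)], ")"), "paretopaths_structure")
  if (nrow(a) > 1L) {
    brk <- which(a$to[-nrow(a)] != a$from[-1])
    if (length(brk))
      stop_pp(paste0("disconnected arc sequence at position ", brk[1], ": arc ",
                     a$from[brk[1]], "->", a$to[brk[1]], " followed by ",
                     a$from[brk[1] + 1], "->", a$to[brk[1] + 1]),
              "paretopaths_structure")
  }
  c(log_risk = sum(a$log_risk), mwd = sum(a$mwd), elev = sum(a$elev_cost))
}

#' Traversal failure probability from cumulative log-risk
#'
#' Converts the additive risk objective `f1 = sum(ln(1/(1 - pi_ij)))` back to
#' the probability that traversal of the whole path fails,
#' `1 - prod(1 - pi_ij) = 1 - exp(-f1)`. Strictly increasing in `f1`, so path
#' orderings under either form agree.
#'
#' @param f1 nonnegative cumulative log-risk (vectorised)
#' @return failure probability in `[0, 1)`
#' @export
failure_probability <- function(f1) {
  if (any(f1 < 0))
    stop_pp("cumulative log-risk must be nonnegative", "paretopaths_domain")
  -expm1(-f1)
}

# ---------------------------------------------------------------------------
# Pareto set container

new_pareto_set <- function(origin, destination, paths, supported = NULL) {
  obj <- if (length(paths)) t(vapply(paths, function(p) p$objectives, numeric(3)))
         else matrix(numeric(0), 0, 3)
  colnames(obj) <- c("log_risk", "mwd", "elev")
  if (!is.null(supported) && length(supported) == length(paths))
    for (k in seq_along(paths)) paths[[k]]$supported <- supported[k]
  structure(list(origin = origin, destination = destination, paths = paths,
                 objectives = obj,
                 supported = supported %||% rep(NA, length(paths))),
            class = "pareto_set")
}

#' @export
print.pareto_set <- function(x, ...) {
  ns <- sum(x$supported, na.rm = TRUE)
  nu <- sum(!x$supported, na.rm = TRUE)
  cat("pareto_set ", x$origin, " -> ", x$destination, ": ",
      length(x$paths), " non-dominated path(s)", sep = "")
  if (!all(is.na(x$supported)))
    cat(" (", ns, " supported, ", nu, " unsupported)", sep = "")
  cat("\n")
  if (nrow(x$objectives)) {
    df <- as.data.frame(x$objectives)
    df$failure_prob <- failure_probability(df$log_risk)
    if (!all(is.na(x$supported))) df$supported <- x$supported
    print(utils::head(df[order(df$log_risk), ], 15), row.names = FALSE)
    if (nrow(df) > 15) cat("  ... and", nrow(df) - 15, "more\n")
  }
  invisible(x)
}
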