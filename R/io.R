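#' Read a landscape network from CSV tables
#'
#' Native schema: a node table with columns `id, x, y, elevation` (optional
#' `land_cover, twi, wetland_id, is_entrance`) and an arc table with one row
#' per *directed* arc, columns `from, to, length` (optional precomputed
#' `pi/risk, m/moisture, z/elev_cost, mwd, log_risk, land_cover`). Common
#' column synonyms are normalised (`elev` for `elevation`, `pi` for `risk`,
#' `z` for `elev_cost`, `m` for `moisture`, `len`/`dist` for `length`,
#' `wetland` for `wetland_id`); a table whose adjacencies appear only once is
#' treated as undirected and expanded to two directed arcs per adjacency.
#' Unknown columns are preserved untouched on the returned tables.
#'
#' Validation failures (missing endpoint nodes, negative lengths, risks at or
#' above 1, duplicate ids) raise errors naming the offending rows.
#'
#' @param node_file,arc_file CSV paths (or anything `read.csv` accepts)
#' @return a [landscape_network()]; if the derived-cost columns were absent,
#'   run [derive_costs()] before solving
#' @export
read_network <- function(node_file, arc_file) {
  nodes <- utils::read.csv(node_file, stringsAsFactors = FALSE)
  arcs <- utils::read.csv(arc_file, stringsAsFactors = FALSE)
  nodes <- rename_synonyms(nodes, list(
    elevation = c("elevation", "elev", "e", "z"),
    wetland_id = c("wetland_id", "wetland", "habitat_id"),
    twi = c("twi", "wetness", "m")))
  arcs <- rename_synonyms(arcs, list(
    from = c("from", "i", "source", "tail"),
    to = c("to", "j", "target", "head"),
    length = c("length", "len", "dist", "distance", "c", "cij"),
    risk = c("risk", "pi", "pij"),
    moisture = c("moisture", "m", "mij"),
    elev_cost = c("elev_cost", "z", "zij"),
    mwd = c("mwd", "moisture_weighted_distance", "wdist"),
    log_risk = c("log_risk", "lnrisk")))
  if ("risk" %in% names(arcs) && !("log_risk" %in% names(arcs)) &&
      !anyNA(arcs$risk))
    arcs$log_risk <- -log1p(-arcs$risk)
  # sniff undirected storage: no adjacency present in both directions
  key <- paste(arcs$from, arcs$to, sep = "\r")
  rev_key <- paste(arcs$to, arcs$from, sep = "\r")
  if (nrow(arcs) && !any(rev_key %in% key)) {
    back <- arcs
    back$from <- arcs$to
    back$to <- arcs$from
    arcs <- rbind(arcs, back)
  }
  landscape_network(nodes, arcs)
}

rename_synonyms <- function(df, spec) {
  low <- tolower(names(df))
  for (canon in names(spec)) {
    if (canon %in% names(df)) next
    hit <- which(low %in% tolower(spec[[canon]]))
    if (length(hit)) names(df)[hit[1]] <- canon
  }
  df
}

#' Write a landscape network to CSV tables
#'
#' Inverse of [read_network()] under the native schema (one row per directed
#' arc; internal index columns are dropped).
#'
#' @param net a [landscape_network()]
#' @param node_file,arc_file output CSV paths
#' @return `net`, invisibly
#' @export
write_network <- function(net, node_file, arc_file) {
  nodes <- net$nodes
  arcs <- net$arcs
  arcs <- arcs[, !startsWith(names(arcs), "."), drop = FALSE]
  arcs$wetland_internal <- NULL
  drop_all_na <- function(df) df[, vapply(df, function(c) !all(is.na(c)),
                                          logical(1)), drop = FALSE]
  utils::write.csv(drop_all_na(nodes), node_file, row.names = FALSE)
  utils::write.csv(drop_all_na(arcs), arc_file, row.names = FALSE)
  invisible(net)
}

#' Efficient frontiers for every wetland origin-destination pair
#'
#' Convenience driver: runs either the label-correcting search (one run per
#' origin wetland; complete efficient sets, classified supported /
#' unsupported) or MONISE (one run per ordered pair; supported solutions
#' only) between the representative nodes of all wetland pairs.
#'
#' @param net a [landscape_network()] with derived costs and `>= 2` wetlands
#' @param method `"labeling"` or `"monise"`
#' @param classify classify supported/unsupported (labeling only; MONISE
#'   output is supported by construction). Default TRUE.
#' @param ... passed to [label_all()] or [monise()]
#' @return named list of `pareto_set`, names `"<origin_wetland>-><dest_wetland>"`
#' @export
od_frontiers <- function(net, method = c("labeling", "monise"),
                         classify = TRUE, ...) {
  method <- match.arg(method)
  reps <- wetland_representatives(net)
  if (length(reps) < 2)
    stop_pp("need >= 2 wetlands for OD analysis", "paretopaths_validation")
  out <- list()
  if (method == "labeling") {
    for (ow in names(reps)) {
      res <- label_all(net, reps[[ow]],
                       destinations = reps[setdiff(names(reps), ow)],
                       classify = classify, ...)
      for (dw in names(res))
        out[[paste0(ow, "->", dw)]] <- res[[dw]]
    }
    # key destinations by wetland id rather than node id
    names(out) <- vapply(strsplit(names(out), "->", fixed = TRUE), function(p) {
      dn <- p[2]
      dw <- names(reps)[match(dn, reps)]
      paste0(p[1], "->", if (is.na(dw)) dn else dw)
    }, character(1))
  } else {
    for (ow in names(reps)) for (dw in setdiff(names(reps), ow))
      out[[paste0(ow, "->", dw)]] <- monise(net, reps[[ow]], reps[[dw]], ...)
  }
  out
}

#' Per-wetland and per-objective summaries of efficient path sets
#'
#' Given classified frontiers over origin-destination pairs (as produced by
#' [od_frontiers()]), tabulates (a) the number of supported, unsupported and
#' total non-dominated paths entering and leaving each wetland and (b)
#' mean/SD/min/max of each movement objective split by supported status,
#' with the cumulative log-risk reported as the probability of successful
#' traversal `exp(-f1)`.
#'
#' @param results named list of `pareto_set` with names `"W1->W2"` style
#' @return list with data.frames `wetland_counts` and `objective_summary`
#' @export
report_frontiers <- function(results) {
  ods <- strsplit(names(results), "->", fixed = TRUE)
  origins <- vapply(ods, `[`, character(1), 1)
  dests <- vapply(ods, `[`, character(1), 2)
  wl <- sort(unique(c(origins, dests)))

  counts <- data.frame(wetland_id = wl,
                       supported_in = 0L, supported_out = 0L,
                       unsupported_in = 0L, unsupported_out = 0L,
                       all_in = 0L, all_out = 0L, stringsAsFactors = FALSE)
  rownames(counts) <- wl
  rows <- list()
  for (k in seq_along(results)) {
    ps <- results[[k]]
    ns <- sum(ps$supported %in% TRUE)
    nu <- sum(ps$supported %in% FALSE)
    na_ <- length(ps$paths)
    counts[dests[k], "supported_in"] <- counts[dests[k], "supported_in"] + ns
    counts[origins[k], "supported_out"] <- counts[origins[k], "supported_out"] + ns
    counts[dests[k], "unsupported_in"] <- counts[dests[k], "unsupported_in"] + nu
    counts[origins[k], "unsupported_out"] <- counts[origins[k], "unsupported_out"] + nu
    counts[dests[k], "all_in"] <- counts[dests[k], "all_in"] + na_
    counts[origins[k], "all_out"] <- counts[origins[k], "all_out"] + na_
    if (na_)
      rows[[length(rows) + 1L]] <-
        data.frame(ps$objectives, supported = ps$supported)
  }
  rownames(counts) <- NULL

  obj <- if (length(rows)) do.call(rbind, rows)
         else data.frame(log_risk = numeric(0), mwd = numeric(0),
                         elev = numeric(0), supported = logical(0))
  obj$success_prob <- exp(-obj$log_risk)
  summ <- do.call(rbind, lapply(c(TRUE, FALSE), function(flag) {
    sub <- obj[obj$supported %in% flag, , drop = FALSE]
    do.call(rbind, lapply(c("success_prob", "mwd", "elev"), function(v) {
      x <- sub[[v]]
      data.frame(supported = flag, attribute = v, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  list(wetland_counts = counts, objective_summary = summ)
}

#' Arc usage by a set of paths
#'
#' Counts, for each directed arc and each undirected adjacency, how many of
#' the given paths traverse it, together with the fraction of arcs traversed
#' at least once and never traversed.
#'
#' @param paths list of `habitat_path` (or of `pareto_set`, whose paths are
#'   pooled)
#' @param net the [landscape_network()] the paths refer to
#' @return list with `arc_counts` (directed), `adjacency_counts`
#'   (undirected), `frac_used`, `frac_unused`
#' @export
report_arc_usage <- function(paths, net) {
  if (length(paths) && inherits(paths[[1]], "pareto_set"))
    paths <- unlist(lapply(paths, `[[`, "paths"), recursive = FALSE)
  counts <- integer(nrow(net$arcs))
  for (p in paths)
    counts[p$arcs] <- counts[p$arcs] + 1L
  arc_counts <- data.frame(from = net$arcs$from, to = net$arcs$to,
                           n_paths = counts, stringsAsFactors = FALSE)
  ukey <- ifelse(net$arcs$from < net$arcs$to,
                 paste(net$arcs$from, net$arcs$to, sep = "|"),
                 paste(net$arcs$to, net$arcs$from, sep = "|"))
  und <- stats::aggregate(list(n_paths = counts), by = list(adjacency = ukey),
                          FUN = sum)
  list(arc_counts = arc_counts,
       adjacency_counts = und,
       frac_used = mean(counts > 0),
       frac_unused = mean(counts == 0))
}
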