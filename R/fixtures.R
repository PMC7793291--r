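#' Specification for a synthetic landscape
#'
#' Parameters of the seeded generator in [make_landscape()], which emulates
#' the structure of a vector-based wetland landscape network: a smooth random
#' elevation field on a planar grid, categorical land cover with per-class
#' base traversal risk, wetland habitat patches placed at local elevation
#' minima with zero-cost internal arcs, and a topographic-wetness surface
#' anticorrelated with elevation.
#'
#' @param seed integer RNG seed; the generated network is a deterministic
#'   function of the spec
#' @param grid_n nodes per grid side (default 3)
#' @param n_wetlands number of habitat patches, `>= 2` (default 2)
#' @param wetland_size nodes per patch (default 2; patches of 2+ nodes carry
#'   zero-cost internal arcs, exercising zero-cost cycles)
#' @param spacing grid spacing in meters (default 50, a typical inter-node
#'   distance for a fine vector landscape discretisation)
#' @param elev_amplitude total relief in meters (default 6, gentle floodplain
#'   terrain)
#' @param n_bumps number of Gaussian hills/hollows in the elevation field
#' @param twi_center,twi_sd location and spread of the wetness surface in TWI
#'   units (defaults 3.3 and 3, matching a low-relief wetland mosaic)
#' @param twi_range clip range for TWI values (default `c(-0.66, 21.77)`)
#' @param twi_noise_sd node-level TWI noise (default 1.5), representing
#'   microtopographic wetness variation not captured by the smooth field
#' @param classes land-cover classes available to non-habitat nodes; must be
#'   names of [default_base_risk()]
#' @param diagonal include diagonal adjacencies (default TRUE), giving the
#'   denser planar neighbor structure of a vector-based landscape
#'   discretisation and a richer set of alternative routes
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1, grid_n = 3, n_wetlands = 2,
                         wetland_size = 2, spacing = 50,
                         elev_amplitude = 6, n_bumps = 6,
                         twi_center = 3.3, twi_sd = 3,
                         twi_range = c(-0.66, 21.77), twi_noise_sd = 1.5,
                         classes = c("deciduous_forest", "grassland",
                                     "cropland", "impervious"),
                         diagonal = TRUE) {
  if (n_wetlands < 2) stop_pp("need >= 2 wetlands", "paretopaths_config")
  if (grid_n < 2) stop_pp("grid_n must be >= 2", "paretopaths_config")
  bad <- setdiff(classes, names(default_base_risk()))
  if (length(bad))
    stop_pp(paste0("unknown land-cover class(es): ", paste(bad, collapse = ", ")),
            "paretopaths_config")
  structure(list(seed = seed, grid_n = grid_n, n_wetlands = n_wetlands,
                 wetland_size = wetland_size, spacing = spacing,
                 elev_amplitude = elev_amplitude, n_bumps = n_bumps,
                 twi_center = twi_center, twi_sd = twi_sd,
                 twi_range = twi_range, twi_noise_sd = twi_noise_sd,
                 classes = classes, diagonal = diagonal),
            class = "fixture_spec")
}

#' Generate a synthetic landscape network
#'
#' Deterministic per spec (the generator runs on an isolated RNG stream).
#' Nodes are a `grid_n x grid_n` planar grid with king-move adjacency by
#' default (rook-only with `diagonal = FALSE`), each undirected adjacency
#' materialised as two directed arcs. Elevation is a sum
#' of random Gaussian bumps rescaled to the spec's relief; land cover is a
#' second smooth field binned into the spec's classes; wetlands are placed
#' greedily at the lowest well-separated nodes (with one orthogonal neighbor
#' annexed per extra patch node) and take the wooded-wetland cover class;
#' TWI decreases with elevation plus noise, clipped to the spec's range.
#'
#' @param spec a [fixture_spec()]
#' @param derive also run [derive_costs()] with the given config
#' @param config [cost_config()] used when `derive = TRUE`
#' @param max_retries regenerate (with a shifted stream) if the network is
#'   not strongly connected; the grid construction always is, so this guard
#'   never triggers in practice
#' @return a [landscape_network()]
#' @export
make_landscape <- function(spec = fixture_spec(), derive = FALSE,
                           config = cost_config(), max_retries = 10) {
  for (try in 0:max_retries) {
    net <- with_seed(spec$seed + 100003L * try, build_landscape(spec))
    if (strongly_connected(net)) {
      if (derive) net <- derive_costs(net, config)
      return(net)
    }
  }
  stop_pp("failed to generate a connected landscape", "paretopaths_generation")
}

build_landscape <- function(spec) {
  g <- spec$grid_n
  n <- g * g
  row <- rep(seq_len(g), each = g)
  col <- rep(seq_len(g), times = g)
  x <- (col - 1) * spec$spacing
  y <- (row - 1) * spec$spacing
  extent <- max(1, (g - 1) * spec$spacing)

  bump_field <- function() {
    cx <- stats::runif(spec$n_bumps, 0, extent)
    cy <- stats::runif(spec$n_bumps, 0, extent)
    amp <- stats::runif(spec$n_bumps, -1, 1)
    sig <- stats::runif(spec$n_bumps, extent / 4, extent / 2)
    f <- numeric(n)
    for (k in seq_len(spec$n_bumps))
      f <- f + amp[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * sig[k]^2))
    f
  }
  rescale01 <- function(f) {
    r <- max(f) - min(f)
    if (r < 1e-12) return(rep(0.5, length(f)))
    (f - min(f)) / r
  }

  elev <- rescale01(bump_field() + 0.15 * stats::rnorm(n)) * spec$elev_amplitude
  cover_f <- rescale01(bump_field() + 0.15 * stats::rnorm(n))
  nb <- length(spec$classes)
  cover <- spec$classes[pmin(nb, 1L + floor(cover_f * nb))]

  # wetlands at the lowest well-separated nodes
  wid <- rep(NA_character_, n)
  ord <- order(elev)
  seeds <- integer(0)
  for (i in ord) {
    if (length(seeds) >= spec$n_wetlands) break
    if (all(abs(row[i] - row[seeds]) + abs(col[i] - col[seeds]) >= 2) ||
        !length(seeds))
      seeds <- c(seeds, i)
  }
  if (length(seeds) < spec$n_wetlands)
    seeds <- ord[seq_len(spec$n_wetlands)]
  for (k in seq_along(seeds)) {
    members <- seeds[k]
    if (spec$wetland_size >= 2) {
      nbrs <- which((abs(row - row[seeds[k]]) + abs(col - col[seeds[k]])) == 1 &
                      is.na(wid))
      nbrs <- setdiff(nbrs, seeds)
      if (length(nbrs)) {
        extra <- nbrs[order(elev[nbrs])][seq_len(min(length(nbrs),
                                                     spec$wetland_size - 1))]
        members <- c(members, extra)
      }
    }
    wid[members] <- paste0("W", k)
    cover[members] <- "woody_wetland"
  }

  tw <- spec$twi_center +
    spec$twi_sd * as.numeric(scale(-elev)) +
    stats::rnorm(n, 0, spec$twi_noise_sd)
  tw <- pmin(pmax(tw, spec$twi_range[1]), spec$twi_range[2])

  nodes <- data.frame(id = sprintf("n%03d", seq_len(n)),
                      x = x, y = y, elevation = elev,
                      land_cover = cover, twi = tw,
                      wetland_id = wid, stringsAsFactors = FALSE)

  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    if (col[i] < g) { j <- i + 1L; from <- c(from, i, j); to <- c(to, j, i) }
    if (row[i] < g) { j <- i + g; from <- c(from, i, j); to <- c(to, j, i) }
    if (isTRUE(spec$diagonal)) {
      if (col[i] < g && row[i] < g) {
        j <- i + g + 1L; from <- c(from, i, j); to <- c(to, j, i)
      }
      if (col[i] > 1 && row[i] < g) {
        j <- i + g - 1L; from <- c(from, i, j); to <- c(to, j, i)
      }
    }
  }
  lc_arc <- cover[pmin(from, to)]
  arcs <- data.frame(from = nodes$id[from], to = nodes$id[to],
                     length = sqrt((x[from] - x[to])^2 + (y[from] - y[to])^2),
                     land_cover = lc_arc, stringsAsFactors = FALSE)

  landscape_network(nodes, arcs)
}

strongly_connected <- function(net) {
  n <- nrow(net$nodes)
  reach <- function() {
    seen <- logical(n)
    stack <- 1L
    seen[1L] <- TRUE
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      js <- net$arcs$.to_idx[net$.adj[[i]]]
      new <- js[!seen[js]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    all(seen)
  }
  reach()
}

# ---------------------------------------------------------------------------
# hand-built fixtures

#' Hand-built arithmetic fixture (four nodes in a line)
#'
#' Raw attributes chosen so that every derived quantity is reproducible by
#' hand arithmetic: elevations 100/102/100/101 m, lengths 10/20/30 m, node
#' TWI 2/4/6/8, covers grassland / cropland / deciduous forest. No habitat
#' patches; used to validate the cost derivation.
#'
#' @return a raw [landscape_network()]
#' @export
fixture_arithmetic <- function() {
  nodes <- data.frame(id = c("A", "B", "C", "D"),
                      x = c(0, 10, 30, 60), y = 0,
                      elevation = c(100, 102, 100, 101),
                      land_cover = c("grassland", "cropland",
                                     "deciduous_forest", "deciduous_forest"),
                      twi = c(2, 4, 6, 8), stringsAsFactors = FALSE)
  arcs <- data.frame(from = c("A", "B", "B", "C", "C", "D"),
                     to = c("B", "A", "C", "B", "D", "C"),
                     length = c(10, 10, 20, 20, 30, 30),
                     land_cover = c("grassland", "grassland", "cropland",
                                    "cropland", "deciduous_forest",
                                    "deciduous_forest"),
                     stringsAsFactors = FALSE)
  landscape_network(nodes, arcs)
}

# helper: arcs table with directly supplied objective triples (both
# directions share the symmetric attributes)
costed_arcs <- function(from, to, log_risk, mwd, elev, length = 10) {
  data.frame(from = c(from, to), to = c(to, from),
             length = length,
             risk = -expm1(-c(log_risk, log_risk)),
             log_risk = c(log_risk, log_risk),
             mwd = c(mwd, mwd), elev_cost = c(elev, elev),
             moisture = 1, land_cover = "grassland",
             stringsAsFactors = FALSE)
}

#' Hand-built fixture with supported and unsupported solutions
#'
#' Eight nodes: habitat W1 = \{w1a, w1b\} joined by zero-cost internal arcs
#' (a zero-cost cycle), habitat W2 = \{w2a\}, and five parallel two-arc
#' routes from the W1 entrance to W2 with path totals
#' (2,10,4), (10,2,4), (6.5,6.5,4), (5,5,9) and (12,12,12).
#' The first four are the Pareto frontier; (6.5,6.5,4) is unsupported (the
#' midpoint of the first two lies componentwise below it) and (12,12,12) is
#' dominated. All arcs exist in both directions.
#'
#' @return a costed [landscape_network()]
#' @export
fixture_multimodal <- function() {
  nodes <- data.frame(id = c("w1a", "w1b", "m1", "m2", "m3", "m4", "m5", "w2a"),
                      x = c(0, 10, 30, 30, 30, 30, 30, 50),
                      y = c(0, 0, 20, 10, 0, -10, -20, 0),
                      elevation = 0,
                      wetland_id = c("W1", "W1", NA, NA, NA, NA, NA, "W2"),
                      stringsAsFactors = FALSE)
  arcs <- rbind(
    costed_arcs("w1a", "w1b", 0, 0, 0, length = 5),
    costed_arcs("w1b", "m1", 1, 5, 2),    costed_arcs("m1", "w2a", 1, 5, 2),
    costed_arcs("w1b", "m2", 5, 1, 2),    costed_arcs("m2", "w2a", 5, 1, 2),
    costed_arcs("w1b", "m3", 3.25, 3.25, 2), costed_arcs("m3", "w2a", 3.25, 3.25, 2),
    costed_arcs("w1b", "m4", 2.5, 2.5, 4.5), costed_arcs("m4", "w2a", 2.5, 2.5, 4.5),
    costed_arcs("w1b", "m5", 6, 6, 6),    costed_arcs("m5", "w2a", 6, 6, 6))
  landscape_network(nodes, arcs)
}

#' Hand-built biobjective classification fixture
#'
#' Three parallel routes whose (risk, moisture-weighted distance) totals are
#' (1,3), (3,1) and (2.5,2.5), all with the same elevation total: the
#' archetypal frontier on which (2.5,2.5) is efficient but unsupported
#' (above the segment joining the extremes).
#'
#' @return a costed [landscape_network()]
#' @export
fixture_biobjective <- function() {
  nodes <- data.frame(id = c("o", "a", "b", "c", "d"),
                      x = c(0, 20, 20, 20, 40), y = c(0, 10, 0, -10, 0),
                      elevation = 0,
                      wetland_id = c("W1", NA, NA, NA, "W2"),
                      stringsAsFactors = FALSE)
  arcs <- rbind(
    costed_arcs("o", "a", 0.5, 1.5, 0.5),  costed_arcs("a", "d", 0.5, 1.5, 0.5),
    costed_arcs("o", "b", 1.5, 0.5, 0.5),  costed_arcs("b", "d", 1.5, 0.5, 0.5),
    costed_arcs("o", "c", 1.25, 1.25, 0.5), costed_arcs("c", "d", 1.25, 1.25, 0.5))
  landscape_network(nodes, arcs)
}
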