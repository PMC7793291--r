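#' Cost-derivation configuration
#'
#' Parameters turning raw landscape attributes (endpoint elevations, arc
#' length, land cover, topographic wetness) into the three per-arc objective
#' attributes.
#'
#' @param w_p uphill weight in the elevation cost (default 2): uphill
#'   movement is costed twice as high as downhill, reflecting its greater
#'   energetic burden for small terrestrial animals. Only the ratio `w_p/w_n`
#'   matters for the Pareto set.
#' @param w_n downhill weight (default 1). Requires `w_p >= w_n > 0`.
#' @param M ideal surface moisture level in TWI units; deviations below `M`
#'   are penalised. `NULL` (default) uses the maximum observed arc moisture,
#'   which keeps every deviation nonnegative.
#' @param moisture_offset the constant added to the moisture deviation so a
#'   nonzero-length arc at ideal moisture still carries positive distance
#'   cost (default 1).
#' @param base_risk_table named numeric vector mapping land-cover class to
#'   base traversal-failure risk `pi_b` in (0, 1). Default:
#'   [default_base_risk()].
#' @param risk_length_factor coefficient of the length adjustment: an arc as
#'   long as the network's longest gains `risk_length_factor * 100` percent
#'   extra risk (default 0.5, i.e. up to +50%).
#' @param twi_max,twi_min substitution values for degenerate terrain cells:
#'   zero slope with positive drainage gets `twi_max`, zero slope with zero
#'   drainage gets `twi_min`. `NULL` (default) means "use the observed
#'   max/min meaningful TWI of the data at hand".
#' @return object of class `cost_config`
#' @export
cost_config <- function(w_p = 2, w_n = 1, M = NULL, moisture_offset = 1,
                        base_risk_table = default_base_risk(),
                        risk_length_factor = 0.5,
                        twi_max = NULL, twi_min = NULL) {
  if (!(w_p >= w_n && w_n > 0))
    stop_pp("requires w_p >= w_n > 0", "paretopaths_config")
  if (any(base_risk_table <= 0 | base_risk_table >= 1))
    stop_pp("base risks must lie strictly in (0, 1)", "paretopaths_config")
  structure(list(w_p = w_p, w_n = w_n, M = M,
                 moisture_offset = moisture_offset,
                 base_risk_table = base_risk_table,
                 risk_length_factor = risk_length_factor,
                 twi_max = twi_max, twi_min = twi_min),
            class = "cost_config")
}

#' Default land-cover base risks
#'
#' Relative traversal-failure risk per land-cover class for a wetland
#' amphibian system: wooded wetland is safest, impervious surface riskiest.
#'
#' @return named numeric vector of base risks
#' @export
default_base_risk <- function() {
  c(woody_wetland = 0.060,
    deciduous_forest = 0.065,
    deciduous_woody = 0.070,
    grassland = 0.075,
    open_water = 0.085,
    cropland = 0.090,
    impervious = 0.095)
}

#' Direction-dependent elevation cost of an arc
#'
#' `z = w_p * (e_j - e_i)` when moving uphill or flat (`e_j >= e_i`), and
#' `z = w_n * (e_i - e_j)` downhill; always nonnegative. Because the cost is
#' asymmetric, each undirected adjacency must be stored as two directed arcs.
#'
#' @param e_i,e_j elevations (m) of the start and end node (vectorised)
#' @param config a [cost_config()]
#' @return elevation cost in meters
#' @export
elevation_cost <- function(e_i, e_j, config = cost_config()) {
  ifelse(e_j >= e_i, config$w_p * (e_j - e_i), config$w_n * (e_i - e_j))
}

#' Topographic wetness index
#'
#' `TWI = ln(alpha / tan(beta))` for drainage area `alpha` and local slope
#' tangent `tan(beta)`. Flat cells are substituted: zero slope with positive
#' drainage receives `twi_max` (ponding), zero slope with zero drainage
#' receives `twi_min`.
#'
#' @param alpha drainage area, square meters (vectorised)
#' @param tan_beta slope tangent, dimensionless, `>= 0`
#' @param config a [cost_config()]; its `twi_max`/`twi_min` must be set for
#'   degenerate cells to be substitutable
#' @return TWI value
#' @export
twi <- function(alpha, tan_beta, config = cost_config()) {
  if (any(tan_beta < 0))
    stop_pp("negative slope tangent", "paretopaths_domain")
  if (any(alpha < 0))
    stop_pp("negative drainage area", "paretopaths_domain")
  out <- numeric(length(alpha))
  flat <- tan_beta == 0
  if (any(flat & alpha > 0)) {
    if (is.null(config$twi_max))
      stop_pp("zero-slope cell with drainage needs config$twi_max",
              "paretopaths_config")
    out[flat & alpha > 0] <- config$twi_max
  }
  if (any(flat & alpha == 0)) {
    if (is.null(config$twi_min))
      stop_pp("zero-slope zero-drainage cell needs config$twi_min",
              "paretopaths_config")
    out[flat & alpha == 0] <- config$twi_min
  }
  ok <- !flat
  out[ok] <- log(alpha[ok] / tan_beta[ok])
  out
}

#' Moisture-weighted distance of an arc
#'
#' `(M - m_ij + offset) * c_ij`: arc length scaled up by how far the arc's
#' moisture `m_ij` falls below the ideal level `M`. Dry arcs are costlier to
#' traverse, so distance and desiccation exposure are minimised jointly.
#'
#' @param m_ij arc moisture in TWI units (vectorised)
#' @param c_ij arc length in meters
#' @param config a [cost_config()] whose `M` is set (numeric)
#' @return moisture-weighted distance, nonnegative whenever `m_ij <= M + offset`
#' @export
moisture_weighted_distance <- function(m_ij, c_ij, config = cost_config()) {
  if (is.null(config$M))
    stop_pp("config$M (ideal moisture) is unset", "paretopaths_config")
  out <- (config$M - m_ij + config$moisture_offset) * c_ij
  if (any(out < 0))
    stop_pp(paste0("negative moisture-weighted distance (arc moisture exceeds ",
                   "M + offset); raise config$M"), "paretopaths_config")
  out
}

#' Length-adjusted traversal risk
#'
#' Longer arcs expose the mover to their land cover for longer, so the base
#' risk is inflated linearly with relative arc length:
#' `pi_ij = pi_b + c_ij * pi_b / (2 * c_max)`, reaching `1.5 * pi_b` for the
#' longest arc in the network.
#'
#' @param pi_b base risk of the arc's land-cover class (vectorised)
#' @param c_ij arc length, `0 <= c_ij <= c_max`
#' @param c_max longest arc length in the network, `> 0`
#' @param risk_length_factor maximum relative uplift (default 0.5)
#' @return adjusted risk `pi_ij < 1`
#' @export
adjusted_risk <- function(pi_b, c_ij, c_max, risk_length_factor = 0.5) {
  if (any(c_max <= 0)) stop_pp("c_max must be positive", "paretopaths_domain")
  if (any(c_ij > c_max))
    stop_pp("arc length exceeds c_max", "paretopaths_domain")
  if (any(c_ij < 0)) stop_pp("negative arc length", "paretopaths_domain")
  pi_b * (1 + risk_length_factor * c_ij / c_max)
}

#' Derive all per-arc objective attributes
#'
#' Populates `elev_cost`, `mwd`, `risk` and `log_risk` for every arc of a raw
#' network: elevation cost from endpoint elevations ([elevation_cost()]),
#' moisture-weighted distance from arc moisture and length
#' ([moisture_weighted_distance()]), and traversal risk from the land-cover
#' base risk inflated by relative arc length ([adjusted_risk()]), stored
#' additively as `log_risk = ln(1/(1 - pi_ij))`. Arcs internal to a wetland
#' are hard-set to zero on all three objectives (habitat interiors are
#' treated as homogeneous, cost-free terrain). `c_max` is the maximum length
#' over external arcs of nonzero length. Arc moisture, when absent, is taken
#' as the mean of the endpoint nodes' TWI values.
#'
#' @param net a [landscape_network()] carrying raw attributes
#' @param config a [cost_config()]
#' @return the network with derived costs; the resolved configuration (with
#'   defaulted `M`) is attached as attribute `"config"`
#' @export
derive_costs <- function(net, config = cost_config()) {
  stopifnot(inherits(net, "landscape_network"))
  arcs <- net$arcs
  ext <- !arcs$wetland_internal

  if (anyNA(arcs$moisture)) {
    if (is.null(net$nodes$twi) || anyNA(net$nodes$twi))
      stop_pp("arcs lack moisture and nodes lack a complete twi column",
              "paretopaths_validation")
    m_nodes <- net$nodes$twi
    arcs$moisture <- (m_nodes[arcs$.from_idx] + m_nodes[arcs$.to_idx]) / 2
  }

  if (anyNA(arcs$land_cover[ext]))
    stop_pp("external arcs lack a land_cover class", "paretopaths_validation")
  pib <- config$base_risk_table[as.character(arcs$land_cover)]
  unknown <- ext & is.na(pib)
  if (any(unknown))
    stop_pp(paste0("unknown land-cover class(es): ",
                   paste(unique(arcs$land_cover[unknown]), collapse = ", ")),
            "paretopaths_lookup")

  lens <- arcs$length[ext & arcs$length > 0]
  if (!length(lens))
    stop_pp("no external arc with positive length; c_max undefined",
            "paretopaths_validation")
  c_max <- max(lens)

  if (is.null(config$M)) config$M <- max(arcs$moisture[ext])

  # wetland-internal arcs carry zero on all three objectives by construction;
  # they are excluded from the derivation entirely
  e <- net$nodes$elevation
  arcs$elev_cost <- arcs$mwd <- arcs$risk <- numeric(nrow(arcs))
  arcs$base_risk <- numeric(nrow(arcs))
  arcs$elev_cost[ext] <- elevation_cost(e[arcs$.from_idx[ext]],
                                        e[arcs$.to_idx[ext]], config)
  arcs$mwd[ext] <- moisture_weighted_distance(arcs$moisture[ext],
                                              arcs$length[ext], config)
  arcs$base_risk[ext] <- unname(pib[ext])
  arcs$risk[ext] <- adjusted_risk(unname(pib[ext]), arcs$length[ext], c_max,
                                  config$risk_length_factor)
  arcs$log_risk <- -log1p(-arcs$risk)

  if (any(arcs$risk >= 1))
    stop_pp("derived risk >= 1; check base_risk_table", "paretopaths_validation")

  net$arcs <- arcs
  attr(net, "config") <- config
  attr(net, "c_max") <- c_max
  net
}
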