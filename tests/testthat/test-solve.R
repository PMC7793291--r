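test_that("weighted solver picks the cheaper of parallel routes", {
  nodes <- data.frame(id = c("o", "m", "n", "d"), x = c(0, 1, 1, 2),
                      y = c(0, 1, -1, 0), elevation = 0)
  mk <- function(from, to, lr, mwd, z)
    data.frame(from = from, to = to, length = 1, risk = -expm1(-lr),
               log_risk = lr, mwd = mwd, elev_cost = z)
  arcs <- rbind(mk("o", "m", 1, 1, 1), mk("m", "d", 1, 1, 0),
                mk("o", "n", 2, 2, 0.5), mk("n", "d", 3, 2, 0.5))
  net <- landscape_network(nodes, arcs)
  # equal weights: route via m costs (2+2+1)/3 < (5+4+1)/3
  p <- solve_weighted(net, "o", "d", rep(1, 3) / 3)
  expect_identical(p$nodes, c("o", "m", "d"))
  expect_equal(unname(p$objectives), c(2, 2, 1))
  # weight on elevation only: route via n wins (1 vs 1? no: 1 vs 1) ->
  # z totals are 1 (via m) vs 1 (via n); tie broken by lexicographic f1
  p3 <- solve_weighted(net, "o", "d", c(0, 0, 1))
  expect_identical(p3$nodes, c("o", "m", "d"))
})

test_that("pure risk weight finds a zero-risk path when one exists", {
  nodes <- data.frame(id = c("o", "a", "b", "d"), x = 0:3, y = 0, elevation = 0)
  mk <- function(from, to, lr, mwd, z)
    data.frame(from = from, to = to, length = 1, risk = -expm1(-lr),
               log_risk = lr, mwd = mwd, elev_cost = z)
  arcs <- rbind(mk("o", "a", 0, 50, 9), mk("a", "d", 0, 50, 9),
                mk("o", "b", 0.01, 1, 1), mk("b", "d", 0.01, 1, 1))
  net <- landscape_network(nodes, arcs)
  p <- solve_weighted(net, "o", "d", c(1, 0, 0))
  expect_equal(p$objectives[["log_risk"]], 0)
  expect_identical(p$nodes, c("o", "a", "d"))
})

test_that("solver errors are informative", {
  net <- fixture_multimodal()
  expect_error(solve_weighted(net, "w1a", "w1a", c(1, 0, 0)),
               class = "paretopaths_domain")
  expect_error(solve_weighted(net, "w1a", "w2a", c(0.5, 0.6, -0.1)),
               class = "paretopaths_domain")
  # unreachable destination
  nodes <- data.frame(id = c("o", "d"), x = 0:1, y = 0, elevation = 0)
  arcs <- data.frame(from = "d", to = "o", length = 1, risk = 0.1,
                     log_risk = -log(0.9), mwd = 1, elev_cost = 0)
  iso <- landscape_network(nodes, arcs)
  expect_error(solve_weighted(iso, "o", "d", c(1, 0, 0)),
               "no path", class = "paretopaths_no_path")
})

test_that("weighted optimum matches exhaustive enumeration on toy fixtures", {
  for (s in c(1, 4, 12)) {
    net <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    reps <- wetland_representatives(net)
    o <- reps[[1]]; d <- reps[[2]]
    walks <- oracle_enumerate_paths(net, o, d)
    vals <- t(vapply(walks, function(w) oracle_eval(net, w), numeric(3)))
    for (w in list(rep(1, 3) / 3, c(0.7, 0.2, 0.1), c(0.05, 0.05, 0.9))) {
      p <- solve_weighted(net, o, d, w)
      expect_equal(sum(w * p$objectives), min(vals %*% w), tolerance = 1e-9)
    }
  }
})

test_that("scalarised optimal cost agrees with an igraph shortest path", {
  skip_if_not_installed("igraph")
  net <- make_landscape(fixture_spec(seed = 21, grid_n = 5, n_wetlands = 3),
                        derive = TRUE)
  reps <- wetland_representatives(net)
  w <- c(0.2, 0.5, 0.3)
  cost <- w[1] * net$arcs$log_risk + w[2] * net$arcs$mwd +
    w[3] * net$arcs$elev_cost
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$arcs$from, to = net$arcs$to, weight = cost),
    vertices = net$nodes$id)
  for (d in reps[-1]) {
    p <- solve_weighted(net, reps[[1]], d, w)
    ig <- igraph::distances(g, v = reps[[1]], to = d, mode = "out")[1, 1]
    expect_equal(sum(w * p$objectives), ig, tolerance = 1e-9)
  }
})

test_that("anchor solves minimise their own objective and are efficient", {
  expect_error(solve_anchor(fixture_multimodal(), "w1a", "w2a", 4),
               class = "paretopaths_domain")
  for (s in c(5, 23)) {
    net <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    reps <- wetland_representatives(net)
    fr <- oracle_frontier(net, reps[[1]], reps[[2]])
    for (l in 1:3) {
      anc <- solve_anchor(net, reps[[1]], reps[[2]], l)
      expect_equal(anc$objectives[[l]], min(fr[, l]), tolerance = 1e-9)
      # anchored solution is non-dominated against the oracle frontier
      dominated <- any(apply(fr, 1, function(v)
        all(v <= anc$objectives) && any(v < anc$objectives)))
      expect_false(dominated)
    }
  }
})

test_that("strictly positive weights always return non-dominated paths", {
  set.seed(99)
  for (s in 31:35) {
    net <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    reps <- wetland_representatives(net)
    fr <- oracle_frontier(net, reps[[1]], reps[[2]])
    for (k in 1:5) {
      w <- stats::runif(3, 0.05, 1)
      w <- w / sum(w)
      p <- solve_weighted(net, reps[[1]], reps[[2]], w)
      dominated <- any(apply(fr, 1, function(v)
        all(v <= p$objectives) && any(v < p$objectives)))
      expect_false(dominated)
    }
  }
})
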