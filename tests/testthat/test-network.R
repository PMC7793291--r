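test_that("path evaluation sums arc attributes and converts risk correctly", {
  net <- fixture_multimodal()

  # empty path: origin == destination, zero vector
  empty <- list(origin = "w1a", destination = "w1a", arcs = integer(0))
  expect_equal(unname(evaluate_path(empty, net)), c(0, 0, 0))

  # single arc with pi = 0.5 carries log-risk ln 2
  nodes <- data.frame(id = c("u", "v"), x = c(0, 1), y = 0, elevation = 0)
  arcs <- data.frame(from = "u", to = "v", length = 10, risk = 0.5,
                     log_risk = log(2), mwd = 10, elev_cost = 2)
  single <- landscape_network(nodes, arcs)
  p1 <- list(origin = "u", destination = "v", arcs = 1L)
  expect_equal(unname(evaluate_path(p1, single)), c(log(2), 10, 2))

  # multi-arc route matches an independent per-arc hand sum
  hop <- function(i, j) which(net$arcs$from == i & net$arcs$to == j)
  idx <- c(hop("w1a", "w1b"), hop("w1b", "m1"), hop("m1", "w2a"))
  route <- list(origin = "w1a", destination = "w2a", arcs = idx)
  hand <- c(sum(net$arcs$log_risk[idx]), sum(net$arcs$mwd[idx]),
            sum(net$arcs$elev_cost[idx]))
  expect_equal(unname(evaluate_path(route, net)), hand)
})

test_that("disconnected arc sequences are rejected naming the break", {
  net <- fixture_multimodal()
  a1 <- which(net$arcs$from == "w1a" & net$arcs$to == "w1b")
  a2 <- which(net$arcs$from == "m1" & net$arcs$to == "w2a")
  broken <- list(origin = "w1a", destination = "w2a", arcs = c(a1, a2))
  expect_error(evaluate_path(broken, net), "disconnected",
               class = "paretopaths_structure")
})

test_that("failure probability is the multiplicative complement of log-risk", {
  expect_identical(failure_probability(0), 0)
  expect_equal(failure_probability(log(2)), 0.5)
  # two arcs with class risks 0.06 and 0.09: 1 - 0.94 * 0.91
  f1 <- -log(1 - 0.06) - log(1 - 0.09)
  expect_equal(failure_probability(f1), 1 - 0.94 * 0.91, tolerance = 1e-12)
  expect_equal(failure_probability(f1), 0.1446, tolerance = 1e-12)
  expect_error(failure_probability(-0.1), class = "paretopaths_domain")
})

test_that("log-risk round trip and order preservation hold on random paths", {
  net <- make_landscape(fixture_spec(seed = 3), derive = TRUE)
  reps <- wetland_representatives(net)
  bf <- brute_force_pareto(net, reps[[1]], reps[[2]], max_paths = 5000,
                           classify = FALSE)
  for (p in bf$paths) {
    mult <- 1 - prod(1 - net$arcs$risk[p$arcs])
    expect_equal(failure_probability(p$objectives[["log_risk"]]), mult,
                 tolerance = 1e-12)
  }
  # ordering by additive f1 equals ordering by failure probability
  f1 <- bf$objectives[, "log_risk"]
  expect_identical(order(f1), order(failure_probability(f1)))
})

test_that("network validation catches structural defects", {
  nodes <- data.frame(id = c("a", "b"), x = 0, y = 0, elevation = 0)
  expect_error(landscape_network(nodes,
                                 data.frame(from = "a", to = "zz", length = 1)),
               "missing node", class = "paretopaths_validation")
  expect_error(landscape_network(nodes,
                                 data.frame(from = "a", to = "b", length = -1)),
               "negative", class = "paretopaths_validation")
  expect_error(landscape_network(nodes,
                                 data.frame(from = "a", to = "b", length = 1,
                                            risk = 1.0)),
               class = "paretopaths_validation")
  expect_error(landscape_network(rbind(nodes, nodes),
                                 data.frame(from = "a", to = "b", length = 1)),
               "duplicate", class = "paretopaths_validation")
})

test_that("wetland-internal arcs are identified from node membership", {
  net <- fixture_multimodal()
  internal <- net$arcs$wetland_internal
  expect_true(all(net$arcs$from[internal] %in% c("w1a", "w1b")))
  expect_true(all(net$arcs$log_risk[internal] == 0 &
                    net$arcs$mwd[internal] == 0 &
                    net$arcs$elev_cost[internal] == 0))
  expect_setequal(wetland_representatives(net), c("w1a", "w2a"))
})
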