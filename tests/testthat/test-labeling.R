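test_that("label merging filters dominated and duplicate triples", {
  r <- merge_labels(matrix(numeric(0), 0, 3), c(1, 1, 1))
  expect_true(r$changed)
  expect_equal(unname(r$labels), rbind(c(1, 1, 1)))

  r <- merge_labels(rbind(c(1, 1, 1)), c(2, 2, 2))
  expect_false(r$changed)
  expect_equal(nrow(r$labels), 1)

  # equal triples are dropped by default but kept in enumeration mode
  r <- merge_labels(rbind(c(1, 1, 1)), c(1, 1, 1))
  expect_false(r$changed)
  r <- merge_labels(rbind(c(1, 1, 1)), c(1, 1, 1), dedupe_equal = FALSE)
  expect_true(r$changed)

  # insertion removes everything the candidate dominates; survivors checked
  # against a pairwise dominance oracle
  existing <- rbind(c(2, 2, 2), c(1, 1, 5))
  r <- merge_labels(existing, c(1, 3, 1))
  pool <- rbind(existing, c(1, 3, 1))
  expect_same_frontier(r$labels, pool[oracle_pareto_mask(pool), , drop = FALSE])
})

test_that("labeling a single-arc network yields that arc's triple", {
  net <- landscape_network(
    data.frame(id = c("u", "v"), x = 0:1, y = 0, elevation = 0,
               wetland_id = c("W1", "W2")),
    data.frame(from = "u", to = "v", length = 1, risk = 0.2,
               log_risk = -log(0.8), mwd = 7, elev_cost = 1))
  res <- label_all(net, "u")
  expect_named(res, "v")
  expect_equal(unname(res$v$objectives[1, ]), c(-log(0.8), 7, 1))
  expect_identical(res$v$paths[[1]]$nodes, c("u", "v"))
})

test_that("labeling equals exhaustive enumeration on the handmade fixture", {
  net <- fixture_multimodal()
  res <- label_all(net, "w1a", classify = TRUE)[["w2a"]]
  bf <- brute_force_pareto(net, "w1a", "w2a")
  expect_equal(res$objectives, bf$objectives, tolerance = 1e-12)
  expect_identical(path_signatures(res), path_signatures(bf))
  expect_identical(res$supported, bf$supported)
})

test_that("labeling equals the oracle as vectors and arc sequences on random fixtures", {
  for (s in c(2, 8, 19, 27, 33)) {
    net <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    reps <- wetland_representatives(net)
    for (o in names(reps)) {
      res <- label_all(net, reps[[o]],
                       destinations = reps[setdiff(names(reps), o)])
      for (d in names(res)) {
        bf <- brute_force_pareto(net, reps[[o]], d, max_paths = 5000,
                                 classify = FALSE)
        expect_equal(res[[d]]$objectives, bf$objectives, tolerance = 1e-12,
                     info = paste("seed", s, o, "->", d))
        expect_identical(path_signatures(res[[d]]), path_signatures(bf))
      }
    }
  }
})

test_that("equal-vector mode retains alternative routes per vector", {
  # two disjoint routes with identical triples
  nodes <- data.frame(id = c("o", "a", "b", "d"), x = c(0, 1, 1, 2),
                      y = c(0, 1, -1, 0), elevation = 0,
                      wetland_id = c("W1", NA, NA, "W2"))
  mk <- function(from, to)
    data.frame(from = from, to = to, length = 1, risk = 0.1,
               log_risk = -log(0.9), mwd = 2, elev_cost = 1)
  net <- landscape_network(nodes, rbind(mk("o", "a"), mk("a", "d"),
                                        mk("o", "b"), mk("b", "d")))
  dedup <- label_all(net, "o")[["d"]]
  keep <- label_all(net, "o", keep_equal_vectors = TRUE)[["d"]]
  expect_equal(length(dedup$paths), 1L)
  expect_equal(length(keep$paths), 2L)
  # canonical representative: lexicographically smallest node sequence
  expect_identical(dedup$paths[[1]]$nodes, c("o", "a", "d"))
  expect_setequal(path_signatures(keep), c("o>a>d", "o>b>d"))
})

test_that("labeling terminates and stays finite across zero-cost cycles", {
  # the handmade fixture has a zero-cost habitat cycle w1a <-> w1b
  net <- fixture_multimodal()
  res <- label_all(net, "w1a")
  expect_true(all(vapply(res, function(p) length(p$paths), integer(1)) < 50))
  # generated fixtures with two-node wetlands carry zero-cost cycles too
  for (s in c(3, 14)) {
    gnet <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    expect_true(any(gnet$arcs$wetland_internal))
    zero <- gnet$arcs$wetland_internal
    expect_true(all(gnet$arcs$log_risk[zero] == 0))
    res <- label_all(gnet, wetland_representatives(gnet)[[1]])
    expect_true(all(vapply(res, function(p) length(p$paths), integer(1)) >= 1))
  }
})

test_that("every prefix of a reported path is itself non-dominated", {
  net <- make_landscape(fixture_spec(seed = 6), derive = TRUE)
  reps <- wetland_representatives(net)
  res <- label_all(net, reps[[1]], destinations = reps[[2]])[[1]]
  obj <- cbind(net$arcs$log_risk, net$arcs$mwd, net$arcs$elev_cost)
  for (p in res$paths) {
    for (k in seq_along(p$arcs)[-length(p$arcs)]) {
      pre <- p$arcs[seq_len(k)]
      mid <- net$arcs$to[pre[k]]
      v <- colSums(obj[pre, , drop = FALSE])
      fr <- oracle_frontier(net, reps[[1]], mid)
      dominated <- any(apply(fr, 1, function(u) all(u <= v) && any(u < v)))
      expect_false(dominated, info = paste("prefix to", mid))
    }
  }
})

test_that("unreachable destinations give empty sets, not errors", {
  nodes <- data.frame(id = c("o", "d"), x = 0:1, y = 0, elevation = 0,
                      wetland_id = c("W1", "W2"))
  arcs <- data.frame(from = "d", to = "o", length = 1, risk = 0.1,
                     log_risk = -log(0.9), mwd = 1, elev_cost = 0)
  net <- landscape_network(nodes, arcs)
  res <- label_all(net, "o")
  expect_equal(length(res$d$paths), 0L)
})
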