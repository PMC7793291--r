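test_that("elevation cost weights uphill twice as high as downhill", {
  cfg <- cost_config()
  expect_identical(elevation_cost(100, 100, cfg), 0)
  expect_identical(elevation_cost(100, 102, cfg), 4)
  expect_identical(elevation_cost(102, 100, cfg), 2)
  # direction pair identity: z(i->j) + z(j->i) = (w_p + w_n) * |de|
  e <- runif(20, 90, 110)
  for (k in 1:19) {
    de <- abs(e[k + 1] - e[k])
    expect_equal(elevation_cost(e[k], e[k + 1], cfg) +
                   elevation_cost(e[k + 1], e[k], cfg),
                 (cfg$w_p + cfg$w_n) * de, tolerance = 1e-12)
  }
})

test_that("TWI follows ln(a/tan b) with substitution at degenerate cells", {
  cfg <- cost_config(twi_max = 21.77, twi_min = -0.66)
  expect_equal(twi(exp(1), 1, cfg), 1)
  expect_equal(twi(5, 0, cfg), 21.77)
  expect_equal(twi(0, 0, cfg), -0.66)
  expect_equal(twi(c(exp(2), 5, 0), c(1, 0, 0), cfg), c(2, 21.77, -0.66))
  expect_error(twi(1, -0.1, cfg), class = "paretopaths_domain")
  expect_error(twi(5, 0, cost_config()), class = "paretopaths_config")
})

test_that("moisture-weighted distance penalises dryness linearly", {
  cfg <- cost_config(M = 7)
  expect_equal(moisture_weighted_distance(7, 10, cfg), 10)
  expect_equal(moisture_weighted_distance(3, 10, cfg), 50)
  expect_equal(moisture_weighted_distance(2, 0, cfg), 0)
  expect_error(moisture_weighted_distance(9.5, 10, cfg),
               "raise config\\$M", class = "paretopaths_config")
})

test_that("risk adjustment inflates base risk by up to 50% with arc length", {
  # woody wetland class at the longest arc: exactly 1.5 * 0.060
  expect_equal(adjusted_risk(0.060, 100, 100), 0.090, tolerance = 1e-12)
  # impervious at zero length: no uplift
  expect_equal(adjusted_risk(0.095, 0, 100), 0.095)
  # cropland at half the maximum length
  expect_equal(adjusted_risk(0.090, 50, 100), 0.1125, tolerance = 1e-12)
  expect_error(adjusted_risk(0.06, 101, 100), class = "paretopaths_domain")
  # monotone nondecreasing in length, bounded by 1.5 * base
  lens <- seq(0, 100, by = 5)
  r <- adjusted_risk(0.075, lens, 100)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 1.5 * 0.075 + 1e-15))
})

test_that("derive_costs reproduces a spreadsheet-style recomputation", {
  net <- derive_costs(fixture_arithmetic())
  a <- net$arcs
  # hand-derived: M = max arc moisture = 7, c_max = 30
  # arc moistures are endpoint TWI means: A-B 3, B-C 5, C-D 7
  expect_equal(attr(net, "config")$M, 7)
  expect_equal(attr(net, "c_max"), 30)
  ab <- which(a$from == "A" & a$to == "B")
  bc <- which(a$from == "B" & a$to == "C")
  cd <- which(a$from == "C" & a$to == "D")
  expect_equal(a$elev_cost[c(ab, bc, cd)], c(4, 2, 2))          # 2*2, 1*2, 2*1
  expect_equal(a$mwd[c(ab, bc, cd)], c(50, 60, 30))             # (M-m+1)*c
  expect_equal(a$risk[ab], 0.075 * (1 + 10 / 60), tolerance = 1e-12)
  expect_equal(a$risk[bc], 0.090 * (1 + 20 / 60), tolerance = 1e-12)
  expect_equal(a$risk[cd], 0.065 * (1 + 30 / 60), tolerance = 1e-12)
  expect_equal(a$log_risk, log(1 / (1 - a$risk)), tolerance = 1e-12)
  # reverse arcs carry symmetric risk/mwd but swapped elevation branches
  ba <- which(a$from == "B" & a$to == "A")
  expect_equal(a$risk[ba], a$risk[ab])
  expect_equal(a$mwd[ba], a$mwd[ab])
  expect_equal(a$elev_cost[ba], 2)                              # downhill 1*2
})

test_that("derive_costs zeroes wetland-internal arcs and flags unknown covers", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = 0,
                      elevation = c(5, 9), twi = c(1, 2),
                      wetland_id = "W1")
  arcs <- data.frame(from = c("a", "b"), to = c("b", "a"), length = 3,
                     land_cover = "woody_wetland")
  all_internal <- landscape_network(nodes, arcs)
  # a network made only of habitat interior has no external arc to scale by
  expect_error(derive_costs(all_internal), class = "paretopaths_validation")

  net <- fixture_arithmetic()
  net$arcs$land_cover[1] <- "lava_field"
  expect_error(derive_costs(net), "lava_field", class = "paretopaths_lookup")
})

test_that("derived networks have nonnegative costs and the pairwise z identity", {
  for (s in c(2, 9, 17)) {
    net <- make_landscape(fixture_spec(seed = s), derive = TRUE)
    a <- net$arcs
    expect_true(all(a$elev_cost >= 0 & a$mwd >= 0 &
                      a$log_risk >= 0 & a$risk >= 0 & a$risk < 1))
    expect_true(all(a$elev_cost[a$wetland_internal] == 0))
    cfg <- attr(net, "config")
    key <- paste(pmin(a$.from_idx, a$.to_idx), pmax(a$.from_idx, a$.to_idx))
    ext <- !a$wetland_internal
    for (k in unique(key[ext])) {
      pair <- which(key == k & ext)
      if (length(pair) == 2) {
        de <- abs(net$nodes$elevation[a$.from_idx[pair[1]]] -
                    net$nodes$elevation[a$.to_idx[pair[1]]])
        expect_equal(sum(a$elev_cost[pair]), (cfg$w_p + cfg$w_n) * de,
                     tolerance = 1e-9)
      }
    }
  }
})
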