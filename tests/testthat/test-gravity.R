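test_that("gravity intensity matches hand-derived fixtures", {
  # unit case: K = 1/2, masses 1, distance 1
  expect_equal(gravity_intensity(1, 1, 1, 1, 1, b = 2), 0.5)
  # K = 3/4, mass product 24, D^2 = 4 -> 0.75 * 24 / 4 = 4.5
  expect_equal(gravity_intensity(2, 3, 4, 1, 2, b = 2), 4.5)
  # swapped direction: K = 1/4 -> 1.5; ratio equals G_i / G_j = 3
  expect_equal(gravity_intensity(4, 1, 2, 3, 2, b = 2), 1.5)
  expect_error(gravity_intensity(-1, 1, 1, 1, 1), "positive")
  expect_error(gravity_intensity(1, 1, 1, 1, 0), "positive")
})

test_that("directional ratio identity and distance homogeneity hold", {
  set.seed(11)
  for (k in 1:50) {
    v <- runif(5, 0.1, 10)
    tij <- gravity_intensity(v[1], v[2], v[3], v[4], v[5])
    tji <- gravity_intensity(v[3], v[4], v[1], v[2], v[5])
    expect_equal(tij / tji, v[2] / v[4], tolerance = 1e-12)
    # doubling distance with b = 2 divides T by 4
    expect_equal(gravity_intensity(v[1], v[2], v[3], v[4], 2 * v[5]),
                 tij / 4, tolerance = 1e-12)
  }
})

test_that("intensity is monotone in each mass argument", {
  # brute-force partial differences over a grid
  grid <- seq(0.5, 3, by = 0.5)
  h <- 1e-3
  for (base in list(c(1, 1, 1, 1, 1), c(2, 0.5, 1.5, 3, 2))) {
    for (arg in 1:4) {
      for (g in grid) {
        v <- base; v[arg] <- g
        up <- v; up[arg] <- g + h
        t0 <- gravity_intensity(v[1], v[2], v[3], v[4], v[5])
        t1 <- gravity_intensity(up[1], up[2], up[3], up[4], up[5])
        expect_gt(t1, t0)
      }
    }
  }
})

test_that("network construction applies edge-threshold rules", {
  regions <- c("A", "B", "C")
  P <- c(A = 5, B = 5, C = 1)
  G <- c(A = 4, B = 4, C = 1)
  d <- matrix(1, 3, 3, dimnames = list(regions, regions))
  diag(d) <- 0
  net_all <- build_gravity_network(P, G, d, 2005, threshold_rule = "all")
  expect_equal(nrow(net_all$edges), 6)
  expect_true(all(net_all$edges$retained))

  # A<->B dominates; under row-mean only the dominant pair survives from A, B
  net <- build_gravity_network(P, G, d, 2005, threshold_rule = "row-mean")
  kept <- net$edges[net$edges$retained, ]
  expect_true(all(c("A", "B") %in% kept$src))
  expect_false(any(kept$src == "A" & kept$dst == "C"))
  # brute-force check of the rule on every row
  for (i in regions) {
    row_t <- net$intensity[i, setdiff(regions, i)]
    for (j in setdiff(regions, i)) {
      expect_identical(
        net$edges$retained[net$edges$src == i & net$edges$dst == j],
        unname(net$intensity[i, j] >= mean(row_t)))
    }
  }

  # identical equidistant regions: all intensities equal, density 1
  Pu <- c(A = 2, B = 2, C = 2); Gu <- c(A = 3, B = 3, C = 3)
  netu <- build_gravity_network(Pu, Gu, d, 2005, threshold_rule = "row-mean")
  expect_equal(network_metrics(netu)$density, 1)
})

test_that("network metrics report density and strongest pairs", {
  regions <- c("A", "B", "C")
  P <- c(A = 5, B = 4, C = 1); G <- c(A = 4, B = 5, C = 1)
  d <- matrix(1, 3, 3, dimnames = list(regions, regions)); diag(d) <- 0
  net <- build_gravity_network(P, G, d, 2005, threshold_rule = "all")
  m <- network_metrics(net, top_k = 1)
  expect_equal(m$density, 1)
  expect_setequal(unlist(m$top_pairs[1, c("a", "b")]), c("A", "B"))

  net1 <- build_gravity_network(P, G, d, 2005,
                                threshold_rule = max(net$intensity))
  expect_equal(network_metrics(net1)$density, 1 / 6)
})

test_that("coordination index lies in [0,1] and tracks dispersion", {
  regions <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(regions, regions)); diag(d) <- 0
  # one dominant pair: retained share ~ 1 -> index near 0
  P <- c(A = 50, B = 50, C = 0.1, D = 0.1)
  G <- c(A = 50, B = 50, C = 0.1, D = 0.1)
  net_conc <- build_gravity_network(P, G, d, 2005)
  # uniform linkage: every edge retained -> index exactly 0 (edge case)
  Pu <- c(A = 1, B = 1, C = 1, D = 1)
  net_unif <- build_gravity_network(Pu, Pu, d, 2006)
  idx <- coordination_index(list(net_conc, net_unif))
  expect_true(all(idx >= 0 & idx <= 1))
  expect_lt(idx[["2005"]], 0.01)
  expect_equal(idx[["2006"]], 0)
  expect_error(coordination_index(list()), "at least one")
})

test_that("sqrt-mass variant preserves the directional identity", {
  t1 <- gravity_intensity(2, 3, 4, 1, 2, sqrt_masses = TRUE)
  t2 <- gravity_intensity(4, 1, 2, 3, 2, sqrt_masses = TRUE)
  expect_equal(t1 / t2, 3, tolerance = 1e-12)
  expect_equal(t1, 0.75 * sqrt(6) * sqrt(4) / 4)
})
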