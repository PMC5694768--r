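test_that("hyperbolic distance handles degenerate and textbook cases", {
  expect_equal(hyperbolic_distance(1.3, 0.7, 1.3, 0.7), 0)
  expect_equal(hyperbolic_distance(2, 1, 0.5, 1), 1.5)          # collinear
  expect_equal(hyperbolic_distance(1, 0, 1, pi),
               acosh(cosh(1)^2 + sinh(1)^2), tolerance = 1e-12)
  # curvature rescaling
  expect_equal(hyperbolic_distance(2, 0.3, 5, 0.3, zeta = 3), 3)
  expect_error(hyperbolic_distance(1, 0, 1, 0, zeta = 0), "positive")
})

test_that("hyperbolic distance is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  for (k in 1:50) {
    r <- runif(3, 0, 6)
    th <- runif(3, 0, 2 * pi)
    d12 <- hyperbolic_distance(r[1], th[1], r[2], th[2])
    d21 <- hyperbolic_distance(r[2], th[2], r[1], th[1])
    d13 <- hyperbolic_distance(r[1], th[1], r[3], th[3])
    d23 <- hyperbolic_distance(r[2], th[2], r[3], th[3])
    expect_equal(d12, d21)
    expect_gte(d13 + d23 + 1e-9, d12)
  }
})

test_that("pairwise distances match the scalar formula and 3D great circles", {
  set.seed(4)
  co <- random_coords(10)
  H <- pairwise_hyperbolic_distances(co)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(H[i, j],
                   hyperbolic_distance(co$r[i], co$theta[i], co$r[j], co$theta[j]))
    }
  }
  expect_equal(diag(H), rep(0, 10))
  expect_equal(H, t(H))
  # all nodes at the origin collapse to a zero matrix
  zo <- tibble::tibble(node = 1:4, r = 0, theta = c(0, 1, 2, 3))
  expect_equal(pairwise_hyperbolic_distances(zo), matrix(0, 4, 4))
  # 3D: opposite poles at equal radius have central angle pi, so the
  # geodesic runs through the origin: h = 2r
  sph <- tibble::tibble(node = 1:2, r = 1, theta = c(0, 0), phi = c(0, pi))
  expect_equal(pairwise_hyperbolic_distances(sph)[1, 2],
               acosh(cosh(1)^2 + sinh(1)^2))
})

test_that("geometric weights decay with distance and fill shortest paths", {
  co <- tibble::tibble(node = 1:3, r = c(1, 0, 1), theta = c(0, 0, pi))
  # path 1-2-3: HD(1,2) = HD(2,3) = 1
  p3 <- toy_fixtures("path:3")
  W <- geometric_weights(p3, co, mode = "observed_only")
  expect_equal(W[1, 2], 0.5)
  expect_equal(W[2, 3], 0.5)
  expect_equal(W[1, 3], 0)                 # unobserved pair left unweighted
  expect_equal(diag(W), rep(1, 3))
  W2 <- geometric_weights(p3, co, mode = "observed_plus_hsp")
  expect_equal(W2[1, 3], 1 / (1 + 2))      # HSP = 1 + 1
  expect_true(all(W2 > 0 & W2 <= 1))
})

test_that("HSP uses the minimum-total-distance path over observed edges", {
  set.seed(21)
  for (k in 1:5) {
    edges <- random_connected_graph(7, 0.4)
    co <- random_coords(7)
    H <- pairwise_hyperbolic_distances(co)
    W <- geometric_weights(edges, co, mode = "observed_plus_hsp")
    adj <- lapply(1:7, function(v) {
      sort(c(edges$to[edges$from == v], edges$from[edges$to == v]))
    })
    for (i in 1:6) {
      for (j in (i + 1):7) {
        hsp <- 1 / W[i, j] - 1
        paths <- all_simple_paths_brute(adj, i, j)
        lens <- vapply(paths, function(p) {
          sum(H[cbind(p[-length(p)], p[-1])])
        }, numeric(1))
        expect_equal(hsp, min(lens), tolerance = 1e-10)
      }
    }
  }
})

test_that("hop-basis HSP sums distances along a minimum-hop path", {
  # square with one heavy diagonal route: hop basis may differ from
  # weighted basis only by taking fewer hops
  edges <- toy_fixtures("cycle:4")
  co <- tibble::tibble(node = 1:4, r = c(0, 3, 0.1, 3), theta = c(0, 1, 2, 3))
  Ww <- geometric_weights(edges, co, mode = "observed_plus_hsp",
                          hsp_basis = "weighted")
  Wh <- geometric_weights(edges, co, mode = "observed_plus_hsp",
                          hsp_basis = "hops")
  expect_true(all(1 / Wh - 1 >= 1 / Ww - 1 - 1e-12))  # weighted is minimal
})

test_that("geometric weights demand full coordinate coverage", {
  co <- random_coords(2)
  expect_error(geometric_weights(toy_fixtures("path:3"), co), "every node")
})
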