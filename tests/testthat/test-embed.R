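test_that("the pipeline returns one in-range coordinate per node, deterministically", {
  net <- generate_pso(80, m = 3, temp = 0.2, seed = 14)
  for (red in c("ISO", "ncISO", "LE", "MCE", "ncMCE")) {
    emb <- embed_network(net$edges, "RA1", red, "EA", gamma = 2.5)
    co <- tidy(emb)
    expect_equal(nrow(co), 80)
    expect_true(all(co$theta >= 0 & co$theta < 2 * pi), info = red)
    expect_true(all(co$r >= 0), info = red)
    again <- embed_network(net$edges, "RA1", red, "EA", gamma = 2.5)
    expect_identical(emb, again, info = red)
  }
})

test_that("radial coordinates follow the degree-ranked closed form", {
  st <- toy_fixtures("star:4")
  # hub rank 1, leaves ranks 2..5 by ascending id
  r <- radial_coordinates(st, gamma = 2, zeta = 1)   # beta = 1
  expect_equal(r, c(0, 2 * log(2:5)))
  r2 <- radial_coordinates(st, gamma = 3, zeta = 1)  # beta = 0.5
  expect_equal(r2[1], log(5))
  expect_equal(max(r2), 2 * log(5))                  # youngest rank collapses
  expect_error(radial_coordinates(st, gamma = 1), "exceed 1")
  expect_error(radial_coordinates(st, gamma = 2.5, zeta = -1), "positive")
})

test_that("fitted gamma is used when none is supplied", {
  net <- generate_pso(150, m = 3, temp = 0.2, seed = 3)
  emb <- embed_network(net$edges, "RA1", "ncMCE", "EA")
  d <- igraph::degree(
    igraph::graph_from_edgelist(as.matrix(net$edges), directed = FALSE))
  expect_equal(emb$config$gamma, fit_degree_exponent(d)$gamma)
})

test_that("user-supplied weights bypass pre-weighting", {
  net <- generate_pso(60, m = 2, temp = 0, seed = 5)
  w <- preweight_edges(net$edges, "RA1")
  direct <- embed_network(w, preweight = "NONE", reducer = "ncMCE",
                          adjust = "EA", gamma = 2.5)
  expect_equal(direct$config$preweight, "user")
  viarule <- embed_network(net$edges, "RA1", "ncMCE", "EA", gamma = 2.5)
  expect_equal(tidy(direct), tidy(viarule))
})

test_that("mirrored angular coordinates leave both accuracy metrics unchanged", {
  net <- generate_pso(70, m = 3, temp = 0.1, seed = 9)
  emb <- embed_network(net$edges, "RA1", "ncMCE", "EA", gamma = 2.5)
  co <- tidy(emb)
  mir <- co
  mir$theta <- (2 * pi - mir$theta) %% (2 * pi)
  expect_equal(hd_correlation(net$coords, mir),
               hd_correlation(net$coords, co), tolerance = 1e-10)
  expect_equal(c_score(net$coords$theta, mir$theta),
               c_score(net$coords$theta, co$theta))
})

test_that("pre-weighting boosts angular recovery over the unweighted variants", {
  hds <- vapply(1:10, function(s) {
    net <- generate_pso(100, m = 4, temp = 0, gamma = 2.5, seed = s)
    vapply(list(c("RA1", "LE"), c("NONE", "LE"),
                c("RA1", "ncMCE"), c("NONE", "ncMCE")), function(v) {
      emb <- embed_network(net$edges, v[1], v[2], "EA", gamma = 2.5)
      hd_correlation(net$coords, tidy(emb))
    }, numeric(1))
  }, numeric(4))
  means <- rowMeans(hds)
  expect_gt(means[1], means[2])   # RA1-LE-EA > LE-EA
  expect_gt(means[3], means[4])   # RA1-ncMCE-EA > ncMCE-EA
})

test_that("3D embeddings carry spherical angles and refuse EA", {
  net <- generate_pso(60, m = 3, temp = 0.1, seed = 21)
  for (red in c("ISO", "ncISO", "LE")) {
    emb <- embed_network(net$edges, "RA1", red, "CA", dims = 3, gamma = 2.5)
    co <- tidy(emb)
    expect_true(all(co$phi >= 0 & co$phi <= pi), info = red)
    expect_true(all(co$theta >= 0 & co$theta < 2 * pi), info = red)
  }
  expect_error(
    embed_network(net$edges, "RA1", "ISO", "EA", dims = 3, gamma = 2.5),
    "2D")
  expect_error(
    embed_network(net$edges, "RA1", "ncMCE", "CA", dims = 3, gamma = 2.5),
    "2D")
})

test_that("summary methods describe the configuration", {
  net <- generate_pso(40, m = 2, temp = 0, seed = 2)
  emb <- embed_network(net$edges, "RA1", "ncMCE", "EA", gamma = 2.5)
  gl <- glance(emb)
  expect_equal(gl$preweight, "RA1")
  expect_equal(gl$reducer, "ncMCE")
  expect_equal(gl$n, 40)
  expect_s3_class(autoplot(emb), "ggplot")
  expect_s3_class(autoplot(net), "ggplot")
})
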