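test_that("HD-correlation is 1 for exact and rigidly rotated coordinates", {
  set.seed(2)
  co <- random_coords(30)
  expect_equal(hd_correlation(co, co), 1)
  rot <- co
  rot$theta <- (rot$theta + 1.23) %% (2 * pi)
  expect_equal(hd_correlation(co, rot), 1, tolerance = 1e-10)
  mir <- co
  mir$theta <- (2 * pi - mir$theta) %% (2 * pi)
  expect_equal(hd_correlation(co, mir), 1, tolerance = 1e-10)
})

test_that("HD-correlation of independent random coordinates is near zero", {
  set.seed(31)
  vals <- vapply(1:5, function(k) {
    a <- random_coords(100)
    b <- random_coords(100)
    hd_correlation(a, b)
  }, numeric(1))
  expect_true(all(abs(vals) < 0.3))
})

test_that("HD-correlation rejects degenerate input", {
  same <- tibble::tibble(node = 1:4, r = 1, theta = 1)
  other <- random_coords(4)
  expect_error(hd_correlation(same, other), "zero variance")
  expect_error(hd_correlation(random_coords(2), random_coords(2)), "3 nodes")
})

test_that("C-score matches exhaustive pair counting", {
  th <- c(0.3, 1.1, 2.9, 4.0, 5.5)
  expect_equal(c_score(th, th), 1)
  expect_equal(c_score(th, (2 * pi - th) %% (2 * pi)), 1)   # mirror
  expect_equal(c_score(c(0, 1, 2, 4.5), c(0, 2, 1, 4.5)), 0.5)
  # independent enumeration oracle, both orientations
  oracle <- function(a, b) {
    n <- length(a)
    dir <- function(x, y) ((y - x) %% (2 * pi)) <= pi
    one <- function(bb) {
      s <- 0
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          s <- s + (dir(a[i], a[j]) == dir(bb[i], bb[j]))
        }
      }
      s / (n * (n - 1) / 2)
    }
    max(one(b), one((2 * pi - b) %% (2 * pi)))
  }
  set.seed(5)
  for (k in 1:10) {
    a <- runif(7, 0, 2 * pi)
    b <- runif(7, 0, 2 * pi)
    expect_equal(c_score(a, b), oracle(a, b))
  }
})

test_that("C-score is invariant under rotation of either angle set", {
  set.seed(6)
  a <- runif(20, 0, 2 * pi)
  b <- runif(20, 0, 2 * pi)
  base <- c_score(a, b)
  for (shift in c(0.5, 2, 5)) {
    expect_equal(c_score((a + shift) %% (2 * pi), b), base)
    expect_equal(c_score(a, (b + shift) %% (2 * pi)), base)
  }
  expect_error(c_score(1, 1), "length")
})

test_that("angle alignment recovers planted rotations and reflections", {
  set.seed(8)
  th <- sort(runif(40, 0, 2 * pi))
  al <- align_angles(th, th)
  expect_equal(attr(al, "rotation_deg"), 0)
  expect_false(attr(al, "reflected"))
  rot <- (th + pi / 2) %% (2 * pi)
  al2 <- align_angles(th, rot)
  expect_equal((attr(al2, "rotation_deg")) %% 360, 270)
  expect_gt(attr(al2, "correlation"), 0.99)
  # C-score is untouched by alignment
  b <- runif(40, 0, 2 * pi)
  expect_equal(c_score(th, as.numeric(align_angles(th, b))), c_score(th, b))
})

test_that("NMI matches the hand-evaluated contingency example", {
  # detected {1,1}/{2}{2} vs truth: table [[2,0],[1,1]] on 4 nodes
  detected <- c("a", "a", "b", "b")
  truth <- c("x", "x", "x", "y")
  I <- 0.5 * log(4 / 3) + 0.25 * log(2 / 3) + 0.25 * log(2)
  Ht <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(nmi(detected, truth, adjusted = "never"), I / sqrt(log(2) * Ht))
  expect_equal(nmi(detected, truth, adjusted = "never"), 0.345594, tolerance = 1e-5)
})

test_that("NMI is symmetric, label-invariant and bounded", {
  set.seed(12)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:4, 40, replace = TRUE)
  expect_equal(nmi(a, b, adjusted = "never"), nmi(b, a, adjusted = "never"))
  expect_equal(nmi(a, a, adjusted = "never"), 1)
  relab <- c(9, 7, 5)[a]
  expect_equal(nmi(relab, a, adjusted = "never"), 1)
  v <- nmi(a, b, adjusted = "never")
  expect_gte(v, 0)
  expect_lte(v, 1)
  expect_error(nmi(rep(1, 10), sample(1:2, 10, replace = TRUE),
                   adjusted = "never"), "zero entropy")
})

test_that("adjusted NMI corrects chance agreement and auto-triggers on few communities", {
  set.seed(13)
  # independent partitions: unadjusted NMI is biased above 0, adjusted is not
  raw <- adj <- numeric(20)
  for (k in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:4, 60, replace = TRUE)
    raw[k] <- nmi(a, b, adjusted = "never")
    adj[k] <- nmi(a, b, adjusted = "always")
  }
  expect_gt(mean(raw), 0.05)
  expect_lt(abs(mean(adj)), 0.05)
  # identical partitions stay at 1 under adjustment
  expect_equal(nmi(a, a, adjusted = "always"), 1)
  # auto rule: N/n_T <= 100 selects the adjusted score
  expect_equal(nmi(a, b), nmi(a, b, adjusted = "always"))
  # ... and a partition with very few communities (N/n_T > 100) stays raw
  big_t <- rep(1:2, each = 150)
  big_d <- sample(1:3, 300, replace = TRUE)
  expect_equal(nmi(big_d, big_t), nmi(big_d, big_t, adjusted = "never"))
})
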