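test_that("true-curve curvature follows the closed form", {
  line <- true_curve(function(x) 2 * x + 1, function(x) rep(2, length(x)),
                     function(x) rep(0, length(x)), c(-10, 10))
  expect_equal(curve_curvature(line, c(-5, 0, 5)), c(0, 0, 0))
  parab <- true_curve(function(x) x^2 / 2, function(x) x,
                      function(x) rep(1, length(x)), c(-5, 5))
  expect_equal(curve_curvature(parab, 0), 1)
  R <- 40
  arc <- true_curve(function(x) sqrt(R^2 - x^2),
                    function(x) -x / sqrt(R^2 - x^2),
                    function(x) -R^2 / (R^2 - x^2)^1.5,
                    c(-20, 20))
  xs <- seq(-20, 20, by = 0.5)
  expect_equal(curve_curvature(arc, xs), rep(1 / R, length(xs)),
               tolerance = 1e-9)
  expect_error(curve_curvature(parab, 9), "domain")
})

test_that("discrete curvature vanishes on straight and regular vertex runs", {
  straight <- cbind(seq(0, 50, by = 5), seq(0, 25, by = 2.5))
  for (i in 3:(nrow(straight) - 2))
    expect_equal(polyline_curvature(straight, i), 0)
  # regular polygon: equal interior angles and edge lengths
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  poly <- cbind(cos(th), sin(th)) * 30
  expect_equal(polyline_curvature(poly, 5), 0, tolerance = 1e-12)
  expect_error(polyline_curvature(straight, 2), "stencil")
  expect_error(polyline_curvature(straight, nrow(straight) - 1), "stencil")
})

test_that("discrete curvature equals a hand-computed quotient", {
  P <- rbind(c(0, 0), c(1, 0), c(2, 0.2), c(3, 0.6), c(4, 1.2))
  ang <- function(k) {
    u <- P[k - 1, ] - P[k, ]; v <- P[k + 1, ] - P[k, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  d <- function(i, j) sqrt(sum((P[i, ] - P[j, ])^2))
  by_hand <- abs((ang(2) + ang(4) - 2 * ang(3)) / (d(2, 3) + d(3, 4)))
  expect_equal(polyline_curvature(P, 3), by_hand, tolerance = 1e-12)
  expect_equal(abs(polyline_curvature(P, 3, signed = TRUE)), by_hand)
})

test_that("curvature error matches a term-by-term recomputation", {
  line <- true_curve(function(x) 3 - x, function(x) rep(-1, length(x)),
                     function(x) rep(0, length(x)), c(0, 100))
  P <- cbind(seq(0, 100, by = 10), 3 - seq(0, 100, by = 10))
  expect_equal(curvature_error(line, P), 0)

  parab <- true_curve(function(x) x^2 / 200, function(x) x / 100,
                      function(x) rep(1 / 100, length(x)), c(0, 100))
  xs <- seq(0, 100, by = 20)
  Q <- cbind(xs, xs^2 / 200)
  got <- curvature_error(parab, Q)
  idx <- 3:(length(xs) - 2)
  manual <- mean(vapply(idx, function(i) {
    kc <- abs(1 / 100) / (1 + (xs[i] / 100)^2)^1.5
    abs(kc - polyline_curvature(Q, i))
  }, numeric(1)))
  expect_equal(got, manual, tolerance = 1e-12)

  # refining the polyline does not increase the error; checked on a
  # constant-curvature arc so the evaluated vertex set stays comparable
  R <- 150
  arc <- true_curve(function(x) R - sqrt(R^2 - x^2),
                    function(x) x / sqrt(R^2 - x^2),
                    function(x) R^2 / (R^2 - x^2)^1.5, c(-60, 60))
  on_arc <- function(step) {
    th0 <- asin(60 / R)
    th <- seq(-th0, th0, length.out = ceiling(2 * th0 * R / step))
    cbind(R * sin(th), R - R * cos(th))
  }
  coarse <- curvature_error(arc, on_arc(20))
  fine <- curvature_error(arc, on_arc(10))
  expect_lte(fine, coarse + 1e-9)
  expect_error(curvature_error(parab, Q[1:4, ]), "5 vertices")
})

test_that("leaf recall reports the raw percentage, over-detection included", {
  expect_equal(leaf_recall(8, 8), 100)
  expect_equal(leaf_recall(0, 8), 0)
  expect_equal(leaf_recall(9, 8), 112.5)
  expect_error(leaf_recall(3, 0), ">= 1")
})

test_that("tip misses are flagged when the outer fifth holds no point", {
  midrib <- cbind(seq(0, 100, by = 2), 0)   # base -> tip along x
  full <- as_seed_points(seq(0, 100, by = 10), rep(0, 11))
  expect_false(tip_miss(midrib, full, corridor = 5))
  inner <- as_seed_points(seq(0, 70, by = 10), rep(0, 8))
  expect_true(tip_miss(midrib, inner, corridor = 5))
  one85 <- as_seed_points(85, 0)
  expect_false(tip_miss(midrib, one85, corridor = 5))
  expect_true(tip_miss(midrib, as_seed_points(numeric(), numeric())))
})

test_that("skeletons are scored against synthetic truth by tip matching", {
  p <- make_plant_top(6, rng_seed = 4)
  sk <- gt_skeleton(p, step = 8)
  ev <- evaluate_skeleton(sk, p)
  expect_equal(ev$leaf_recall, 100)
  expect_equal(ev$n_matched, 6L)
  expect_lt(ev$curvature_error, 0.02)
})
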