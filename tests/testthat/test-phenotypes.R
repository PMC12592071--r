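# skeleton of straight radial leaves around a pot at `center`
radial_skeleton <- function(angles_deg, r_in, r_out, pot,
                            step = 5, view = "top") {
  leaves <- lapply(angles_deg, function(a) {
    th <- a * pi / 180
    rr <- seq(r_out, r_in, by = -step)   # tip first
    cbind(pot$center[1] + rr * cos(th), pot$center[2] + rr * sin(th))
  })
  as_skeleton(leaves, view = view, pot = pot)
}

test_that("leaf count is the number of polylines", {
  pot <- list(center = c(0, 0), radius = 10)
  expect_equal(leaf_count(radial_skeleton(c(0, 90, 200), 12, 40, pot)), 3L)
  expect_equal(leaf_count(as_skeleton(list())), 0L)
})

test_that("crown width is the max pairwise tip distance over the pot diameter", {
  pot <- list(center = c(0, 0), radius = 50)
  sk <- as_skeleton(list(rbind(c(0, 0), c(0, 30), c(0, 60)),
                         rbind(c(200, 0), c(200, 30), c(200, 60))),
                    pot = pot)
  cw <- crown_width(sk)
  expect_equal(cw, 200)
  expect_equal(relative_crown_width(cw, pot), 2)
  # coincident tips
  sk0 <- as_skeleton(list(rbind(c(5, 5), c(6, 20)), rbind(c(5, 5), c(30, 6))))
  expect_equal(crown_width(sk0), 0)
  # tips diametrically opposed on the pot rim: ratio exactly 1
  skr <- as_skeleton(list(rbind(c(-50, 0), c(-20, 0)),
                          rbind(c(50, 0), c(20, 0))), pot = pot)
  expect_equal(relative_crown_width(crown_width(skr), pot), 1)
  expect_warning(cw1 <- crown_width(as_skeleton(list(rbind(c(0, 0), c(1, 1))))),
                 "two leaves")
  expect_true(is.na(cw1))
})

test_that("length consistency is the population variance of arc lengths", {
  sk <- as_skeleton(list(rbind(c(0, 0), c(3, 0)),
                         rbind(c(0, 10), c(5, 10))))
  expect_equal(length_consistency(sk), 1)        # lengths 3 and 5
  same <- as_skeleton(list(rbind(c(0, 0), c(4, 0)),
                           rbind(c(0, 9), c(4, 9))))
  expect_equal(length_consistency(same), 0)
  expect_equal(length_consistency(as_skeleton(list(rbind(c(0, 0), c(7, 0))))),
               0)
})

test_that("ring weights are a softmax peaking mid-radius", {
  expect_equal(gaussian_weights(1, 1), 1)
  expect_equal(gaussian_weights(5, 1e6), rep(0.2, 5), tolerance = 1e-9)
  for (n in c(2, 3, 7, 10, 100, 1000)) {
    w <- gaussian_weights(n, n / 4)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_lte(abs(which.max(w) - n / 2), 0.5)
  }
})

test_that("equally spaced radial leaves have zero distribution variance", {
  pot <- list(center = c(100, 100), radius = 20)
  sk <- radial_skeleton(seq(0, 315, by = 45), 22, 90, pot)
  expect_lt(distribution_consistency(sk, n_rings = 5), 1e-9)
})

test_that("ring arcs match hand geometry at three intersection angles", {
  pot <- list(center = c(0, 0), radius = 10)
  sk <- radial_skeleton(c(0, 90, 180), 12, 40, pot)
  # crown radius 40 -> one mid ring at 10 + (40 - 10) / 2 = 25
  got <- distribution_consistency(sk, n_rings = 1)
  R <- 25
  arcs <- R * c(pi / 2, pi / 2, pi)
  expect_equal(got, mean((arcs - mean(arcs))^2), tolerance = 1e-9)
})

test_that("rings missing a second intersection are skipped and reweighted", {
  pot <- list(center = c(0, 0), radius = 10)
  # leaf A spans radii 12..40 at 0 degrees; leaf B only 12..18 at 120
  A <- cbind(seq(40, 12, by = -2), 0)
  thB <- 120 * pi / 180
  rB <- seq(18, 12, by = -2)
  B <- cbind(rB * cos(thB), rB * sin(thB))
  sk <- as_skeleton(list(A, B), pot = pot)
  cw <- crown_width(sk)
  r_crown <- cw / 2
  radii <- 10 + (1:2) * (r_crown - 10) / 3
  expect_true(radii[1] < 18 && radii[2] > 18)  # ring 2 misses leaf B
  got <- distribution_consistency(sk, n_rings = 2)
  arcs <- radii[1] * c(2 * pi / 3, 4 * pi / 3)
  expect_equal(got, mean((arcs - mean(arcs))^2), tolerance = 1e-9)
})

test_that("height consistency averages keypoint heights above the line", {
  ref <- list(row = 100)
  sk <- as_skeleton(list(rbind(c(0, 90), c(5, 90)),     # mean height 10
                         rbind(c(20, 80), c(25, 80))),  # mean height 20
                    view = "front", reference = ref)
  expect_equal(height_consistency(sk), 25)
  eq <- as_skeleton(list(rbind(c(0, 80), c(5, 90)),
                         rbind(c(20, 95), c(25, 75))),
                    view = "front", reference = ref)
  expect_equal(height_consistency(eq), 0)
  # keypoints below the line contribute negative heights to the mean
  lo <- as_skeleton(list(rbind(c(0, 110), c(5, 110)),   # mean height -10
                         rbind(c(9, 90), c(14, 90))),   # mean height +10
                    view = "front", reference = ref)
  expect_equal(height_consistency(lo), 100)
})

test_that("phenotypes are translation invariant and scale covariant", {
  p <- make_plant_top(6, rng_seed = 5)
  sk <- gt_skeleton(p)
  base <- phenotype_report(sk)
  shift <- function(s, dx, dy) {
    s$leaves$x <- s$leaves$x + dx; s$leaves$y <- s$leaves$y + dy
    s$pot$center <- s$pot$center + c(dx, dy)
    s
  }
  moved <- phenotype_report(shift(sk, 31.5, -17))
  for (col in c("crown_width", "relative_crown_width", "length_consistency",
                "distribution_consistency"))
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-9)

  scale_by <- function(s, f) {
    s$leaves$x <- s$leaves$x * f; s$leaves$y <- s$leaves$y * f
    s$pot$center <- s$pot$center * f; s$pot$radius <- s$pot$radius * f
    s
  }
  s2 <- phenotype_report(scale_by(sk, 2))
  expect_equal(s2$crown_width, 2 * base$crown_width, tolerance = 0.01)
  expect_equal(s2$relative_crown_width, base$relative_crown_width,
               tolerance = 0.01)
  expect_equal(s2$length_consistency, 4 * base$length_consistency,
               tolerance = 0.01)
  expect_equal(s2$distribution_consistency, 4 * base$distribution_consistency,
               tolerance = 0.01)

  # front view: height consistency shifts/scales the same way
  pf <- make_plant_front(4, rng_seed = 5)
  skf <- gt_skeleton(pf)
  h0 <- height_consistency(skf)
  skf2 <- skf
  skf2$leaves$y <- skf2$leaves$y * 2
  skf2$reference$row <- skf2$reference$row * 2
  expect_equal(height_consistency(skf2), 4 * h0, tolerance = 0.01)
})

test_that("distribution consistency is rotation invariant about the pot", {
  pot <- list(center = c(0, 0), radius = 15)
  sk <- radial_skeleton(c(0, 70, 160, 250), 17, 60, pot)
  base <- distribution_consistency(sk, n_rings = 4)
  th <- 40 * pi / 180
  rot <- sk
  rot$leaves <- dplyr::mutate(sk$leaves,
                              x0 = x * cos(th) - y * sin(th),
                              y0 = x * sin(th) + y * cos(th),
                              x = x0, y = y0)
  expect_equal(distribution_consistency(rot, pot = pot, n_rings = 4), base,
               tolerance = 1e-6)
})

test_that("the report fills only the view-appropriate phenotypes", {
  p <- make_plant_top(6, rng_seed = 1)
  rep_top <- phenotype_report(gt_skeleton(p))
  expect_equal(rep_top$leaf_count, 6L)
  expect_false(any(is.na(rep_top[c("crown_width", "relative_crown_width",
                                   "length_consistency",
                                   "distribution_consistency")])))
  expect_true(is.na(rep_top$height_consistency))
  pf <- make_plant_front(4, rng_seed = 1)
  rep_f <- phenotype_report(gt_skeleton(pf))
  expect_true(is.na(rep_f$crown_width))
  expect_false(is.na(rep_f$height_consistency))
})
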