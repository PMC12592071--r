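test_that("hue window with saturation/value floors classifies pixels", {
  px <- function(r, g, b) {
    a <- array(0, c(1, 1, 3)); a[1, 1, ] <- c(r, g, b); a
  }
  expect_true(hsv_mask(px(255, 255, 0))[1, 1])    # hue 60: leaf green
  expect_true(hsv_mask(px(180, 255, 0))[1, 1])    # hue ~78, still inside
  expect_false(hsv_mask(px(0, 255, 128))[1, 1])   # hue ~150: outside
  expect_false(hsv_mask(px(255, 0, 0))[1, 1])     # red, hue 0
  expect_false(hsv_mask(px(0, 0, 0))[1, 1])       # black fails the value floor
  expect_false(hsv_mask(px(128, 128, 128))[1, 1]) # grey fails saturation
  expect_error(hsv_mask(array(0, c(0, 3, 3))), "empty")
})

test_that("hue boundaries are inclusive and in degrees", {
  # hue 60 degrees = pure yellow-green (255, 255, 0) scaled
  a <- array(0, c(1, 2, 3))
  a[1, 1, ] <- c(200, 200, 0)   # hue 60, saturated
  a[1, 2, ] <- c(0, 200, 200)   # hue 180 (cyan)
  m <- hsv_mask(a, 35, 85)
  expect_true(m[1, 1])
  expect_false(m[1, 2])
})

test_that("closing-then-opening fills holes and removes speckle", {
  m <- matrix(FALSE, 30, 30)
  m[6:25, 6:25] <- TRUE
  m[15, 15] <- FALSE            # 1-px hole
  out <- refine_mask(m, 5)
  expect_true(out[15, 15])
  lone <- matrix(FALSE, 30, 30); lone[10, 10] <- TRUE
  expect_false(any(refine_mask(lone, 5)))
  expect_identical(refine_mask(matrix(TRUE, 9, 9)), matrix(TRUE, 9, 9))
  expect_identical(refine_mask(matrix(FALSE, 9, 9)), matrix(FALSE, 9, 9))
})

test_that("refinement matches the set-theoretic morphology oracle", {
  withr::with_seed(42, {
    m <- matrix(runif(64 * 64) < 0.45, 64, 64)
  })
  expect_identical(refine_mask(m, 5), oracle_refine(m, 5))
})

test_that("contours are filtered by area then elongation", {
  m <- matrix(FALSE, 200, 200)
  m[10:19, 10:19] <- TRUE        # 10x10: area 100 < 500 -> out
  m[40:69, 50:149] <- TRUE       # 30x100: area 3000, AR ~3.33 -> kept
  m[100:159, 100:159] <- TRUE    # 60x60: area 3600, AR 1 -> out
  fc <- filter_contours(m, area_min = 500, ar_min = 2)
  expect_equal(nrow(fc$contours), 1L)
  expect_equal(fc$contours$area, 3000)
  expect_equal(fc$contours$rect_long, 100, tolerance = 1e-6)
  expect_equal(fc$contours$rect_short, 30, tolerance = 1e-6)
  # final mask is the kept rectangle only, and a subset of the input
  expect_true(all(fc$mask_leaf[40:69, 50:149]))
  expect_false(any(fc$mask_leaf[10:19, 10:19]))
  expect_true(all(!fc$mask_leaf | m))
  expect_error(filter_contours(matrix(FALSE, 5, 5)), "foreground")
})

test_that("raising the filter thresholds never adds a contour", {
  withr::with_seed(7, {
    m <- matrix(FALSE, 150, 150)
    for (k in 1:6) {
      r0 <- sample(1:110, 1); c0 <- sample(1:110, 1)
      m[r0:(r0 + sample(4:40, 1)), c0:(c0 + sample(4:40, 1))] <- TRUE
    }
  })
  base <- filter_contours(m, area_min = 100, ar_min = 1)$contours$label
  for (am in c(300, 500, 900)) for (ar in c(1.2, 2, 3)) {
    got <- filter_contours(m, area_min = am, ar_min = ar)$contours$label
    expect_true(all(got %in% base))
    expect_lte(length(got), length(base))
  }
})

test_that("pot circle uses the mask centroid and half the shortest contour", {
  mask <- matrix(FALSE, 100, 100)
  mask[41:60, 41:60] <- TRUE  # symmetric about (50.5, 50.5)
  contours <- tibble::tibble(rect_long = c(300, 200),
                             perimeter = c(620, 410))
  pc <- estimate_pot_circle(mask, contours)
  expect_equal(pc$radius, 100)
  expect_equal(pc$center, c(50.5, 50.5))
  expect_equal(estimate_pot_circle(mask, contours[1, ])$radius, 150)
  expect_equal(estimate_pot_circle(mask, contours, mode = "perimeter")$radius,
               205)
  expect_gt(pc$radius, 0)
  expect_error(estimate_pot_circle(mask, contours[0, ]), "no contours")
})

test_that("reference line: hint, pot detection, and mask fallback", {
  expect_identical(estimate_reference_line(pot_hint = 123),
                   list(row = 123, method = "hint"))
  p <- make_plant_front(4, rng_seed = 3)
  est <- estimate_reference_line(p$image)
  expect_equal(est$method, "pot")
  expect_equal(est$row, p$gt_reference$row)
  mask <- matrix(FALSE, 600, 600); mask[100:512, 300] <- TRUE
  fb <- estimate_reference_line(NULL, leaf_mask = mask)
  expect_identical(fb, list(row = 512L, method = "fallback"))
})
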