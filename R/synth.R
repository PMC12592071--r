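# Synthetic plant renderer with exact ground truth.
#
# Top view: leaves radiate from the pot rim with gently bending midribs
# (parabolic in each leaf's local frame). Front view: leaves arch from
# the pot's top edge and droop outward, nested so neighbouring arcs never
# cross. Leaves taper to ~1 px half-width at the tip, so the tip-miss
# phenomenon (narrow tips vanishing under boundary erosion) is
# reproducible. Background is hue-neutral grey and the pot brown, so HSV
# segmentation is exercised non-trivially.

# map image coordinates into a leaf's local frame (x along the leaf axis)
to_leaf_frame <- function(frame, xy) {
  dx <- xy[, 1L] - frame$origin[[1L]]
  dy <- xy[, 2L] - frame$origin[[2L]]
  ca <- cos(frame$angle); sa <- sin(frame$angle)
  cbind(dx * ca + dy * sa, -dx * sa + dy * ca)
}

from_leaf_frame <- function(frame, xy) {
  ca <- cos(frame$angle); sa <- sin(frame$angle)
  cbind(frame$origin[[1L]] + xy[, 1L] * ca - xy[, 2L] * sa,
        frame$origin[[2L]] + xy[, 1L] * sa + xy[, 2L] * ca)
}

# half-width profile: w_base along the blade, tapering to ~1 px at the
# tip over the outermost `taper_frac` of the arc with shape `taper_exp`
# (1 = linear). Narrow tips vanish under the boundary erosion; a short
# linear taper keeps the thin region around 1% of the leaf area, a long
# soft taper (taper_frac = 1, taper_exp < 1) mimics gradually narrowing
# blades.
width_profile <- function(t, w_base = 8, taper_frac = 0.15, taper_exp = 1) {
  1 + (w_base - 1) * pmin(1, (1 - t) / taper_frac)^taper_exp
}

# stamp filled disks along a midrib into image and mask (in place-ish)
render_leaf <- function(img, mask, pts, widths, rgb) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  for (i in seq_len(nrow(pts))) {
    w <- widths[[i]]
    x0 <- pts[i, 1L]; y0 <- pts[i, 2L]
    xs <- max(1L, floor(x0 - w)):min(W, ceiling(x0 + w))
    ys <- max(1L, floor(y0 - w)):min(H, ceiling(y0 + w))
    if (length(xs) == 0L || length(ys) == 0L) next
    dx2 <- (xs - x0)^2
    for (yy in ys) {
      sel <- xs[dx2 + (yy - y0)^2 <= w^2]
      if (length(sel) > 0L) {
        mask[yy, sel] <- TRUE
        img[cbind(yy, sel, 1L)] <- rgb[[1L]]
        img[cbind(yy, sel, 2L)] <- rgb[[2L]]
        img[cbind(yy, sel, 3L)] <- rgb[[3L]]
      }
    }
  }
  list(img = img, mask = mask)
}

leaf_green <- function(hue_deg, s = 0.72, v = 0.62) {
  round(grDevices::col2rgb(grDevices::hsv(hue_deg / 360, s, v))[, 1L])
}

new_synthetic_plant <- function(image, midribs, pot, reference, view,
                                rng_seed, gt_mask = NULL) {
  tips <- t(vapply(midribs, function(g) g$tip, numeric(2)))
  cw <- if (nrow(tips) >= 2L) max(stats::dist(tips)) else 0
  structure(list(image = image, gt_midribs = midribs,
                 gt_count = length(midribs), gt_crown_width = cw,
                 gt_pot = pot, gt_reference = reference, gt_mask = gt_mask,
                 view = view, rng_seed = as.integer(rng_seed)),
            class = "synthetic_plant")
}

#' @export
print.synthetic_plant <- function(x, ...) {
  cat(sprintf("<synthetic_plant> %s view, %d leaves, %dx%d px, seed %d\n",
              x$view, x$gt_count, nrow(x$image), ncol(x$image), x$rng_seed))
  invisible(x)
}

#' Synthetic top-view plant
#'
#' Renders `n_leaves` leaves radiating from the pot rim with jittered
#' angles and smoothly bending midribs (a parabola `y = c x^2` in each
#' leaf's local frame, `x` measured outward from the base along the
#' initial direction). Ground truth — midrib curves with exact
#' derivatives, tips, leaf count, crown width, pot circle — is recorded
#' before rendering. Deterministic per seed.
#'
#' @param n_leaves Number of leaves (>= 1).
#' @param pot_radius Pot radius, px.
#' @param image_side Square image side, px.
#' @param overlap_level `"none"`, `"mild"` or `"heavy"`; sets the default
#'   angular jitter and bending amplitude, and how tightly leaves may
#'   approach each other. Heavy packing that cannot be placed after 25
#'   retries raises an error.
#' @param rng_seed Integer seed.
#' @param jitter Angular jitter as a fraction of the even spacing;
#'   `NULL` uses the overlap level's default. 0 gives exactly even
#'   spacing.
#' @param curvature Midrib bending coefficient `c` in 1/px; `NULL` draws
#'   one per leaf from the overlap level's amplitude, a scalar fixes it
#'   for every leaf (0 = straight leaves).
#' @param w_base Half-width at the leaf base, px.
#' @param taper_frac Outermost arc fraction over which the half-width
#'   tapers linearly to ~1 px.
#' @param hard Add green background speckle and a square green blob to
#'   exercise the area and aspect-ratio filters.
#' @return A `synthetic_plant`: RGB `image` (`H x W x 3`, 0--255),
#'   `gt_midribs` (per leaf: `curve`, local `frame`, dense base-to-tip
#'   `polyline`, `tip`, `base`, `length`), `gt_count`, `gt_crown_width`,
#'   `gt_pot`, `gt_mask` (rendered leaf mask), `view`, `rng_seed`.
#' @examples
#' p <- make_plant_top(8, rng_seed = 1)
#' p$gt_count
#' @export
make_plant_top <- function(n_leaves, pot_radius = 55, image_side = 560,
                           overlap_level = c("none", "mild", "heavy"),
                           rng_seed = 0L, jitter = NULL, curvature = NULL,
                           w_base = 6, taper_frac = 0.08, hard = FALSE) {
  overlap_level <- match.arg(overlap_level)
  stopifnot(n_leaves >= 1, pot_radius > 10, image_side >= 8 * pot_radius / 3)
  defaults <- switch(overlap_level,
                     none  = list(jit = 0.04, amp = 0.0006),
                     mild  = list(jit = 0.22, amp = 0.0011),
                     heavy = list(jit = 0.50, amp = 0.0018))
  if (is.null(jitter)) jitter <- defaults$jit
  amp <- defaults$amp

  withr::with_seed(as.integer(rng_seed), {
    cx <- image_side / 2; cy <- image_side / 2
    base_r <- pot_radius  # bases on the pot rim
    spacing <- 2 * pi / n_leaves
    # base gap must survive the 5x5 closing, which bridges ~4 px
    min_gap <- (2 * w_base + 8) / base_r
    if (n_leaves > 1L && n_leaves * min_gap > 2 * pi)
      abort("could not place leaves without base collisions; fewer leaves or a larger pot")
    angles <- (seq_len(n_leaves) - 1) * spacing +
      stats::runif(n_leaves, -jitter, jitter) * spacing
    if (n_leaves > 1L) {
      # relax overcrowded neighbours apart until every base gap fits
      ord <- order(angles %% (2 * pi))
      a <- sort(angles %% (2 * pi))
      for (it in seq_len(100L)) {
        gaps <- diff(c(a, a[[1L]] + 2 * pi))
        if (min(gaps) >= min_gap - 1e-9) break
        for (k in seq_len(n_leaves)) {
          nxt <- if (k == n_leaves) 1L else k + 1L
          gap <- (if (k == n_leaves) a[[1L]] + 2 * pi else a[[nxt]]) - a[[k]]
          if (gap < min_gap) {
            push <- (min_gap - gap) / 2
            a[[k]] <- a[[k]] - push
            a[[nxt]] <- a[[nxt]] + push
          }
        }
        a <- sort(a %% (2 * pi))
      }
      angles[ord] <- a
    }

    L_max <- image_side / 2 - base_r - w_base - 6
    # zero jitter renders the fully symmetric template: equal lengths,
    # equal spacing (so the ground-truth distribution variance is 0)
    lengths <- if (jitter == 0) {
      rep(0.785 * L_max, n_leaves)
    } else stats::runif(n_leaves, 0.62, 0.95) * L_max
    curv <- if (is.null(curvature)) {
      stats::runif(n_leaves, -amp, amp)
    } else rep(curvature, n_leaves)
    hues <- stats::runif(n_leaves, 45, 75)

    midribs <- vector("list", n_leaves)
    for (j in seq_len(n_leaves)) {
      phi <- angles[[j]]; L <- lengths[[j]]; cc <- curv[[j]]
      base <- c(cx + base_r * cos(phi), cy + base_r * sin(phi))
      frame <- list(origin = base, angle = phi)
      xs <- seq(0, L, by = 1)
      poly <- from_leaf_frame(frame, cbind(xs, cc * xs^2))
      midribs[[j]] <- list(
        curve = true_curve(
          f = local({cc0 <- cc; function(x) cc0 * x^2}),
          df = local({cc0 <- cc; function(x) 2 * cc0 * x}),
          ddf = local({cc0 <- cc; function(x) rep(2 * cc0, length(x))}),
          domain = c(0, L)),
        frame = frame, polyline = poly,
        base = poly[1L, ], tip = poly[nrow(poly), ], length = L)
    }

    img <- array(128, dim = c(image_side, image_side, 3L))
    mask <- matrix(FALSE, image_side, image_side)
    # pot: brown disk
    xg <- matrix(seq_len(image_side), image_side, image_side, byrow = TRUE)
    yg <- matrix(seq_len(image_side), image_side, image_side)
    pot_px <- (xg - cx)^2 + (yg - cy)^2 <= pot_radius^2
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[pot_px] <- c(120, 80, 50)[[ch]]; img[, , ch] <- pl
    }
    if (hard) img <- add_hard_clutter(img, image_side)
    for (j in seq_len(n_leaves)) {
      g <- midribs[[j]]
      ss <- seq(0, g$length, by = 0.75)
      pts <- from_leaf_frame(g$frame, cbind(ss, curv[[j]] * ss^2))
      ww <- width_profile(ss / g$length, w_base, taper_frac)
      rl <- render_leaf(img, mask, pts, ww, leaf_green(hues[[j]]))
      img <- rl$img; mask <- rl$mask
    }
    new_synthetic_plant(img, midribs,
                        pot = list(center = c(cx, cy), radius = pot_radius),
                        reference = NULL, view = "top", rng_seed = rng_seed,
                        gt_mask = mask)
  })
}

add_hard_clutter <- function(img, side) {
  # a green square blob (area filter passes, aspect-ratio filter rejects)
  sq <- leaf_green(60)
  rr <- 8:52; cc <- 8:52
  for (ch in 1:3) { pl <- img[, , ch]; pl[rr, cc] <- sq[[ch]]; img[, , ch] <- pl }
  # small green speckles (opening / area filter fodder)
  for (k in seq_len(30L)) {
    x0 <- stats::runif(1, 10, side - 10); y0 <- stats::runif(1, 10, side - 10)
    if (abs(x0 - side / 2) < side * 0.42 && abs(y0 - side / 2) < side * 0.42) next
    xs <- max(1, floor(x0 - 2)):min(side, ceiling(x0 + 2))
    ys <- max(1, floor(y0 - 2)):min(side, ceiling(y0 + 2))
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[ys, xs] <- sq[[ch]]; img[, , ch] <- pl
    }
  }
  img
}

#' Synthetic front-view plant
#'
#' Renders `n_leaves` blade-shaped leaves fanning up and outward from
#' behind the pot rim, alternating left/right — the regular convex
#' morphology of a front-view cereal or young orchid. Each midrib is a
#' segment of a convex parabola `row(col)`: it rises steeply from the
#' base, bends smoothly outward, and ends at the tip before reaching the
#' apex, so every consecutive ground-truth triple passes the arch test
#' and the midrib is monotone away from the plant base. Inner leaves are
#' taller and steeper, so neighbouring midribs diverge and never cross;
#' the merging leaf bases are hidden behind the pot, whose top edge is
#' the reference line.
#'
#' @param n_leaves Number of leaves (1 to 12; at most 6 per side).
#' @param image_side Square image side, px.
#' @param rng_seed Integer seed.
#' @param jitter Scale factor on all random shape variation; 0 renders
#'   every leaf with its side's deterministic template (a mirrored pair
#'   for `n_leaves = 2` has exactly equal heights).
#' @param w_base Half-width at the leaf base, px.
#' @param taper_frac,taper_exp Taper extent and shape of the half-width
#'   profile; the default long soft taper mimics gradually narrowing
#'   blades.
#' @return A `synthetic_plant` with `gt_reference` (`list(row)`) instead
#'   of a pot circle; midrib curves are `row(col)` parabola segments in
#'   image coordinates (identity local frame).
#' @export
make_plant_front <- function(n_leaves, image_side = 560, rng_seed = 0L,
                             jitter = 1, w_base = 5, taper_frac = 1,
                             taper_exp = 0.7) {
  stopifnot(n_leaves >= 1, image_side >= 280)
  if (n_leaves > 12L) abort("at most 12 front-view leaves (6 per side)")
  withr::with_seed(as.integer(rng_seed), {
    sc <- image_side / 560
    cx <- image_side / 2
    ref_row <- round(image_side * 0.78)
    n_left <- ceiling(n_leaves / 2); n_right <- n_leaves - n_left
    side_of <- c(rep(-1, n_left), rep(1, n_right))
    rank_of <- c(seq_len(n_left), seq_len(max(n_right, 0L)))

    midribs <- vector("list", n_leaves)
    for (j in seq_len(n_leaves)) {
      s <- side_of[[j]]; i <- rank_of[[j]]
      # inner leaves steep and long, outer ones flatter and shorter
      alpha <- (78 - 10 * (i - 1)) * (1 + jitter * stats::runif(1, -0.02, 0.02))
      m <- tan(alpha * pi / 180)
      x0 <- cx + s * (8 + 20 * (i - 1)) * sc +
        jitter * stats::runif(1, -1.5, 1.5)
      xspan <- 150 * sc * (1 - 0.07 * (i - 1)) *
        (1 + jitter * stats::runif(1, -0.04, 0.04))
      xspan <- min(xspan, (image_side - 14 - s * (x0 - cx) - cx) )
      # keep the tip inside the frame vertically
      xspan <- min(xspan, (ref_row - 14) / (0.56 * m))
      cc <- 0.44 * m / xspan   # tip slope = 0.12 * base slope, no droop
      f <- local({m0 <- m; c0 <- cc; s0 <- s; x00 <- x0; r0 <- ref_row
                  function(x) r0 - m0 * s0 * (x - x00) + c0 * (x - x00)^2})
      df <- local({m0 <- m; c0 <- cc; s0 <- s; x00 <- x0
                   function(x) -m0 * s0 + 2 * c0 * (x - x00)})
      ddf <- local({c0 <- cc; function(x) rep(2 * c0, length(x))})
      us <- seq(0, xspan, by = 0.5)               # base -> tip
      xs <- x0 + s * us
      poly <- cbind(xs, f(xs))
      midribs[[j]] <- list(
        curve = true_curve(f, df, ddf, domain = range(c(x0, x0 + s * xspan))),
        frame = list(origin = c(0, 0), angle = 0),
        polyline = poly, base = poly[1L, ], tip = poly[nrow(poly), ],
        length = sum(sqrt(rowSums(diff(poly)^2))))
    }

    img <- array(128, dim = c(image_side, image_side, 3L))
    mask <- matrix(FALSE, image_side, image_side)
    hues <- stats::runif(n_leaves, 45, 75)
    for (j in seq_len(n_leaves)) {
      g <- midribs[[j]]
      P <- g$polyline
      seg <- sqrt(rowSums(diff(P)^2))
      tt <- c(0, cumsum(seg)) / sum(seg)
      ww <- width_profile(tt, w_base, taper_frac, taper_exp)
      rl <- render_leaf(img, mask, P, ww, leaf_green(hues[[j]]))
      img <- rl$img; mask <- rl$mask
    }
    # pot drawn last so it occludes the crowded leaf bases: leaves emerge
    # from behind its top edge (the reference line) as separate blades
    bases <- vapply(midribs, function(g) g$base[[1L]], numeric(1))
    pc <- max(1, round(min(bases) - 26 * sc)):min(image_side,
                                                  round(max(bases) + 26 * sc))
    pr <- ref_row:min(image_side, ref_row + round(image_side * 0.15))
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[pr, pc] <- c(120, 80, 50)[[ch]]; img[, , ch] <- pl
    }
    # pot occludes the mask below the reference line as well
    mask[pr, ] <- FALSE
    new_synthetic_plant(img, midribs, pot = NULL,
                        reference = list(row = ref_row), view = "front",
                        rng_seed = rng_seed, gt_mask = mask)
  })
}

#' Skeleton from ground-truth midribs
#'
#' Downsamples the exact midrib polylines of a synthetic plant into a
#' `plant_skeleton` (tip-first vertex order), for testing phenotype
#' computations against known geometry.
#'
#' @param truth A `synthetic_plant`.
#' @param step Arc-length step between kept vertices, px.
#' @return A `plant_skeleton`.
#' @export
gt_skeleton <- function(truth, step = 10) {
  stopifnot(inherits(truth, "synthetic_plant"))
  leaves <- purrr::imap(truth$gt_midribs, function(g, j) {
    P <- g$polyline[rev(seq(1, nrow(g$polyline), by = max(1L, round(step)))), ,
                    drop = FALSE]
    if (!all(P[1L, ] == g$tip)) P <- rbind(g$tip, P)
    tibble(leaf_id = j, vertex = seq_len(nrow(P)), x = P[, 1L], y = P[, 2L])
  })
  new_plant_skeleton(dplyr::bind_rows(leaves), view = truth$view,
                     pot = truth$gt_pot, reference = truth$gt_reference,
                     params = NULL)
}

#' Write a synthetic plant to disk
#'
#' The rendered image goes to `<stem>.png` and the ground truth (midrib
#' polylines, tips, count, crown width, pot / reference) to
#' `<stem>.json`.
#'
#' @param plant A `synthetic_plant`.
#' @param stem Output path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_synthetic_plant <- function(plant, stem) {
  png_path <- paste0(stem, ".png")
  json_path <- paste0(stem, ".json")
  write_image_png(plant$image, png_path)
  gt <- list(
    view = plant$view, gt_count = plant$gt_count,
    gt_crown_width = plant$gt_crown_width,
    gt_pot = plant$gt_pot, gt_reference = plant$gt_reference,
    rng_seed = plant$rng_seed,
    midribs = purrr::map(plant$gt_midribs, function(g)
      list(polyline = unname(g$polyline), tip = g$tip, base = g$base,
           length = g$length)))
  jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, json_path))
}
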