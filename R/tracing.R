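#' Angle between two vectors
#'
#' `theta = acos(u . v / (|u| |v|)) * 180 / pi`, in degrees within
#' `[0, 180]`.
#'
#' @param u,v Numeric 2-vectors; neither may be zero.
#' @return Angle in degrees.
#' @examples
#' angle_between(c(1, 0), c(0, 1))  # 90
#' @export
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("angle of a zero vector is undefined")
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# vectorised turning angle (degrees) between vector u and each row of V
turn_angles <- function(u, V) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(rowSums(V^2))
  cosv <- (V[, 1L] * u[[1L]] + V[, 2L] * u[[2L]]) / (nu * nv)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Search direction from two consecutive keypoints
#'
#' The dominant axis of the motion `p1 -> p2` and its sense, which
#' restricts the search for the next keypoint to the half-plane of
#' continued motion (halving the search space). Ties between the axes go
#' to horizontal.
#'
#' @param p1,p2 Numeric `(x, y)` points; must differ.
#' @return List with `axis` (`"horizontal"`/`"vertical"`) and `sense`
#'   (`"increasing"`/`"decreasing"`).
#' @examples
#' search_direction(c(10, 0), c(5, 0))  # horizontal, decreasing
#' @export
search_direction <- function(p1, p2) {
  dx <- p2[[1L]] - p1[[1L]]; dy <- p2[[2L]] - p1[[2L]]
  if (dx == 0 && dy == 0) abort("identical points give no direction")
  if (abs(dx) >= abs(dy)) {
    list(axis = "horizontal",
         sense = if (dx > 0) "increasing" else "decreasing")
  } else {
    list(axis = "vertical",
         sense = if (dy > 0) "increasing" else "decreasing")
  }
}

# indices of `cand` (n x 2 coords) in the half-plane of continued motion
# beyond `cur`; `motion` is the last accepted step vector (for mode
# "vector").
halfplane_keep <- function(coords, cur, dir, motion, mode = "axis") {
  if (mode == "vector") {
    return((coords[, 1L] - cur[[1L]]) * motion[[1L]] +
             (coords[, 2L] - cur[[2L]]) * motion[[2L]] > 0)
  }
  ax <- if (dir$axis == "horizontal") 1L else 2L
  if (dir$sense == "increasing") coords[, ax] > cur[[ax]]
  else coords[, ax] < cur[[ax]]
}

#' First keypoint of the next leaf
#'
#' The unvisited point with maximal Euclidean distance from the anchor
#' (the pot centre in top view, the leaf base in front view) — the point
#' closest to a leaf tip. Distance ties go to the smaller `(y, x)`.
#'
#' @param points A `seed_points` tibble (or any tibble with `x`, `y`,
#'   `visited`).
#' @param anchor Numeric `(x, y)` anchor point.
#' @return Row index of the selected point, or `NA_integer_` when every
#'   point has been visited (exhaustion).
#' @export
find_initial_point <- function(points, anchor) {
  free <- which(!points$visited)
  if (length(free) == 0L) return(NA_integer_)
  d <- dist_to(anchor, cbind(points$x[free], points$y[free]))
  free[pick_min(-d, points$y[free], points$x[free])]
}

#' Closest unvisited point inside an expanding search circle
#'
#' The search radius starts at `r0` and grows by `r_step` until at least
#' one unvisited point (restricted to the half-plane when one is given)
#' falls inside, or the radius would exceed `r_max`. Returns the closest
#' such point; distance ties go to the smaller `(y, x)`.
#'
#' @param center Numeric `(x, y)`.
#' @param points A `seed_points` tibble.
#' @param params A [trace_params()].
#' @param half_plane Optional output of [search_direction()]; candidates
#'   must lie strictly beyond `center` in the sense of motion.
#' @return List with `index` (row index or `NA_integer_`) and `radius`
#'   (the final search radius).
#' @export
nearest_in_expanding_circle <- function(center, points, params = trace_params(),
                                        half_plane = NULL) {
  params <- resolve_r_max(params, attr(points, "image_dim"))
  free <- which(!points$visited)
  coords <- cbind(points$x[free], points$y[free])
  if (!is.null(half_plane) && length(free) > 0L) {
    keep <- halfplane_keep(coords, center, half_plane, NULL, "axis")
    free <- free[keep]; coords <- coords[keep, , drop = FALSE]
  }
  if (length(free) == 0L) return(list(index = NA_integer_, radius = params$r0))
  d <- dist_to(center, coords)
  r <- params$r0
  while (r <= params$r_max) {
    inside <- which(d <= r)
    if (length(inside) > 0L) {
      j <- inside[pick_min(d[inside], points$y[free[inside]],
                           points$x[free[inside]])]
      return(list(index = free[[j]], radius = r))
    }
    r <- r + params$r_step
  }
  list(index = NA_integer_, radius = params$r_max)
}

# --- internal expanding-circle engine -------------------------------------
#
# Iterates r = r0, r0 + r_step, ... <= r_max. At each radius the eligible
# candidate rows inside the circle are handed to `select`, which returns a
# row index to accept or NULL to keep expanding. `final` tells `select`
# the cap has been reached. When a radius holds no candidate at all and
# the circle intersects the pot circle, the trace-termination condition
# ||C_pot - P_last|| <= r_pot + r_last is signalled; `floor_row` is the
# front-view analogue (an exhausted circle touching the bottom reference
# line means the leaf base has been reached).
expand_search <- function(center, coords, eligible, params,
                          select, pot = NULL, floor_row = NULL,
                          min_candidates = 1L) {
  if (length(eligible) > 0L) {
    d <- dist_to(center, coords[eligible, , drop = FALSE])
  } else d <- numeric()
  r <- params$r0
  repeat {
    final <- (r + params$r_step) > params$r_max
    inside <- eligible[d <= r]
    sel <- NULL
    if (length(inside) >= min_candidates || (final && length(inside) > 0L)) {
      sel <- select(inside, r, final)
      if (!is.null(sel)) return(list(index = sel, radius = r, pot_stop = FALSE))
    }
    # no admissible candidate at this radius: the leaf has reached its
    # base when the search circle already touches the pot circle (top
    # view) or the bottom reference line (front view)
    if (!is.null(pot)) {
      gap <- sqrt(sum((center - pot$center)^2))
      if (gap <= pot$radius + r) {
        return(list(index = NA_integer_, radius = r, pot_stop = TRUE))
      }
    }
    if (!is.null(floor_row) && center[[2L]] + r >= floor_row) {
      return(list(index = NA_integer_, radius = r, pot_stop = TRUE))
    }
    if (final) return(list(index = NA_integer_, radius = r, pot_stop = FALSE))
    r <- r + params$r_step
  }
}

# closest-point selector with (distance, y, x) tie-break
select_closest <- function(coords, center) {
  force(coords); force(center)
  function(inside, r, final) {
    d <- dist_to(center, coords[inside, , drop = FALSE])
    inside[pick_min(d, coords[inside, 2L], coords[inside, 1L])]
  }
}

# --- random-morphology tracer ---------------------------------------------

#' Trace one leaf with the angle-difference rule (random morphology)
#'
#' Starting from a tip point, the second keypoint is the closest
#' unvisited point found in an expanding circular search. From the third
#' keypoint on, the search is restricted to the half-plane of continued
#' motion and a candidate is accepted only while the turning-angle
#' criterion holds: for the third point the turning angle itself, and
#' thereafter the absolute difference between the candidate's turning
#' angle and the previous one, must not exceed `theta_max` (20 degrees by
#' default); among admissible candidates the one with the smallest
#' criterion wins (ties to smaller distance, then `(y, x)`). The trace
#' ends when an exhausted search circle intersects the pot circle or the
#' radius cap is hit.
#'
#' @param points A `seed_points` tibble.
#' @param start Row index of the tip point (must be unvisited).
#' @param pot Pot circle `list(center, radius)` used for the termination
#'   condition, or `NULL`.
#' @param params A [trace_params()].
#' @return List with `indices` (ordered row indices, tip first), `ok`
#'   (`TRUE` iff at least `min_keypoints` points were accepted) and
#'   `points` (the input with accepted points marked visited).
#' @export
trace_leaf_random <- function(points, start, pot = NULL,
                              params = trace_params()) {
  params <- resolve_r_max(params, attr(points, "image_dim"))
  stopifnot(!points$visited[[start]])
  coords <- cbind(points$x, points$y)
  visited <- points$visited
  chain <- start
  visited[[start]] <- TRUE

  # P2: plain nearest neighbour, no half-plane
  res <- expand_search(coords[start, ], coords, which(!visited), params,
                       select_closest(coords, coords[start, ]), pot = pot)
  if (!is.na(res$index)) {
    chain <- c(chain, res$index)
    visited[[res$index]] <- TRUE

    repeat {
      n <- length(chain)
      cur <- coords[chain[[n]], ]
      prev <- coords[chain[[n - 1L]], ]
      motion <- cur - prev
      dir <- search_direction(prev, cur)
      free <- which(!visited)
      if (length(free) > 0L) {
        keep <- halfplane_keep(coords[free, , drop = FALSE], cur, dir,
                               motion, params$halfplane_mode)
        free <- free[keep]
      }
      prev_turn <- if (n >= 3L) {
        angle_between(prev - coords[chain[[n - 2L]], ], motion)
      } else NA_real_
      select_angle <- function(inside, r, final) {
        V <- coords[inside, , drop = FALSE]
        V[, 1L] <- V[, 1L] - cur[[1L]]; V[, 2L] <- V[, 2L] - cur[[2L]]
        turn <- turn_angles(motion, V)
        crit <- if (is.na(prev_turn)) turn else abs(turn - prev_turn)
        ok <- crit <= params$theta_max
        if (!any(ok)) return(NULL)  # keep expanding
        cand <- inside[ok]
        d <- dist_to(cur, coords[cand, , drop = FALSE])
        cand[pick_min(crit[ok], d, coords[cand, 2L], coords[cand, 1L])]
      }
      res <- expand_search(cur, coords, free, params, select_angle, pot = pot)
      if (is.na(res$index)) break
      chain <- c(chain, res$index)
      visited[[res$index]] <- TRUE
    }
  }
  points$visited <- visited
  list(indices = chain, ok = length(chain) >= params$min_keypoints,
       points = points)
}

# --- regular-morphology tracer --------------------------------------------

# arch (convexity) test: does the middle vertex q lie on or above the
# chord joining p and r (smaller row = higher)? `tol` is a perpendicular
# slack in px absorbing the lateral quantisation noise of grid-sampled
# points; tol = 0 is the exact test.
arch_ok <- function(p, q, r, tol = 0) {
  dx <- r[[1L]] - p[[1L]]
  if (abs(dx) < 1e-12) return(q[[2L]] <= max(p[[2L]], r[[2L]]) + tol)
  cross <- (q[[1L]] - p[[1L]]) * (r[[2L]] - p[[2L]]) -
    (q[[2L]] - p[[2L]]) * (r[[1L]] - p[[1L]])
  # signed perpendicular height of q above the chord (px, y grows down)
  h <- cross * sign(dx) / sqrt(dx^2 + (r[[2L]] - p[[2L]])^2)
  h >= -tol
}

#' Arch (convexity) test along a polyline
#'
#' For every consecutive vertex triple, checks that the middle vertex
#' does not fall below the chord of its neighbours by more than `tol` px
#' (perpendicular distance; rows grow downward, so "below" means a larger
#' row). This encodes the front-view constraint that leaves arch under
#' gravity.
#'
#' @param polyline `n x 2` matrix or tibble with `x`, `y` (n >= 3).
#' @param tol Perpendicular slack in px (0 = exact concavity).
#' @return Logical vector, one entry per interior vertex.
#' @export
arch_test <- function(polyline, tol = 0) {
  P <- if (is.matrix(polyline)) polyline else cbind(polyline$x, polyline$y)
  stopifnot(nrow(P) >= 3L)
  vapply(2:(nrow(P) - 1L), function(i)
    arch_ok(P[i - 1L, ], P[i, ], P[i + 1L, ], tol), logical(1))
}

#' Trace one leaf with the convexity / curvature-minimization rule
#' (regular morphology)
#'
#' Front-view leaves arch under gravity, so consecutive keypoint triples
#' must stay convex (the middle vertex never falls below the chord of its
#' neighbours). From the tip, the second keypoint is the nearby point
#' whose row is closest to the tip's. Later points are held as tentative:
#' when a subsequent candidate forms a convex triple with the last two
#' confirmed keypoints *and* lies above the current tentative point, it
#' replaces it (the flatter arch has lower curvature); otherwise the
#' tentative point is confirmed and the candidate becomes the next
#' tentative point, provided it keeps the chain convex.
#'
#' From the third keypoint on, the search is restricted to the half-plane
#' of continued motion (the search-direction rule applies to both
#' morphologies), and a trace whose exhausted search circle touches the
#' bottom reference line has reached the leaf base and ends there — the
#' front-view analogue of the pot-intersection termination.
#'
#' @inheritParams trace_leaf_random
#' @param reference Optional reference line `list(row)` for the base
#'   termination rule.
#' @return As [trace_leaf_random()]. Points rejected during tentative
#'   replacement stay unvisited and remain available to later leaves.
#' @export
trace_leaf_regular <- function(points, start, params = trace_params(),
                               reference = NULL) {
  params <- resolve_r_max(params, attr(points, "image_dim"))
  stopifnot(!points$visited[[start]])
  coords <- cbind(points$x, points$y)
  visited <- points$visited
  rejected <- rep(FALSE, nrow(coords))  # this-leaf rejections
  chain <- start
  visited[[start]] <- TRUE
  floor_row <- if (!is.null(reference)) reference$row else NULL

  eligible <- function() which(!visited & !rejected)

  # P2: row closest to the tip's row, among >= 2 candidates when possible
  p1 <- coords[start, ]
  sel_rowmatch <- function(inside, r, final) {
    dy <- abs(coords[inside, 2L] - p1[[2L]])
    d <- dist_to(p1, coords[inside, , drop = FALSE])
    inside[pick_min(dy, d, coords[inside, 2L], coords[inside, 1L])]
  }
  res <- expand_search(p1, coords, eligible(), params, sel_rowmatch,
                       floor_row = floor_row, min_candidates = 2L)
  if (!is.na(res$index)) {
    chain <- c(chain, res$index)
    visited[[res$index]] <- TRUE
    tem <- NA_integer_

    repeat {
      n <- length(chain)
      a <- coords[chain[[n - 1L]], ]; b <- coords[chain[[n]], ]
      center <- if (is.na(tem)) b else coords[tem, ]
      dir <- search_direction(a, b)
      free <- eligible()
      if (length(free) > 0L) {
        keep <- halfplane_keep(coords[free, , drop = FALSE], center, dir,
                               b - a, params$halfplane_mode)
        free <- free[keep]
      }
      if (is.na(tem)) {
        # first tentative after the last confirmed pair: convex triple
        # with minimal turning angle at b
        sel_convex <- function(inside, r, final) {
          ok <- vapply(inside, function(j)
            arch_ok(a, b, coords[j, ], params$arch_tol), logical(1))
          if (!any(ok)) return(NULL)
          cand <- inside[ok]
          turn <- vapply(cand, function(j)
            angle_between(b - a, coords[j, ] - b), numeric(1))
          d <- dist_to(b, coords[cand, , drop = FALSE])
          cand[pick_min(turn, d, coords[cand, 2L], coords[cand, 1L])]
        }
        res <- expand_search(center, coords, free, params, sel_convex,
                             floor_row = floor_row, min_candidates = 2L)
        if (is.na(res$index)) break
        tem <- res$index
        rejected[[tem]] <- TRUE  # withheld while tentative
      } else {
        res <- expand_search(center, coords, free, params,
                             select_closest(coords, center),
                             floor_row = floor_row, min_candidates = 2L)
        if (is.na(res$index)) {  # exhausted: confirm the tentative point
          chain <- c(chain, tem)
          visited[[tem]] <- TRUE; rejected[[tem]] <- FALSE
          tem <- NA_integer_
          break
        }
        cand <- res$index
        ct <- coords[tem, ]; cc <- coords[cand, ]
        if (arch_ok(a, b, cc, params$arch_tol) && cc[[2L]] < ct[[2L]]) {
          # flatter arch: replace the tentative point (vector addition
          # b -> tem -> cand collapses to b -> cand); the old tentative
          # stays set aside for this leaf but is free for later ones
          rejected[[cand]] <- TRUE
          tem <- cand
        } else {
          # confirm tem; cand becomes the next tentative if it keeps the
          # chain convex, else it is set aside for this leaf
          chain <- c(chain, tem)
          visited[[tem]] <- TRUE; rejected[[tem]] <- FALSE
          if (arch_ok(b, ct, cc, params$arch_tol)) {
            tem <- cand
            rejected[[cand]] <- TRUE
          } else {
            rejected[[cand]] <- TRUE
            tem <- NA_integer_
          }
        }
      }
    }
    if (!is.na(tem)) {
      chain <- c(chain, tem)
      visited[[tem]] <- TRUE
    }
  }
  points$visited <- visited
  list(indices = chain, ok = length(chain) >= params$min_keypoints,
       points = points)
}

# --- whole-plant loop ------------------------------------------------------

# distance from each row of `coords` to polyline `poly` (m x 2)
dist_to_polyline <- function(coords, poly) {
  dmin <- rep(Inf, nrow(coords))
  for (s in seq_len(nrow(poly) - 1L)) {
    p <- poly[s, ]; q <- poly[s + 1L, ]
    v <- q - p; L2 <- sum(v^2)
    if (L2 == 0) {
      d <- dist_to(p, coords)
    } else {
      t <- ((coords[, 1L] - p[[1L]]) * v[[1L]] +
              (coords[, 2L] - p[[2L]]) * v[[2L]]) / L2
      t <- pmin(1, pmax(0, t))
      d <- sqrt((coords[, 1L] - (p[[1L]] + t * v[[1L]]))^2 +
                  (coords[, 2L] - (p[[2L]] + t * v[[2L]]))^2)
    }
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Trace every leaf of a plant
#'
#' Repeats the per-leaf tracer until exhaustion: the unvisited point
#' farthest from the anchor (pot centre in top view, leaf base in front
#' view) seeds the next leaf tip, the view-appropriate tracer connects
#' it, and leftover points within `consume_width` px of the accepted
#' polyline are retired so they cannot seed duplicate leaves. Traces
#' shorter than `min_keypoints` are dropped (their points are still
#' consumed).
#'
#' @param points A `seed_points` tibble.
#' @param view `"top"` (angle-difference tracer) or `"front"`
#'   (convexity tracer).
#' @param pot Pot circle (top view).
#' @param reference Reference line `list(row)` (front view); points on or
#'   below it are never leaf tips.
#' @param params A [trace_params()].
#' @return A `plant_skeleton` object: list with `leaves` (tibble
#'   `leaf_id`, `vertex`, `x`, `y`, tip first), `view`, `pot`,
#'   `reference`, `params`.
#' @export
trace_all <- function(points, view = c("top", "front"), pot = NULL,
                      reference = NULL, params = trace_params()) {
  view <- match.arg(view)
  params <- resolve_r_max(params, attr(points, "image_dim"))
  if (view == "top" && is.null(pot)) abort("top view needs a pot circle")
  if (view == "front" && is.null(reference))
    abort("front view needs a reference line")
  anchor <- if (view == "top") pot$center
  else c(if (nrow(points)) mean(points$x) else 0, reference$row)

  coords <- cbind(points$x, points$y)
  leaves <- list()
  leaf_id <- 0L
  repeat {
    elig <- points
    if (view == "front") {
      elig$visited <- elig$visited | elig$y >= reference$row
    }
    start <- find_initial_point(elig, anchor)
    if (is.na(start)) break
    # a discarded trace is retried from the same tip with the offending
    # second keypoint masked out: on fine sampling grids the closest
    # point can sit perpendicular to the leaf axis (the grid-band
    # artefact), which dooms the whole trace
    exclude <- integer()
    repeat {
      pts_try <- points
      pts_try$visited[exclude] <- TRUE
      tr <- if (view == "top") {
        trace_leaf_random(pts_try, start, pot, params)
      } else {
        trace_leaf_regular(pts_try, start, params, reference)
      }
      if (tr$ok || length(tr$indices) < 2L || length(exclude) >= 3L) break
      exclude <- c(exclude, tr$indices[[2L]])
    }
    points <- tr$points
    points$visited[setdiff(exclude, tr$indices)] <- FALSE
    poly <- coords[tr$indices, , drop = FALSE]
    if (tr$ok) {
      leaf_id <- leaf_id + 1L
      leaves[[leaf_id]] <- tibble(leaf_id = leaf_id,
                                  vertex = seq_len(nrow(poly)),
                                  x = poly[, 1L], y = poly[, 2L])
      # consume the corridor around the accepted polyline
      if (params$consume_width > 0 && any(!points$visited)) {
        free <- which(!points$visited)
        d <- dist_to_polyline(coords[free, , drop = FALSE], poly)
        points$visited[free[d <= params$consume_width]] <- TRUE
      }
    }
  }
  new_plant_skeleton(
    leaves = if (leaf_id > 0L) dplyr::bind_rows(leaves) else
      tibble(leaf_id = integer(), vertex = integer(),
             x = numeric(), y = numeric()),
    view = view, pot = pot, reference = reference, params = params)
}

new_plant_skeleton <- function(leaves, view, pot = NULL, reference = NULL,
                               params = NULL) {
  structure(list(leaves = leaves, view = view, pot = pot,
                 reference = reference, params = params),
            class = "plant_skeleton")
}

#' @export
print.plant_skeleton <- function(x, ...) {
  n <- length(unique(x$leaves$leaf_id))
  cat(sprintf("<plant_skeleton> %s view, %d %s, %d keypoints\n",
              x$view, n, if (n == 1L) "leaf" else "leaves",
              nrow(x$leaves)))
  if (!is.null(x$pot))
    cat(sprintf("  pot circle: center (%.1f, %.1f), radius %.1f px\n",
                x$pot$center[[1L]], x$pot$center[[2L]], x$pot$radius))
  if (!is.null(x$reference))
    cat(sprintf("  reference line: row %.0f\n", x$reference$row))
  invisible(x)
}
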