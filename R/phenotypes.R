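# Geometric phenotypes computed from a traced plant skeleton.
#
# All variances are population variances (divide by n). Quantities are in
# pixels (px) or px^2; relative crown width is dimensionless.

#' Leaf count
#'
#' @param skeleton A `plant_skeleton`.
#' @return Number of traced polylines.
#' @export
leaf_count <- function(skeleton) {
  length(unique(skeleton$leaves$leaf_id))
}

# tip (first vertex) of every leaf, as a matrix
leaf_tips <- function(skeleton) {
  tips <- skeleton$leaves |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::slice_head(n = 1L) |>
    dplyr::ungroup()
  cbind(tips$x, tips$y)
}

#' Crown width and relative crown width
#'
#' Crown width is the maximum pairwise Euclidean distance between leaf
#' tips (the first keypoint of each polyline), in px. The relative crown
#' width divides by the pot-circle diameter, making the feature robust to
#' image scale.
#'
#' @param skeleton A `plant_skeleton` with at least two leaves.
#' @return `crown_width()`: px; `relative_crown_width()`: dimensionless.
#' @export
crown_width <- function(skeleton) {
  tips <- leaf_tips(skeleton)
  if (nrow(tips) < 2L) {
    warn("crown width needs at least two leaves")
    return(NA_real_)
  }
  max(stats::dist(tips))
}

#' @rdname crown_width
#' @param cw Crown width in px.
#' @param pot Pot circle `list(center, radius)`.
#' @export
relative_crown_width <- function(cw, pot) {
  cw / (2 * pot$radius)
}

#' Leaf length consistency
#'
#' The length of a leaf is the total arc length of its skeleton polyline
#' (sum of consecutive-vertex distances). Leaf length consistency is the
#' population variance of these lengths across leaves, in px^2; 0 means
#' perfectly uniform leaf lengths.
#'
#' @param skeleton A `plant_skeleton` with at least one leaf.
#' @return Variance in px^2.
#' @export
length_consistency <- function(skeleton) {
  lens <- skeleton$leaves |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::summarise(len = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2))) |>
    dplyr::pull("len")
  if (length(lens) == 0L) return(NA_real_)
  var_pop(lens)
}

#' Gaussian ring weights
#'
#' Softmax of `-(j - N/2)^2 / (2 sigma^2)` over `j = 1..N`: weights sum
#' to one and peak at the ring nearest `N/2`, so mid-radius rings — where
#' leaf spacing is most informative — dominate the distribution
#' consistency.
#'
#' @param n Number of rings.
#' @param sigma Gaussian width (> 0).
#' @return Numeric vector of length `n` summing to 1.
#' @examples
#' gaussian_weights(5, 1e6)  # ~ uniform
#' @export
gaussian_weights <- function(n, sigma) {
  stopifnot(n >= 1, sigma > 0)
  j <- seq_len(n)
  z <- -(j - n / 2)^2 / (2 * sigma^2)
  e <- exp(z - max(z))
  e / sum(e)
}

# intersection angles of a circle with one segment p -> q, as angles
# (radians, atan2 convention) about the circle centre
circle_segment_angles <- function(center, radius, p, q) {
  d <- q - p
  f <- p - center
  a <- sum(d^2)
  if (a == 0) return(numeric())
  b <- 2 * sum(f * d)
  cc <- sum(f^2) - radius^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric())
  sq <- sqrt(disc)
  ts <- unique(c((-b - sq) / (2 * a), (-b + sq) / (2 * a)))
  ts <- ts[ts >= 0 & ts <= 1]
  vapply(ts, function(t) {
    pt <- p + t * d
    atan2(pt[[2L]] - center[[2L]], pt[[1L]] - center[[1L]])
  }, numeric(1))
}

#' Leaf distribution consistency (top view)
#'
#' How uniformly the leaves occupy the space around the pot. A crown
#' circle with the crown width as diameter is centred on the pot;
#' `n_rings` concentric circles are placed at equal radial increments
#' strictly between the pot circle and the crown circle. Each ring is
#' intersected with all skeleton segments; the sorted intersection angles
#' cut the ring into arcs whose lengths are the distances between
#' adjacent leaves at that radius. The phenotype is the Gaussian-weighted
#' (mid-radius emphasised) average of the population variances of those
#' arc lengths, in px^2. Rings with fewer than two intersections are
#' skipped and the weights renormalized over the remaining rings.
#'
#' @param skeleton A top-view `plant_skeleton` with >= 2 leaves.
#' @param pot Pot circle; defaults to the skeleton's own.
#' @param n_rings Number of rings (default 9).
#' @param sigma Gaussian weight width (default `n_rings / 4`).
#' @return Weighted variance in px^2, or `NA` when no ring intersects any
#'   leaf.
#' @export
distribution_consistency <- function(skeleton, pot = skeleton$pot,
                                     n_rings = 9L, sigma = n_rings / 4) {
  if (is.null(pot)) abort("distribution consistency needs a pot circle")
  cw <- crown_width(skeleton)
  if (is.na(cw)) return(NA_real_)
  r_crown <- cw / 2
  if (r_crown <= pot$radius) {
    warn("crown circle does not extend beyond the pot circle")
    return(NA_real_)
  }
  radii <- pot$radius + seq_len(n_rings) *
    (r_crown - pot$radius) / (n_rings + 1)
  segs <- skeleton$leaves |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::group_split()
  ring_var <- rep(NA_real_, n_rings)
  for (j in seq_len(n_rings)) {
    angs <- numeric()
    for (leaf in segs) {
      P <- cbind(leaf$x, leaf$y)
      for (s in seq_len(nrow(P) - 1L)) {
        angs <- c(angs, circle_segment_angles(pot$center, radii[[j]],
                                              P[s, ], P[s + 1L, ]))
      }
    }
    if (length(angs) < 2L) next
    angs <- sort(angs)
    angs <- angs[c(TRUE, diff(angs) > 1e-9)]  # merge duplicate tangencies
    if (length(angs) >= 2L &&
        (angs[[length(angs)]] - angs[[1L]]) > 2 * pi - 1e-9) {
      angs <- angs[-length(angs)]
    }
    if (length(angs) < 2L) next
    gaps <- c(diff(angs), 2 * pi - (angs[[length(angs)]] - angs[[1L]]))
    ring_var[[j]] <- var_pop(radii[[j]] * gaps)
  }
  use <- !is.na(ring_var)
  if (!any(use)) {
    warn("no ring intersects any leaf skeleton")
    return(NA_real_)
  }
  w <- gaussian_weights(n_rings, sigma)[use]
  sum(w / sum(w) * ring_var[use])
}

#' Leaf height consistency (front view)
#'
#' Heights are measured upward from the bottom reference line (the top
#' edge of the flowerpot): `h = reference_row - y`, so keypoints below
#' the line get negative heights. Each leaf is summarised by the mean
#' height of its keypoints; the phenotype is the population variance of
#' these means across leaves, in px^2.
#'
#' @param skeleton A front-view `plant_skeleton`.
#' @param reference Reference line `list(row)`; defaults to the
#'   skeleton's own.
#' @return Variance in px^2.
#' @export
height_consistency <- function(skeleton, reference = skeleton$reference) {
  if (is.null(reference)) abort("height consistency needs a reference line")
  hbar <- skeleton$leaves |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::summarise(h = mean(reference$row - .data$y)) |>
    dplyr::pull("h")
  if (length(hbar) == 0L) return(NA_real_)
  var_pop(hbar)
}

#' Phenotype report for one plant
#'
#' Computes the five phenotypes applicable to the skeleton's view: leaf
#' count and — top view — crown width, relative crown width, leaf length
#' consistency and leaf distribution consistency, or — front view — leaf
#' height consistency. Fields not applicable to the view are `NA`.
#'
#' @param skeleton A `plant_skeleton`.
#' @param n_rings,sigma Ring count and Gaussian width for the
#'   distribution consistency.
#' @return A one-row tibble with columns `view`, `leaf_count`,
#'   `crown_width`, `relative_crown_width`, `length_consistency`,
#'   `distribution_consistency`, `height_consistency`.
#' @export
phenotype_report <- function(skeleton, n_rings = 9L, sigma = n_rings / 4) {
  top <- skeleton$view == "top"
  n <- leaf_count(skeleton)
  cw <- if (top && n >= 2L) crown_width(skeleton) else NA_real_
  tibble(
    view = skeleton$view,
    leaf_count = n,
    crown_width = cw,
    relative_crown_width =
      if (top && !is.na(cw)) relative_crown_width(cw, skeleton$pot)
      else NA_real_,
    length_consistency = if (top && n >= 1L) length_consistency(skeleton)
      else NA_real_,
    distribution_consistency =
      if (top && n >= 2L)
        suppressWarnings(distribution_consistency(skeleton,
                                                  n_rings = n_rings,
                                                  sigma = sigma))
      else NA_real_,
    height_consistency =
      if (!top && n >= 1L) height_consistency(skeleton) else NA_real_
  )
}
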