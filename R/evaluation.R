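# Evaluation of predicted skeletons against ground-truth midrib curves:
# curvature error, leaf recall, and the tip-miss diagnostic.

#' Ground-truth skeleton curve
#'
#' A twice-differentiable curve `y(x)` with known first and second
#' derivatives on a closed domain, used as the reference when scoring a
#' predicted polyline.
#'
#' @param f,df,ddf Functions of `x` returning `y`, `y'`, `y''`.
#' @param domain Numeric `c(x_lo, x_hi)`.
#' @return An object of class `true_curve`.
#' @examples
#' arc <- true_curve(function(x) sqrt(100 - x^2),
#'                   function(x) -x / sqrt(100 - x^2),
#'                   function(x) -100 / (100 - x^2)^1.5,
#'                   c(-5, 5))
#' curve_curvature(arc, 0)  # 1/R = 0.1
#' @export
true_curve <- function(f, df, ddf, domain) {
  stopifnot(is.function(f), is.function(df), is.function(ddf),
            length(domain) == 2L, domain[[1L]] < domain[[2L]])
  structure(list(f = f, df = df, ddf = ddf, domain = domain),
            class = "true_curve")
}

#' Ground-truth curve from a dense point list
#'
#' For externally supplied ground truth given only as points, derivatives
#' are estimated by a local quadratic fit around each query abscissa.
#'
#' @param xy `n x 2` matrix of `(x, y)` samples with distinct, ordered x.
#' @param k Number of nearest samples per fit (>= 5).
#' @return A `true_curve`.
#' @export
true_curve_from_points <- function(xy, k = 7L) {
  stopifnot(nrow(xy) >= k, k >= 5)
  xs <- xy[, 1L]; ys <- xy[, 2L]
  fit_at <- function(x0) {
    idx <- order(abs(xs - x0))[seq_len(k)]
    cf <- stats::lm.fit(cbind(1, xs[idx] - x0, (xs[idx] - x0)^2),
                        ys[idx])$coefficients
    c(cf[[1L]], cf[[2L]], 2 * cf[[3L]])
  }
  true_curve(
    f = function(x) vapply(x, function(x0) fit_at(x0)[[1L]], numeric(1)),
    df = function(x) vapply(x, function(x0) fit_at(x0)[[2L]], numeric(1)),
    ddf = function(x) vapply(x, function(x0) fit_at(x0)[[3L]], numeric(1)),
    domain = range(xs))
}

#' Curvature of the true curve
#'
#' `kappa(x) = |y''(x)| / (1 + y'(x)^2)^(3/2)`, in 1/px.
#'
#' @param curve A [true_curve()].
#' @param x Abscissae inside the curve's domain.
#' @return Non-negative curvature values.
#' @export
curve_curvature <- function(curve, x) {
  stopifnot(inherits(curve, "true_curve"))
  if (any(x < curve$domain[[1L]] - 1e-9 | x > curve$domain[[2L]] + 1e-9))
    abort("x outside the curve domain")
  abs(curve$ddf(x)) / (1 + curve$df(x)^2)^1.5
}

# interior angle (radians) at vertex k of polyline P: pi on a straight run
interior_angle <- function(P, k) {
  u <- P[k - 1L, ] - P[k, ]
  v <- P[k + 1L, ] - P[k, ]
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("repeated vertices give no interior angle")
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv))))
}

#' Discrete curvature of a polyline vertex
#'
#' `kappa_i = (theta_{i-1} + theta_{i+1} - 2 theta_i) /
#' (d_{i-1,i} + d_{i,i+1})`, where `theta_k` is the interior angle at
#' vertex `k` in radians and `d` the edge lengths in px, giving units of
#' 1/px commensurable with the true-curve curvature. The second
#' difference of a constant angle vanishes, so straight runs and regular
#' polygons have zero curvature. By default the magnitude is returned;
#' `signed = TRUE` keeps the sign of the second difference.
#'
#' @param polyline `n x 2` matrix (or tibble with `x`, `y`) of ordered
#'   vertices.
#' @param i Vertex index; the full stencil needs `3 <= i <= n - 2`.
#' @param signed Keep the sign? Default `FALSE`.
#' @return Curvature in 1/px.
#' @export
polyline_curvature <- function(polyline, i, signed = FALSE) {
  P <- if (is.matrix(polyline)) polyline else cbind(polyline$x, polyline$y)
  n <- nrow(P)
  if (i < 3L || i > n - 2L) abort("stencil out of range: need 3 <= i <= n-2")
  th <- vapply((i - 1L):(i + 1L), function(k) interior_angle(P, k), numeric(1))
  d1 <- sqrt(sum((P[i, ] - P[i - 1L, ])^2))
  d2 <- sqrt(sum((P[i + 1L, ] - P[i, ])^2))
  k <- (th[[1L]] + th[[3L]] - 2 * th[[2L]]) / (d1 + d2)
  if (signed) k else abs(k)
}

#' Mean curvature error of a predicted polyline
#'
#' Mean absolute difference between the true-curve curvature and the
#' discrete polyline curvature, evaluated at the x-coordinates of the
#' polyline's interior vertices (those with a full curvature stencil and
#' inside the curve domain).
#'
#' @param curve A [true_curve()].
#' @param polyline `n x 2` matrix or tibble with `x`, `y`; `n >= 5`.
#' @return Dimensionless mean absolute curvature difference.
#' @export
curvature_error <- function(curve, polyline) {
  P <- if (is.matrix(polyline)) polyline else cbind(polyline$x, polyline$y)
  if (nrow(P) < 5L) abort("curvature error needs at least 5 vertices")
  idx <- 3:(nrow(P) - 2L)
  idx <- idx[P[idx, 1L] >= curve$domain[[1L]] - 1e-9 &
               P[idx, 1L] <= curve$domain[[2L]] + 1e-9]
  if (length(idx) == 0L) abort("no vertex falls inside the curve domain")
  kc <- curve_curvature(curve, P[idx, 1L])
  kp <- vapply(idx, function(i) polyline_curvature(P, i), numeric(1))
  mean(abs(kc - kp))
}

#' Leaf recall rate
#'
#' `100 * detected / ground truth`, in percent. Over-segmentation is
#' reported as is (values above 100 are possible), mirroring how split
#' leaves show up in practice.
#'
#' @param skeleton A `plant_skeleton` (or an integer detected count).
#' @param gt_count True number of leaves (>= 1).
#' @return Percentage.
#' @export
leaf_recall <- function(skeleton, gt_count) {
  if (gt_count < 1) abort("ground-truth leaf count must be >= 1")
  n <- if (inherits(skeleton, "plant_skeleton")) leaf_count(skeleton)
  else as.numeric(skeleton)
  100 * n / gt_count
}

#' Tip-miss diagnostic
#'
#' A leaf tip counts as missed when no sampled seed point lies within a
#' corridor of half-width `corridor` px around the outermost 20% of the
#' midrib's arc length (the part nearest the tip). Narrow tips eroded
#' away during sampling are the typical cause.
#'
#' @param gt_midrib `n x 2` matrix of the true midrib, ordered base to
#'   tip.
#' @param points A `seed_points` tibble (or `n x 2` matrix).
#' @param corridor Corridor half-width, px (default 5).
#' @param tip_fraction Outermost arc-length fraction (default 0.2,
#'   boundary inclusive).
#' @return `TRUE` iff the tip region holds no sampled point.
#' @export
tip_miss <- function(gt_midrib, points, corridor = 5, tip_fraction = 0.2) {
  P <- if (is.matrix(gt_midrib)) gt_midrib else
    cbind(gt_midrib$x, gt_midrib$y)
  stopifnot(nrow(P) >= 2L)
  XY <- if (is.matrix(points)) points else cbind(points$x, points$y)
  if (nrow(XY) == 0L) return(TRUE)
  seg <- sqrt(rowSums(diff(P)^2))
  L <- sum(seg)
  s <- c(0, cumsum(seg))
  cut <- (1 - tip_fraction) * L
  # sub-polyline from arc length `cut` to the tip
  first <- which(s >= cut)[1L]
  if (is.na(first)) first <- nrow(P)
  if (first == 1L) {
    sub <- P
  } else {
    t <- (cut - s[[first - 1L]]) / (s[[first]] - s[[first - 1L]])
    entry <- P[first - 1L, ] + t * (P[first, ] - P[first - 1L, ])
    sub <- rbind(entry, P[first:nrow(P), , drop = FALSE])
  }
  if (nrow(sub) == 1L) sub <- rbind(sub, sub)
  all(dist_to_polyline(XY, sub) > corridor)
}

#' Score a predicted skeleton against synthetic ground truth
#'
#' Matches each predicted leaf to the ground-truth midrib whose tip is
#' nearest its own tip (greedy, each truth used once), transforms the
#' matched polyline into the leaf's local frame where the true midrib is
#' a function `y(x)`, and averages the per-leaf curvature errors. Also
#' reports the leaf recall and, when seed points are supplied, the
#' per-leaf tip-miss flags.
#'
#' @param skeleton A `plant_skeleton`.
#' @param truth A `synthetic_plant` from [make_plant_top()] /
#'   [make_plant_front()].
#' @param points Optional `seed_points` for the tip-miss diagnostic.
#' @param corridor Tip-miss corridor half-width, px.
#' @return List with `leaf_recall` (%), `curvature_error` (mean over
#'   matched leaves, `NA` when nothing matched), `n_matched`, and
#'   `tip_missed` (logical per true leaf, or `NULL`).
#' @export
evaluate_skeleton <- function(skeleton, truth, points = NULL, corridor = 5) {
  stopifnot(inherits(truth, "synthetic_plant"))
  recall <- leaf_recall(skeleton, truth$gt_count)
  ids <- unique(skeleton$leaves$leaf_id)
  errs <- numeric()
  if (length(ids) > 0L) {
    pred_tips <- leaf_tips(skeleton)
    gt_tips <- t(vapply(truth$gt_midribs, function(g) g$tip, numeric(2)))
    taken <- rep(FALSE, nrow(gt_tips))
    for (i in seq_along(ids)) {
      d <- dist_to(pred_tips[i, ], gt_tips)
      d[taken] <- Inf
      j <- which.min(d)
      if (!is.finite(d[[j]])) next
      taken[[j]] <- TRUE
      leaf <- skeleton$leaves[skeleton$leaves$leaf_id == ids[[i]], ]
      if (nrow(leaf) < 5L) next
      g <- truth$gt_midribs[[j]]
      P <- to_leaf_frame(g$frame, cbind(leaf$x, leaf$y))
      P <- P[order(P[, 1L]), , drop = FALSE]
      inside <- P[, 1L] >= g$curve$domain[[1L]] & P[, 1L] <= g$curve$domain[[2L]]
      P <- P[inside, , drop = FALSE]
      if (nrow(P) >= 5L) errs <- c(errs, curvature_error(g$curve, P))
    }
  }
  miss <- NULL
  if (!is.null(points)) {
    miss <- vapply(truth$gt_midribs, function(g)
      tip_miss(g$polyline, points, corridor = corridor), logical(1))
  }
  list(leaf_recall = recall,
       curvature_error = if (length(errs)) mean(errs) else NA_real_,
       n_matched = length(errs),
       tip_missed = miss)
}
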