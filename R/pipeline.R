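#' Run the full skeletonization pipeline on one image
#'
#' Segmentation (HSV threshold, morphology, contour filters, pot circle /
#' reference line) -> boundary erosion and stratified seed sampling ->
#' keypoint tracing with the view-appropriate tracer -> the five
#' phenotypes.
#'
#' @param image Path to a PNG/JPEG file, or an `H x W x 3` array in
#'   `[0, 255]`.
#' @param view `"top"` or `"front"`.
#' @param config A [pipeline_config()].
#' @return List with `skeleton` (a `plant_skeleton`), `phenotypes`
#'   (one-row tibble), `points` (the sampled `seed_points`, with visited
#'   flags as left by the tracer) and `segmentation` (masks, contours,
#'   pot / reference).
#' @export
run_pipeline <- function(image, view = c("top", "front"),
                         config = pipeline_config()) {
  view <- match.arg(view)
  if (is.character(image)) image <- read_plant_image(image)
  seg <- segment_plant(image, view, config)
  eroded <- erode_boundary(seg$mask_leaf, config$erosion_iterations,
                           config$kernel_side)
  pts <- stratified_sample(eroded, grid = config$grid,
                           pot = if (view == "top") seg$pot else NULL,
                           rng_seed = config$rng_seed)
  params <- trace_params(r0 = config$r0, r_step = config$r_step,
                         r_max = config$r_max,
                         theta_max = config$theta_max,
                         min_keypoints = config$min_keypoints,
                         consume_width = config$consume_width,
                         arch_tol = config$arch_tol,
                         halfplane_mode = config$halfplane_mode)
  skel <- trace_all(pts, view = view, pot = seg$pot,
                    reference = seg$reference, params = params)
  if (leaf_count(skel) == 0L)
    abort("no leaf could be traced", class = "leafskel_no_leaves")
  list(skeleton = skel,
       phenotypes = phenotype_report(skel, n_rings = config$n_rings,
                                     sigma = config$sigma),
       points = skel_points_update(pts, skel),
       segmentation = seg)
}

# carry the tracer's visited flags back onto the sampled points
skel_points_update <- function(pts, skel) {
  if (nrow(skel$leaves) > 0L) {
    key <- paste(pts$x, pts$y)
    used <- paste(skel$leaves$x, skel$leaves$y)
    pts$visited <- pts$visited | key %in% used
  }
  pts
}

#' Write / read a plant skeleton as JSON
#'
#' One object per plant: `view`, per-leaf ordered `[x, y]` keypoints (tip
#' first), and the pot circle / reference row when present. The files
#' round-trip losslessly.
#'
#' @param skeleton A `plant_skeleton`.
#' @param path JSON path.
#' @return `write_skeleton()`: `path`, invisibly; `read_skeleton()`: a
#'   `plant_skeleton`.
#' @export
write_skeleton <- function(skeleton, path) {
  leaves <- if (nrow(skeleton$leaves) == 0L) list() else skeleton$leaves |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::group_map(function(df, key)
      list(leaf_id = key$leaf_id,
           keypoints = unname(as.matrix(df[, c("x", "y")]))))
  obj <- list(view = skeleton$view, leaves = leaves,
              pot = skeleton$pot, reference = skeleton$reference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  leaves <- purrr::map(obj$leaves, function(lf) {
    kp <- matrix(unlist(lf$keypoints), ncol = 2L, byrow = is.list(lf$keypoints))
    tibble(leaf_id = lf$leaf_id, vertex = seq_len(nrow(kp)),
           x = kp[, 1L], y = kp[, 2L])
  })
  pot <- obj$pot
  if (!is.null(pot)) pot$center <- unlist(pot$center)
  new_plant_skeleton(
    leaves = if (length(leaves)) dplyr::bind_rows(leaves) else
      tibble(leaf_id = integer(), vertex = integer(),
             x = numeric(), y = numeric()),
    view = obj$view, pot = pot, reference = obj$reference)
}

#' Score a predicted skeleton JSON against a ground-truth JSON
#'
#' Reads a skeleton written by [write_skeleton()] and a ground truth
#' written by [write_synthetic_plant()], matches predicted leaves to true
#' midribs by tip proximity, reconstructs each true midrib as a
#' differentiable curve in the leaf's own frame (local quadratic fits on
#' the dense polyline), and reports leaf recall and mean curvature error.
#'
#' @param pred_json Path to a predicted-skeleton JSON.
#' @param gt_json Path to a ground-truth JSON.
#' @return One-row tibble: `leaf_recall`, `curvature_error`, `n_detected`,
#'   `n_true`, `n_matched`.
#' @export
run_eval <- function(pred_json, gt_json) {
  skel <- read_skeleton(pred_json)
  gt <- jsonlite::read_json(gt_json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  n_true <- gt$gt_count
  ids <- unique(skel$leaves$leaf_id)
  errs <- numeric()
  if (length(ids) > 0L && n_true > 0L) {
    gt_polys <- purrr::map(gt$midribs, function(g)
      matrix(unlist(g$polyline), ncol = 2L,
             byrow = is.list(g$polyline)))
    gt_tips <- t(vapply(gt_polys, function(P) P[nrow(P), ], numeric(2)))
    pred_tips <- leaf_tips(skel)
    taken <- rep(FALSE, nrow(gt_tips))
    for (i in seq_along(ids)) {
      d <- dist_to(pred_tips[i, ], gt_tips)
      d[taken] <- Inf
      j <- which.min(d)
      if (!is.finite(d[[j]])) next
      taken[[j]] <- TRUE
      P <- gt_polys[[j]]
      # leaf frame from the base and the initial midrib direction
      k <- min(nrow(P), 11L)
      frame <- list(origin = P[1L, ],
                    angle = atan2(P[k, 2L] - P[1L, 2L],
                                  P[k, 1L] - P[1L, 1L]))
      gl <- to_leaf_frame(frame, P)
      curve <- true_curve_from_points(gl)
      leaf <- skel$leaves[skel$leaves$leaf_id == ids[[i]], ]
      if (nrow(leaf) < 5L) next
      Q <- to_leaf_frame(frame, cbind(leaf$x, leaf$y))
      Q <- Q[order(Q[, 1L]), , drop = FALSE]
      Q <- Q[Q[, 1L] >= curve$domain[[1L]] & Q[, 1L] <= curve$domain[[2L]], ,
             drop = FALSE]
      if (nrow(Q) >= 5L) errs <- c(errs, curvature_error(curve, Q))
    }
  }
  tibble(leaf_recall = leaf_recall(length(ids), n_true),
         curvature_error = if (length(errs)) mean(errs) else NA_real_,
         n_detected = length(ids), n_true = n_true,
         n_matched = length(errs))
}

#' Overlay a skeleton (and optionally seed points) on an image
#'
#' Burns the traced polylines (red) and seed points (blue) into a copy of
#' the RGB array and writes it as PNG — a quick visual check of the
#' pipeline.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param skeleton A `plant_skeleton`.
#' @param points Optional `seed_points`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, skeleton, points = NULL, path) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  put <- function(img, xs, ys, rgb) {
    ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
    xs <- round(xs[ok]); ys <- round(ys[ok])
    for (ch in 1:3) img[cbind(ys, xs, ch)] <- rgb[[ch]]
    img
  }
  if (!is.null(points) && nrow(points) > 0L) {
    for (dx in -1:1) for (dy in -1:1)
      image <- put(image, points$x + dx, points$y + dy, c(40, 90, 220))
  }
  for (id in unique(skeleton$leaves$leaf_id)) {
    leaf <- skeleton$leaves[skeleton$leaves$leaf_id == id, ]
    for (s in seq_len(nrow(leaf) - 1L)) {
      n <- max(2L, ceiling(2 * sqrt((leaf$x[[s + 1L]] - leaf$x[[s]])^2 +
                                      (leaf$y[[s + 1L]] - leaf$y[[s]])^2)))
      t <- seq(0, 1, length.out = n)
      image <- put(image, leaf$x[[s]] + t * (leaf$x[[s + 1L]] - leaf$x[[s]]),
                   leaf$y[[s]] + t * (leaf$y[[s + 1L]] - leaf$y[[s]]),
                   c(220, 40, 40))
    }
  }
  write_image_png(image, path)
}
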