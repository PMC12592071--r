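#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a plant skeleton
#'
#' One row per keypoint: `leaf_id`, `vertex` (1 = leaf tip), `x`, `y`.
#'
#' @param x A `plant_skeleton`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.plant_skeleton <- function(x, ...) {
  as_tibble(x$leaves)
}

#' One-row summary of a plant skeleton
#'
#' @param x A `plant_skeleton`.
#' @param ... Unused.
#' @return Tibble with `view`, `n_leaves`, `n_keypoints`,
#'   `mean_keypoints_per_leaf`, `pot_radius`, `reference_row`.
#' @export
glance.plant_skeleton <- function(x, ...) {
  n <- leaf_count(x)
  tibble(view = x$view, n_leaves = n, n_keypoints = nrow(x$leaves),
         mean_keypoints_per_leaf = if (n > 0L) nrow(x$leaves) / n else NA_real_,
         pot_radius = if (!is.null(x$pot)) x$pot$radius else NA_real_,
         reference_row = if (!is.null(x$reference)) x$reference$row
         else NA_real_)
}
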