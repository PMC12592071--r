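#' Boundary erosion before seed sampling
#'
#' Shrinks the leaf mask away from its boundary so that sampled points lie
#' near the central skeleton of each leaf rather than on its edge.
#' Standard morphological erosion with an all-ones square kernel, applied
#' `iterations` times.
#'
#' @param mask Logical mask.
#' @param iterations Number of erosions (>= 0; 0 returns the input).
#' @param kernel_side Side of the square kernel (odd, >= 3). Default 5.
#' @return Logical mask, a subset of the input.
#' @export
erode_boundary <- function(mask, iterations = 1L, kernel_side = 5L) {
  stopifnot(is.matrix(mask), iterations >= 0,
            kernel_side >= 3, kernel_side %% 2 == 1)
  if (iterations == 0L || !any(mask)) return(mask)
  k <- EBImage::makeBrush(as.integer(kernel_side), shape = "box")
  img <- as_ebimage(mask)
  for (i in seq_len(iterations)) img <- EBImage::erode(img, k)
  from_ebimage(img)
}

#' Stratified seed-point sampling
#'
#' Partitions the image into a `grid x grid` lattice of equal cells and
#' draws exactly one uniformly random foreground pixel from every cell
#' that contains at least one eligible pixel. Pixels inside the pot circle
#' are ineligible (top view). The draw is fully determined by `rng_seed`.
#'
#' @param mask Logical (eroded) mask.
#' @param grid Cells per side (default 40).
#' @param pot Optional pot circle (`list(center, radius)`); pixels inside
#'   it are excluded.
#' @param rng_seed Integer seed.
#' @return A `seed_points` tibble with columns `x`, `y`, `cell` and
#'   `visited` (all `FALSE`), carrying `rng_seed` and the image dimensions
#'   as attributes. An empty mask yields a zero-row tibble.
#' @examples
#' m <- matrix(TRUE, 80, 80)
#' nrow(stratified_sample(m, grid = 8, rng_seed = 1))  # one per cell: 64
#' @export
stratified_sample <- function(mask, grid = 40L, pot = NULL, rng_seed = 0L) {
  stopifnot(is.matrix(mask), grid >= 1)
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  pts <- tibble(x = as.numeric(idx[, 2L]), y = as.numeric(idx[, 1L]))
  if (!is.null(pot)) {
    d2 <- (pts$x - pot$center[[1L]])^2 + (pts$y - pot$center[[2L]])^2
    pts <- pts[d2 > pot$radius^2, ]
  }
  if (nrow(pts) == 0L) {
    out <- tibble(x = numeric(), y = numeric(), cell = integer(),
                  visited = logical())
    return(new_seed_points(out, rng_seed, c(H, W), grid))
  }
  # cell of a pixel: 0-based row/col bands of (almost) equal width
  cx <- pmin(floor((pts$x - 1) * grid / W), grid - 1)
  cy <- pmin(floor((pts$y - 1) * grid / H), grid - 1)
  pts$cell <- as.integer(cy * grid + cx + 1)
  picked <- withr::with_seed(as.integer(rng_seed), {
    pts |>
      dplyr::arrange(.data$cell, .data$y, .data$x) |>
      dplyr::group_by(.data$cell) |>
      dplyr::slice_sample(n = 1L) |>
      dplyr::ungroup()
  })
  picked <- dplyr::arrange(picked, .data$cell)
  picked$visited <- FALSE
  new_seed_points(picked, rng_seed, c(H, W), grid)
}

new_seed_points <- function(tbl, rng_seed, dim_hw, grid) {
  structure(tbl,
            rng_seed = as.integer(rng_seed),
            image_dim = as.integer(dim_hw),
            grid = as.integer(grid),
            class = c("seed_points", class(tbl)))
}

#' Export seed points as CSV
#'
#' @param points A `seed_points` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seed_points <- function(points, path) {
  utils::write.csv(points[, c("x", "y")], path, row.names = FALSE)
  invisible(path)
}
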