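#' HSV hue-window segmentation
#'
#' Marks a pixel as leaf candidate iff its hue lies inside the green
#' window and both saturation and value clear their floors. Pure hue
#' thresholding classifies black and grey pixels arbitrarily (their hue is
#' undefined), hence the floors.
#'
#' @param image `H x W x 3` numeric array in `[0, 255]`.
#' @param hue_min,hue_max Hue window in degrees, `0 <= hue_min < hue_max
#'   <= 360`. Defaults 35 and 85 (green).
#' @param sat_min,val_min Saturation/value floors on the 0--255 scale.
#' @return Logical `H x W` mask.
#' @examples
#' px <- array(0, c(1, 1, 3)); px[1, 1, ] <- c(0, 255, 0)
#' hsv_mask(px)[1, 1]   # saturated green -> TRUE
#' @export
hsv_mask <- function(image, hue_min = 35, hue_max = 85,
                     sat_min = 40, val_min = 40) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] < 3L)
    abort("`image` must be an H x W x 3 array")
  if (dim(image)[1L] < 1L || dim(image)[2L] < 1L) abort("empty image")
  stopifnot(hue_min >= 0, hue_min < hue_max, hue_max <= 360)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  hsv <- grDevices::rgb2hsv(rbind(c(image[, , 1L]), c(image[, , 2L]),
                                  c(image[, , 3L])), maxColorValue = 255)
  hue <- hsv[1L, ] * 360
  keep <- hue >= hue_min & hue <= hue_max &
    hsv[2L, ] >= sat_min / 255 & hsv[3L, ] >= val_min / 255
  matrix(keep, H, W)
}

#' Morphological mask refinement
#'
#' Applies a morphological closing followed by an opening, both with an
#' all-ones square structuring element. Closing bridges small gaps and
#' holes inside the leaves; opening removes speckle noise in the
#' background.
#'
#' @param mask Logical `H x W` mask.
#' @param kernel_side Side of the square kernel (odd, >= 3). Default 5.
#' @return Logical mask of the same dimensions.
#' @export
refine_mask <- function(mask, kernel_side = 5L) {
  stopifnot(is.matrix(mask), kernel_side >= 3, kernel_side %% 2 == 1)
  if (!any(mask) || all(mask)) return(mask)  # fixed points of both ops
  k <- EBImage::makeBrush(as.integer(kernel_side), shape = "box")
  img <- as_ebimage(mask)
  from_ebimage(EBImage::opening(EBImage::closing(img, k), k))
}

#' Contour filtering by area and elongation
#'
#' Labels the external 8-connected contours of a refined mask, removes
#' contours with area below `area_min` px2, keeps those whose minimum-area
#' bounding rectangle has aspect ratio (longer side / shorter side)
#' strictly greater than `ar_min`, and intersects the input mask with the
#' filled retained contours to produce the final leaf mask.
#'
#' @param mask Logical refined mask.
#' @param area_min Area cut-off in px2 (default 500).
#' @param ar_min Aspect-ratio threshold (default 2, strict).
#' @return A list with `contours` (tibble: one row per retained contour
#'   with area, bounding-rectangle geometry, perimeter and a `boundary`
#'   list-column of closed (x, y) loops), `mask_b` (filled retained
#'   contours) and `mask_leaf` (`mask & mask_b`). Zero retained contours
#'   yield a zero-row tibble and all-false masks.
#' @export
filter_contours <- function(mask, area_min = 500, ar_min = 2) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) abort("mask has no foreground")
  recs <- contour_records(mask)
  keep <- recs$area >= area_min & recs$aspect_ratio > ar_min
  kept <- recs[keep, ]
  mask_b <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(kept) > 0L) {
    lab <- label_components(mask)
    mask_b <- matrix(lab %in% kept$label, nrow(mask), ncol(mask))
    mask_b <- from_ebimage(EBImage::fillHull(as_ebimage(mask_b)))
  }
  list(contours = kept, mask_b = mask_b, mask_leaf = mask & mask_b)
}

#' Pot-circle estimate (top view)
#'
#' The pot circle is centred on the foreground centroid of the leaf mask;
#' its radius is half the "length" of the shortest retained contour. The
#' default reading of a contour's length is the longer side of its
#' minimum-area bounding rectangle (a leaf's length); `mode = "perimeter"`
#' uses half the traced boundary perimeter instead.
#'
#' @param leaf_mask Logical final leaf mask.
#' @param contours Contour tibble from [filter_contours()].
#' @param mode `"rect"` or `"perimeter"`.
#' @return List with `center` (c(x, y)) and `radius` (px).
#' @export
estimate_pot_circle <- function(leaf_mask, contours,
                                mode = c("rect", "perimeter")) {
  mode <- match.arg(mode)
  if (nrow(contours) == 0L) abort("no contours to estimate the pot circle from")
  idx <- which(leaf_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("leaf mask has no foreground")
  center <- c(x = mean(idx[, 2L]), y = mean(idx[, 1L]))
  len <- if (mode == "rect") min(contours$rect_long) else min(contours$perimeter)
  list(center = unname(center), radius = len / 2)
}

#' Bottom reference line (front view)
#'
#' Returns the image row of the top edge of the flowerpot, which serves as
#' the bottom reference line for leaf heights. If `pot_hint` is supplied
#' it is returned unchanged. Otherwise the pot is sought as the largest
#' saturated non-green region in the lower half of the image; if none is
#' found, the bottom-most foreground row of the leaf mask is used and
#' flagged.
#'
#' @param image `H x W x 3` array, or `NULL` when only the mask fallback
#'   is wanted.
#' @param leaf_mask Logical leaf mask (used for the fallback).
#' @param pot_hint Optional known reference row.
#' @param hue_min,hue_max Green window excluded from the pot search.
#' @param sat_min,val_min Saturation/value floors for pot pixels.
#' @return List with `row` and `method` (`"hint"`, `"pot"` or
#'   `"fallback"`).
#' @export
estimate_reference_line <- function(image = NULL, leaf_mask = NULL,
                                    pot_hint = NULL,
                                    hue_min = 35, hue_max = 85,
                                    sat_min = 40, val_min = 40) {
  if (!is.null(pot_hint)) {
    return(list(row = as.numeric(pot_hint), method = "hint"))
  }
  if (!is.null(image)) {
    H <- dim(image)[1L]
    hsv <- grDevices::rgb2hsv(rbind(c(image[, , 1L]), c(image[, , 2L]),
                                    c(image[, , 3L])), maxColorValue = 255)
    hue <- hsv[1L, ] * 360
    potpx <- matrix(!(hue >= hue_min & hue <= hue_max) &
                      hsv[2L, ] >= sat_min / 255 & hsv[3L, ] >= val_min / 255,
                    H, dim(image)[2L])
    potpx[seq_len(floor(H / 2)), ] <- FALSE  # pot sits in the lower half
    if (any(potpx)) {
      lab <- label_components(potpx)
      sizes <- tabulate(lab[lab > 0L])
      comp <- lab == which.max(sizes)
      return(list(row = min(which(rowSums(comp) > 0L)), method = "pot"))
    }
  }
  if (is.null(leaf_mask) || !any(leaf_mask))
    abort("no pot found and no non-empty leaf mask for the fallback")
  list(row = max(which(rowSums(leaf_mask) > 0L)), method = "fallback")
}

#' Segment a plant image
#'
#' Convenience wrapper running the full segmentation stage: HSV hue
#' thresholding, morphological refinement, contour filtering, and the
#' view-appropriate reference estimate (pot circle for the top view,
#' bottom reference line for the front view).
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param view `"top"` or `"front"`.
#' @param config A [pipeline_config()].
#' @return List with `mask_raw`, `mask_refined`, `mask_leaf`, `contours`,
#'   and `pot` (top view) or `reference` (front view).
#' @export
segment_plant <- function(image, view = c("top", "front"),
                          config = pipeline_config()) {
  view <- match.arg(view)
  raw <- hsv_mask(image, config$hue_min, config$hue_max,
                  config$sat_min, config$val_min)
  refined <- refine_mask(raw, config$kernel_side)
  if (!any(refined)) {
    abort("empty leaf mask after refinement", class = "leafskel_empty_mask")
  }
  fc <- filter_contours(refined, config$area_min, config$ar_min)
  if (nrow(fc$contours) == 0L) {
    abort("no contour passed the area/aspect-ratio filters",
          class = "leafskel_empty_mask")
  }
  out <- list(mask_raw = raw, mask_refined = refined,
              mask_leaf = fc$mask_leaf, contours = fc$contours,
              view = view)
  if (view == "top") {
    out$pot <- estimate_pot_circle(fc$mask_leaf, fc$contours,
                                   config$pot_radius_mode)
  } else {
    out$reference <- estimate_reference_line(
      image, fc$mask_leaf,
      hue_min = config$hue_min, hue_max = config$hue_max,
      sat_min = config$sat_min, val_min = config$val_min)
  }
  out
}
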