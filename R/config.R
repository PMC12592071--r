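#' Pipeline configuration
#'
#' Bundles every tunable constant of the skeletonization pipeline. The
#' defaults are the single global parameter set used for all images:
#' hue window 35--85 degrees, 5x5 square structuring element, one boundary
#' erosion, 500 px2 contour area cut-off, aspect-ratio filter > 2, a 40x40
#' sampling grid, 5 px initial search radius and a 20 degree
#' angle-difference threshold. The remaining keys are implementation
#' choices documented in the methods vignette (search-radius growth and
#' cap, point-consumption corridor, ring count and Gaussian width for the
#' distribution phenotype, half-plane and pot-radius interpretations).
#'
#' @param hue_min,hue_max Green hue window in degrees (0--360).
#' @param sat_min,val_min Saturation / value floors on the 0--255 scale;
#'   pixels darker or greyer than these are never foreground.
#' @param kernel_side Side of the square structuring element (odd, >= 3).
#' @param erosion_iterations Boundary erosions applied before sampling.
#' @param area_min Minimum contour area in px2.
#' @param ar_min Minimum aspect ratio (longer / shorter bounding-rect side);
#'   contours must exceed this strictly.
#' @param grid Stratified-sampling grid side (grid x grid cells).
#' @param r0 Initial search radius, px.
#' @param r_step Radius growth per expansion, px; defaults to `r0`.
#' @param r_max Radius cap, px, or `NA` to use a quarter of the image
#'   diagonal at run time.
#' @param theta_max Angle-difference threshold in degrees (inclusive).
#' @param min_keypoints Minimum accepted polyline length; shorter traces
#'   are discarded.
#' @param consume_width Half-width in px of the corridor around an accepted
#'   polyline whose leftover seed points are retired after the trace.
#' @param arch_tol Perpendicular slack of the front-view arch test, px.
#' @param n_rings Number of concentric rings for the distribution
#'   consistency phenotype.
#' @param sigma Gaussian width of the ring weights; defaults to
#'   `n_rings / 4`.
#' @param halfplane_mode `"axis"` (axis-aligned half-plane, the default) or
#'   `"vector"` (half-plane normal to the motion vector).
#' @param pot_radius_mode `"rect"` (half the longer side of the shortest
#'   contour's minimum-area bounding rectangle, the default) or
#'   `"perimeter"` (half the contour perimeter).
#' @param rng_seed Integer seed driving every stochastic stage.
#'
#' @return A named list of class `leafskel_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$theta_max
#' @export
pipeline_config <- function(hue_min = 35, hue_max = 85,
                            sat_min = 40, val_min = 40,
                            kernel_side = 5L,
                            erosion_iterations = 1L,
                            area_min = 500,
                            ar_min = 2,
                            grid = 40L,
                            r0 = 5,
                            r_step = r0,
                            r_max = NA_real_,
                            theta_max = 20,
                            min_keypoints = 3L,
                            consume_width = 8,
                            arch_tol = 3,
                            n_rings = 9L,
                            sigma = n_rings / 4,
                            halfplane_mode = c("axis", "vector"),
                            pot_radius_mode = c("rect", "perimeter"),
                            rng_seed = 0L) {
  halfplane_mode <- match.arg(halfplane_mode)
  pot_radius_mode <- match.arg(pot_radius_mode)
  stopifnot(hue_min >= 0, hue_min < hue_max, hue_max <= 360,
            kernel_side >= 3, kernel_side %% 2 == 1,
            erosion_iterations >= 0, area_min > 0, ar_min >= 1,
            grid >= 1, r0 > 0, r_step > 0,
            is.na(r_max) || r_max > r0,
            theta_max > 0, theta_max < 180,
            min_keypoints >= 3, consume_width >= 0, arch_tol >= 0,
            n_rings >= 1, sigma > 0)
  structure(list(
    hue_min = hue_min, hue_max = hue_max,
    sat_min = sat_min, val_min = val_min,
    kernel_side = as.integer(kernel_side),
    erosion_iterations = as.integer(erosion_iterations),
    area_min = area_min, ar_min = ar_min,
    grid = as.integer(grid),
    r0 = r0, r_step = r_step, r_max = r_max,
    theta_max = theta_max,
    min_keypoints = as.integer(min_keypoints),
    consume_width = consume_width, arch_tol = arch_tol,
    n_rings = as.integer(n_rings), sigma = sigma,
    halfplane_mode = halfplane_mode,
    pot_radius_mode = pot_radius_mode,
    rng_seed = as.integer(rng_seed)
  ), class = "leafskel_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through a flat, human-editable
#' `key: value` text file (one key per line).
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `leafskel_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "leafskel_config"))
  vals <- vapply(config, function(v) format(v, digits = 17), character(1))
  writeLines(paste0(names(config), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  args <- as.list(vals)
  names(args) <- keys
  num <- !(keys %in% c("halfplane_mode", "pot_radius_mode"))
  args[num] <- lapply(args[num], function(v)
    if (identical(v, "NA")) NA_real_ else as.numeric(v))
  do.call(pipeline_config, args)
}

#' @export
print.leafskel_config <- function(x, ...) {
  cat("<leafskel_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
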