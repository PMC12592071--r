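#' Tracer parameters
#'
#' Parameters of the keypoint-connection tracers. `r0` and `theta_max`
#' are the global constants (5 px initial search radius, 20 degree
#' angle-difference threshold); the remainder are implementation choices:
#' the radius grows by `r_step` per expansion up to `r_max` (default a
#' quarter of the image diagonal, resolved at run time when `NA`), traces
#' shorter than `min_keypoints` are discarded, and leftover seed points
#' within `consume_width` px of an accepted polyline are retired so they
#' cannot seed spurious duplicate leaves.
#'
#' @param r0 Initial search radius, px (> 0).
#' @param r_step Radius growth per expansion, px; defaults to `r0`.
#' @param r_max Radius cap, px (`NA` = image diagonal / 4).
#' @param theta_max Angle-difference threshold, degrees, compared
#'   inclusively (`<=`).
#' @param min_keypoints Minimum polyline length (>= 3).
#' @param consume_width Post-trace consumption corridor half-width, px.
#' @param arch_tol Perpendicular slack of the front-view arch test, px;
#'   absorbs the lateral quantisation noise of grid-sampled seed points
#'   (0 = exact concavity).
#' @param halfplane_mode `"axis"` for the axis-aligned half-plane rule or
#'   `"vector"` for the half-plane normal to the motion vector.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(r0 = 5, r_step = r0, r_max = NA_real_,
                         theta_max = 20, min_keypoints = 3L,
                         consume_width = 8, arch_tol = 3,
                         halfplane_mode = c("axis", "vector")) {
  halfplane_mode <- match.arg(halfplane_mode)
  stopifnot(r0 > 0, r_step > 0, is.na(r_max) || r_max > r0,
            theta_max > 0, theta_max < 180,
            min_keypoints >= 3, consume_width >= 0, arch_tol >= 0)
  structure(list(r0 = r0, r_step = r_step, r_max = r_max,
                 theta_max = theta_max,
                 min_keypoints = as.integer(min_keypoints),
                 consume_width = consume_width, arch_tol = arch_tol,
                 halfplane_mode = halfplane_mode),
            class = "trace_params")
}

# fill in r_max from the image diagonal when unset
resolve_r_max <- function(params, dim_hw) {
  if (!is.na(params$r_max)) return(params)
  if (is.null(dim_hw)) {
    params$r_max <- 1e6  # unbounded point sets: effectively no cap
  } else {
    params$r_max <- sqrt(sum(as.numeric(dim_hw)^2)) / 4
  }
  params
}
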