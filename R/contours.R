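# Connected components and contour geometry for binary masks.
#
# Components are 8-connected. EBImage::bwlabel is 4-connective, so labels
# touching diagonally are merged afterwards with a union-find pass.

label_components <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- t(EBImage::imageData(EBImage::bwlabel(as_ebimage(mask))))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)

  H <- nrow(lab); W <- ncol(lab)
  pairs <- NULL
  # diagonal adjacencies between distinct labels
  a <- lab[-H, -W]; b <- lab[-1, -1]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  a <- lab[-H, -1]; b <- lab[-1, -W]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  if (is.null(pairs)) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# External boundary of one 8-connected component by Moore-neighbour
# tracing, starting at the topmost-then-leftmost pixel. Returns a closed
# loop as an n x 2 matrix of (x, y) pixel coordinates.
trace_boundary <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)            # (row, col)
  start <- idx[order(idx[, 1L], idx[, 2L])[1L], ]
  H <- nrow(comp); W <- ncol(comp)
  # clockwise Moore neighbourhood in (dy, dx), starting west
  nb <- cbind(dy = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
              dx = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  inside <- function(y, x) y >= 1L && y <= H && x >= 1L && x <= W && comp[y, x]
  if (nrow(idx) == 1L) return(cbind(x = start[[2L]], y = start[[1L]]))

  path <- matrix(0L, nrow = 4L * nrow(idx) + 8L, ncol = 2L)
  cur <- c(start[[1L]], start[[2L]])
  path[1L, ] <- cur
  npts <- 1L
  dir <- 7L  # came from the north-west: begin scan pointing west-ish
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      ny <- cur[[1L]] + nb[d + 1L, 1L]; nx <- cur[[2L]] + nb[d + 1L, 2L]
      if (inside(ny, nx)) {
        cur <- c(ny, nx)
        npts <- npts + 1L
        if (npts > nrow(path)) path <- rbind(path, path)  # grow, rare
        path[npts, ] <- cur
        dir <- (d + 6L) %% 8L  # backtrack then continue clockwise
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster fully scanned
    if (cur[[1L]] == start[[1L]] && cur[[2L]] == start[[2L]]) break
  }
  cbind(x = path[seq_len(npts), 2L], y = path[seq_len(npts), 1L])
}

# Minimum-area bounding rectangle of a point set by rotating calipers over
# the convex hull. Side lengths include the 1 px pixel footprint so a
# solid w x h pixel block reports sides w and h exactly.
min_area_rect <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) == 1L) {
    return(list(center = c(xy[1L, 1L], xy[1L, 2L]), long = 1, short = 1, angle = 0))
  }
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  hull <- xy[h, , drop = FALSE]
  n <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    p <- hull[i, ]; q <- hull[if (i == n) 1L else i + 1L, ]
    e <- q - p; len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[[2L]], u[[1L]])
    pu <- hull %*% u; pv <- hull %*% v
    w <- max(pu) - min(pu) + 1
    hh <- max(pv) - min(pv) + 1
    if (w * hh < best_area - 1e-12) {
      best_area <- w * hh
      cu <- (max(pu) + min(pu)) / 2; cv <- (max(pv) + min(pv)) / 2
      center <- cu * u + cv * v
      if (w >= hh) {
        best <- list(center = center, long = w, short = hh,
                     angle = atan2(u[[2L]], u[[1L]]) * 180 / pi)
      } else {
        best <- list(center = center, long = hh, short = w,
                     angle = atan2(v[[2L]], v[[1L]]) * 180 / pi)
      }
    }
  }
  best$angle <- ((best$angle + 90) %% 180) - 90  # long-axis direction, (-90, 90]
  best
}

contour_perimeter <- function(boundary) {
  if (nrow(boundary) < 2L) return(0)
  d <- diff(boundary)
  sum(sqrt(rowSums(d^2)))
}

# One record per 8-connected component of `mask`.
contour_records <- function(mask) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) {
    return(tibble(label = integer(), area = numeric(),
                  rect_cx = numeric(), rect_cy = numeric(),
                  rect_long = numeric(), rect_short = numeric(),
                  rect_angle = numeric(), aspect_ratio = numeric(),
                  perimeter = numeric(), boundary = list()))
  }
  recs <- purrr::map(seq_len(n), function(l) {
    comp <- lab == l
    idx <- which(comp, arr.ind = TRUE)
    xy <- cbind(idx[, 2L], idx[, 1L])  # (x, y)
    rect <- min_area_rect(xy)
    bnd <- trace_boundary(comp)
    tibble(label = l, area = nrow(xy),
           rect_cx = rect$center[[1L]], rect_cy = rect$center[[2L]],
           rect_long = rect$long, rect_short = rect$short,
           rect_angle = rect$angle,
           aspect_ratio = rect$long / rect$short,
           perimeter = contour_perimeter(bnd),
           boundary = list(bnd))
  })
  dplyr::bind_rows(recs)
}
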