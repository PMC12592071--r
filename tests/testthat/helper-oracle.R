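# Independent brute-force oracles.
#
# Morphology: pixel-by-pixel set-theoretic definitions. Tracers: a flat
# re-implementation of the printed selection rules that recomputes every
# distance and angle from scratch at each step, with no incremental
# radius bookkeeping or shared code with the package internals.

oracle_erode <- function(m, k = 5L) {
  H <- nrow(m); W <- ncol(m); h <- (k - 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- max(1L, r - h):min(H, r + h)
    cc <- max(1L, c - h):min(W, c + h)
    out[r, c] <- all(m[rr, cc])
  }
  out
}

oracle_dilate <- function(m, k = 5L) {
  H <- nrow(m); W <- ncol(m); h <- (k - 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- max(1L, r - h):min(H, r + h)
    cc <- max(1L, c - h):min(W, c + h)
    out[r, c] <- any(m[rr, cc])
  }
  out
}

oracle_refine <- function(m, k = 5L) {
  closed <- oracle_erode(oracle_dilate(m, k), k)
  oracle_dilate(oracle_erode(closed, k), k)
}

# angle helpers, written plainly
o_ang <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
o_first <- function(...) order(..., method = "radix")[1]

# half-plane membership of point q relative to cur given motion a -> b
o_halfplane <- function(q, cur, a, b) {
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  if (abs(dx) >= abs(dy)) {
    if (dx > 0) q[1] > cur[1] else q[1] < cur[1]
  } else {
    if (dy > 0) q[2] > cur[2] else q[2] < cur[2]
  }
}

o_arch <- function(p, q, r, tol) {
  dx <- r[1] - p[1]
  if (abs(dx) < 1e-12) return(q[2] <= max(p[2], r[2]) + tol)
  cross <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  cross * sign(dx) / sqrt(dx^2 + (r[2] - p[2])^2) >= -tol
}

# radii at which the search circle is evaluated
o_radii <- function(params) {
  rs <- params$r0
  while (rs[length(rs)] + params$r_step <= params$r_max)
    rs <- c(rs, rs[length(rs)] + params$r_step)
  rs
}

oracle_trace_random <- function(coords, start, pot, params) {
  visited <- rep(FALSE, nrow(coords))
  chain <- start
  visited[start] <- TRUE
  radii <- o_radii(params)
  repeat {
    k <- length(chain)
    cur <- coords[chain[k], ]
    accepted <- NA_integer_
    stopped <- FALSE
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      final <- ri == length(radii)
      elig <- which(!visited)
      if (k >= 2) {
        a <- coords[chain[k - 1], ]
        elig <- elig[vapply(elig, function(j)
          o_halfplane(coords[j, ], cur, a, cur), logical(1))]
      }
      d <- sqrt((coords[elig, 1] - cur[1])^2 + (coords[elig, 2] - cur[2])^2)
      inside <- elig[d <= r]
      if (length(inside) > 0) {
        if (k == 1) {
          dd <- sqrt((coords[inside, 1] - cur[1])^2 +
                       (coords[inside, 2] - cur[2])^2)
          accepted <- inside[o_first(dd, coords[inside, 2], coords[inside, 1])]
          break
        }
        a <- coords[chain[k - 1], ]
        motion <- cur - a
        turn <- vapply(inside, function(j)
          o_ang(motion, coords[j, ] - cur), numeric(1))
        crit <- if (k == 2) turn else {
          prev_turn <- o_ang(a - coords[chain[k - 2], ], motion)
          abs(turn - prev_turn)
        }
        ok <- crit <= params$theta_max
        if (any(ok)) {
          cand <- inside[ok]
          dd <- sqrt((coords[cand, 1] - cur[1])^2 +
                       (coords[cand, 2] - cur[2])^2)
          accepted <- cand[o_first(crit[ok], dd, coords[cand, 2],
                                   coords[cand, 1])]
          break
        }
      }
      if (!is.null(pot) &&
          sqrt(sum((cur - pot$center)^2)) <= pot$radius + r) {
        stopped <- TRUE; break
      }
      if (final) { stopped <- TRUE; break }
    }
    if (is.na(accepted)) break
    chain <- c(chain, accepted)
    visited[accepted] <- TRUE
  }
  chain
}

oracle_trace_regular <- function(coords, start, params, reference = NULL) {
  n <- nrow(coords)
  visited <- rep(FALSE, n)
  rejected <- rep(FALSE, n)
  chain <- start
  visited[start] <- TRUE
  floor_row <- if (is.null(reference)) NULL else reference$row
  radii <- o_radii(params)

  # one full expanding-circle pass; `admit` maps candidate rows inside
  # the circle to the accepted row or NA
  sweep <- function(center, elig_fun, admit, min_cand) {
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      final <- ri == length(radii)
      elig <- elig_fun()
      d <- sqrt((coords[elig, 1] - center[1])^2 +
                  (coords[elig, 2] - center[2])^2)
      inside <- elig[d <= r]
      if (length(inside) >= min_cand || (final && length(inside) > 0)) {
        got <- admit(inside)
        if (!is.na(got)) return(got)
      }
      if (!is.null(floor_row) && center[2] + r >= floor_row) return(NA_integer_)
      if (final) return(NA_integer_)
    }
    NA_integer_
  }

  p1 <- coords[start, ]
  p2 <- sweep(p1, function() which(!visited & !rejected), function(inside) {
    dy <- abs(coords[inside, 2] - p1[2])
    dd <- sqrt((coords[inside, 1] - p1[1])^2 + (coords[inside, 2] - p1[2])^2)
    inside[o_first(dy, dd, coords[inside, 2], coords[inside, 1])]
  }, 2L)
  if (!is.na(p2)) {
    chain <- c(chain, p2)
    visited[p2] <- TRUE
    tem <- NA_integer_
    repeat {
      k <- length(chain)
      a <- coords[chain[k - 1], ]; b <- coords[chain[k], ]
      center <- if (is.na(tem)) b else coords[tem, ]
      elig_fun <- function() {
        e <- which(!visited & !rejected)
        e[vapply(e, function(j) o_halfplane(coords[j, ], center, a, b),
                 logical(1))]
      }
      if (is.na(tem)) {
        got <- sweep(center, elig_fun, function(inside) {
          ok <- vapply(inside, function(j)
            o_arch(a, b, coords[j, ], params$arch_tol), logical(1))
          if (!any(ok)) return(NA_integer_)
          cand <- inside[ok]
          turn <- vapply(cand, function(j) o_ang(b - a, coords[j, ] - b),
                         numeric(1))
          dd <- sqrt((coords[cand, 1] - b[1])^2 + (coords[cand, 2] - b[2])^2)
          cand[o_first(turn, dd, coords[cand, 2], coords[cand, 1])]
        }, 2L)
        if (is.na(got)) break
        tem <- got
        rejected[tem] <- TRUE
      } else {
        got <- sweep(center, elig_fun, function(inside) {
          dd <- sqrt((coords[inside, 1] - center[1])^2 +
                       (coords[inside, 2] - center[2])^2)
          inside[o_first(dd, coords[inside, 2], coords[inside, 1])]
        }, 2L)
        if (is.na(got)) {
          chain <- c(chain, tem)
          visited[tem] <- TRUE; rejected[tem] <- FALSE
          tem <- NA_integer_
          break
        }
        ct <- coords[tem, ]; cc <- coords[got, ]
        if (o_arch(a, b, cc, params$arch_tol) && cc[2] < ct[2]) {
          rejected[got] <- TRUE
          tem <- got
        } else {
          chain <- c(chain, tem)
          visited[tem] <- TRUE; rejected[tem] <- FALSE
          if (o_arch(b, ct, cc, params$arch_tol)) {
            tem <- got
            rejected[got] <- TRUE
          } else {
            rejected[got] <- TRUE
            tem <- NA_integer_
          }
        }
      }
    }
    if (!is.na(tem)) {
      chain <- c(chain, tem)
      visited[tem] <- TRUE
    }
  }
  chain
}
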