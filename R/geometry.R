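# Planar polygon engine.
#
# All geometry in the package is planar and projected (meters). Polygons are
# represented as "polysets": collections of convex pieces (counter-clockwise
# vertex matrices). Arbitrary regions -- buffered corridors, catchments built
# from drainage tiles, dissolved protected-area layers -- are unions of such
# pieces; pieces are allowed to overlap, and all area computations are
# union-aware (overlap is never double counted). Union area is computed
# exactly by a vertical sweep whose breakpoints are all vertex x-coordinates
# plus all pairwise edge crossings: between consecutive breakpoints the union
# length of the covered y-intervals is linear in x, so the midpoint rule
# integrates it exactly.

#' Polygon collection (union of convex pieces)
#'
#' Builds a `polyset`, the package's representation of a planar region as a
#' union of convex polygon pieces. Degenerate (near zero area) pieces are
#' dropped. Vertex order is normalised to counter-clockwise.
#'
#' @param pieces list of numeric matrices with two columns (x, y in meters),
#'   each a convex polygon given by its vertices (not closed).
#' @return an object of class `polyset` with elements `pieces` (the vertex
#'   matrices) and `rect` (logical, whether a piece is an axis-aligned
#'   rectangle, enabling fast paths).
#' @export
polyset <- function(pieces = list()) {
  stopifnot(is.list(pieces))
  keep <- list()
  for (m in pieces) {
    if (is.null(m)) next
    m <- as.matrix(m)
    if (nrow(m) < 3L || ncol(m) != 2L) next
    if (abs(signed_area(m)) < 1e-9) next
    if (signed_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    keep[[length(keep) + 1L]] <- unname(m)
  }
  structure(list(pieces = keep, rect = vapply(keep, is_axis_rect, logical(1))),
            class = "polyset")
}

#' @export
print.polyset <- function(x, ...) {
  cat(sprintf("<polyset: %d convex piece(s), union area %.6g km2>\n",
              length(x$pieces), ps_union_area(x) / 1e6))
  invisible(x)
}

#' Rectangle piece helper
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in meters.
#' @return a 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_piece <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

signed_area <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2
}

is_axis_rect <- function(m) {
  nrow(m) == 4L &&
    length(unique(round(m[, 1], 9))) == 2L &&
    length(unique(round(m[, 2], 9))) == 2L &&
    all(round(m[, 1], 9) %in% round(range(m[, 1]), 9)) &&
    all(round(m[, 2], 9) %in% round(range(m[, 2]), 9))
}

ps_is_empty <- function(ps) length(ps$pieces) == 0L

ps_bind <- function(...) {
  parts <- list(...)
  polyset(unlist(lapply(parts, function(p) {
    if (inherits(p, "polyset")) p$pieces else p
  }), recursive = FALSE))
}

ps_bbox <- function(ps) {
  if (ps_is_empty(ps)) return(c(0, 0, 0, 0))
  xs <- unlist(lapply(ps$pieces, function(m) range(m[, 1])))
  ys <- unlist(lapply(ps$pieces, function(m) range(m[, 2])))
  c(min(xs), min(ys), max(xs), max(ys))
}

piece_bboxes <- function(pieces) {
  t(vapply(pieces, function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])),
           numeric(4)))
}

# Sutherland-Hodgman clip of a convex subject by a convex (CCW) clip polygon.
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # signed distance > 0 means left of edge a->b (inside for CCW clip)
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    nxt <- c(2:n, 1L)
    res <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(n)) {
      k2 <- nxt[k]
      in1 <- d[k] >= -1e-12; in2 <- d[k2] >= -1e-12
      if (in1) res <- rbind(res, out[k, ])
      if (in1 != in2) {
        t <- d[k] / (d[k] - d[k2])
        res <- rbind(res, out[k, ] + t * (out[k2, ] - out[k, ]))
      }
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3L || abs(signed_area(out)) < 1e-9) return(NULL)
  out
}

#' Intersection of two polygon collections
#'
#' Pairwise convex clipping with a bounding-box prefilter; the result is the
#' region covered by both inputs (its pieces may overlap when input pieces
#' overlap; all downstream area computations are union-aware).
#'
#' @param a,b `polyset` objects.
#' @return a `polyset`.
#' @export
ps_intersect <- function(a, b) {
  if (ps_is_empty(a) || ps_is_empty(b)) return(polyset())
  ba <- piece_bboxes(a$pieces)
  bb <- piece_bboxes(b$pieces)
  out <- list()
  for (i in seq_along(a$pieces)) {
    cand <- which(bb[, 1] <= ba[i, 3] & bb[, 3] >= ba[i, 1] &
                  bb[, 2] <= ba[i, 4] & bb[, 4] >= ba[i, 2])
    for (j in cand) {
      # fast path: both axis-aligned rectangles
      if (a$rect[i] && b$rect[j]) {
        xmin <- max(ba[i, 1], bb[j, 1]); xmax <- min(ba[i, 3], bb[j, 3])
        ymin <- max(ba[i, 2], bb[j, 2]); ymax <- min(ba[i, 4], bb[j, 4])
        if (xmax - xmin > 1e-12 && ymax - ymin > 1e-12)
          out[[length(out) + 1L]] <- rect_piece(xmin, ymin, xmax, ymax)
      } else {
        cl <- clip_convex(a$pieces[[i]], b$pieces[[j]])
        if (!is.null(cl)) out[[length(out) + 1L]] <- cl
      }
    }
  }
  polyset(out)
}

# x-coordinates of crossings between edge sets (e1, e2 are matrices with
# columns x1, y1, x2, y2). Vectorised over all pairs.
edge_crossing_x <- function(e1, e2) {
  n1 <- nrow(e1); n2 <- nrow(e2)
  if (n1 == 0L || n2 == 0L) return(numeric(0))
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  p1x <- e1[i, 1]; p1y <- e1[i, 2]; d1x <- e1[i, 3] - p1x; d1y <- e1[i, 4] - p1y
  q1x <- e2[j, 1]; q1y <- e2[j, 2]; d2x <- e2[j, 3] - q1x; d2y <- e2[j, 4] - q1y
  den <- d1x * d2y - d1y * d2x
  ok <- abs(den) > 1e-14
  if (!any(ok)) return(numeric(0))
  rx <- q1x - p1x; ry <- q1y - p1y
  t <- (rx * d2y - ry * d2x) / den
  u <- (rx * d1y - ry * d1x) / den
  ok <- ok & t >= -1e-12 & t <= 1 + 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
  (p1x + t * d1x)[ok]
}

piece_edges <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  cbind(m[, 1], m[, 2], m[j, 1], m[j, 2])
}

#' Union area of a polygon collection
#'
#' Exact area of the union of the pieces (overlap counted once), by a
#' vertical sweep with edge-crossing breakpoints and group-wise interval
#' merging.
#'
#' @param ps a `polyset`.
#' @return area in square meters.
#' @export
ps_union_area <- function(ps) {
  pieces <- ps$pieces
  np <- length(pieces)
  if (np == 0L) return(0)
  if (np == 1L) return(abs(signed_area(pieces[[1]])))
  bb <- piece_bboxes(pieces)
  # breakpoints: all vertex x's, plus crossings between bbox-overlapping,
  # not-both-rectangular piece pairs (axis-aligned rectangles can only cross
  # at x's already present as vertices)
  xs <- unlist(lapply(pieces, function(m) m[, 1]))
  cross <- numeric(0)
  for (i in seq_len(np - 1L)) {
    cand <- which(bb[(i + 1L):np, 1] <= bb[i, 3] & bb[(i + 1L):np, 3] >= bb[i, 1] &
                  bb[(i + 1L):np, 2] <= bb[i, 4] & bb[(i + 1L):np, 4] >= bb[i, 2]) + i
    cand <- cand[!(ps$rect[i] & ps$rect[cand])]
    if (!length(cand)) next
    e1 <- piece_edges(pieces[[i]])
    e2 <- do.call(rbind, lapply(pieces[cand], piece_edges))
    cross <- c(cross, edge_crossing_x(e1, e2))
  }
  xs <- sort(unique(round(c(xs, cross), 9)))
  if (length(xs) < 2L) return(0)
  w <- diff(xs)
  keep <- w > 1e-12
  mids <- (xs[-length(xs)] + xs[-1L])[keep] / 2
  w <- w[keep]
  nb <- length(mids)
  if (nb == 0L) return(0)
  # per piece, the covered y-interval [lo, hi] at each midpoint it spans
  g_all <- lo_all <- hi_all <- vector("list", np)
  for (k in seq_len(np)) {
    m <- pieces[[k]]
    idx <- which(mids > bb[k, 1] & mids < bb[k, 3])
    if (!length(idx)) next
    lo <- rep(Inf, length(idx)); hi <- rep(-Inf, length(idx))
    e <- piece_edges(m)
    for (r in seq_len(nrow(e))) {
      x1 <- e[r, 1]; x2 <- e[r, 3]
      if (abs(x2 - x1) < 1e-14) next
      sel <- mids[idx] >= min(x1, x2) - 1e-12 & mids[idx] <= max(x1, x2) + 1e-12
      if (!any(sel)) next
      yy <- e[r, 2] + (mids[idx][sel] - x1) * (e[r, 4] - e[r, 2]) / (x2 - x1)
      lo[sel] <- pmin(lo[sel], yy)
      hi[sel] <- pmax(hi[sel], yy)
    }
    ok <- is.finite(lo) & hi > lo
    g_all[[k]] <- idx[ok]; lo_all[[k]] <- lo[ok]; hi_all[[k]] <- hi[ok]
  }
  g <- unlist(g_all); lo <- unlist(lo_all); hi <- unlist(hi_all)
  if (!length(g)) return(0)
  # group-wise interval union, vectorised: offset each midpoint's intervals
  # into its own disjoint band, then do one global merge
  yr <- range(c(lo, hi))
  big <- (yr[2] - yr[1]) + 1
  base <- (g - 1) * big - yr[1]
  lo2 <- lo + base; hi2 <- hi + base
  o <- order(lo2)
  lo2 <- lo2[o]; hi2 <- hi2[o]; go <- g[o]
  cmax <- cummax(hi2)
  new_run <- c(TRUE, lo2[-1L] > cmax[-length(cmax)] + 1e-12)
  run <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1L] - 1L, length(run))
  run_len <- cmax[ends] - lo2[starts]
  run_g <- go[starts]
  cov <- rep(0, nb)
  agg <- rowsum(run_len, run_g)
  cov[as.integer(rownames(agg))] <- agg[, 1]
  sum(cov * w)
}

#' Point membership in a polygon collection
#'
#' @param ps a `polyset`.
#' @param pts n x 2 matrix of points (meters).
#' @param half_open if `TRUE`, rectangle pieces use half-open membership
#'   `[xmin, xmax) x [ymin, ymax)` so points on shared tile boundaries are
#'   counted once; non-rectangular pieces always use closed membership.
#' @return logical vector of length n.
#' @export
ps_contains <- function(ps, pts, half_open = FALSE) {
  pts <- as.matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  if (ps_is_empty(ps) || nrow(pts) == 0L) return(inside)
  bb <- piece_bboxes(ps$pieces)
  for (k in seq_along(ps$pieces)) {
    cand <- which(!inside & pts[, 1] >= bb[k, 1] - 1e-12 & pts[, 1] <= bb[k, 3] + 1e-12 &
                  pts[, 2] >= bb[k, 2] - 1e-12 & pts[, 2] <= bb[k, 4] + 1e-12)
    if (!length(cand)) next
    if (ps$rect[k] && half_open) {
      ok <- pts[cand, 1] >= bb[k, 1] & pts[cand, 1] < bb[k, 3] &
            pts[cand, 2] >= bb[k, 2] & pts[cand, 2] < bb[k, 4]
    } else {
      m <- ps$pieces[[k]]
      e <- piece_edges(m)
      ok <- rep(TRUE, length(cand))
      for (r in seq_len(nrow(e))) {
        d <- (e[r, 3] - e[r, 1]) * (pts[cand, 2] - e[r, 2]) -
             (e[r, 4] - e[r, 2]) * (pts[cand, 1] - e[r, 1])
        ok <- ok & d >= -1e-9
        if (!any(ok)) break
      }
    }
    inside[cand[ok]] <- TRUE
  }
  inside
}

# Ear-clipping triangulation of a simple (possibly non-convex) polygon,
# returning a list of CCW triangles. Used when loading external polygons
# that are not convex.
triangulate_simple <- function(m) {
  m <- as.matrix(m)
  if (signed_area(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  idx <- seq_len(nrow(m))
  tris <- list()
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    n <- length(idx)
    clipped <- FALSE
    for (k in seq_len(n)) {
      ia <- idx[if (k == 1L) n else k - 1L]; ib <- idx[k]; ic <- idx[if (k == n) 1L else k + 1L]
      a <- m[ia, ]; b <- m[ib, ]; cc <- m[ic, ]
      cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
      if (cr <= 1e-12) next  # reflex or degenerate corner
      tri <- rbind(a, b, cc)
      others <- setdiff(idx, c(ia, ib, ic))
      if (length(others)) {
        inside <- ps_contains(polyset(list(tri)), m[others, , drop = FALSE])
        if (any(inside)) next
      }
      tris[[length(tris) + 1L]] <- tri
      idx <- idx[idx != ib]
      clipped <- TRUE
      break
    }
    if (!clipped) stop("triangulation failed: polygon may be self-intersecting")
  }
  if (length(idx) == 3L) tris[[length(tris) + 1L]] <- m[idx, , drop = FALSE]
  tris
}

# Convert an arbitrary simple polygon ring into convex pieces.
ring_to_pieces <- function(m) {
  m <- as.matrix(m)
  # drop a closing vertex if present
  if (nrow(m) > 1L && all(abs(m[1, ] - m[nrow(m), ]) < 1e-9))
    m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3L) return(list())
  if (is_convex_ring(m)) list(m) else triangulate_simple(m)
}

is_convex_ring <- function(m) {
  n <- nrow(m)
  if (n < 4L) return(TRUE)
  j <- c(2:n, 1L); k <- c(3:n, 1L, 2L)
  cr <- (m[j, 1] - m[, 1]) * (m[k, 2] - m[j, 2]) - (m[j, 2] - m[, 2]) * (m[k, 1] - m[j, 1])
  all(cr >= -1e-9) || all(cr <= 1e-9)
}
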