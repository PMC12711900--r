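# Upstream-scale delineation.
#
# Four spatial scales are attributed to every site: lateral buffer corridors
# following the channel and all tributaries up to 1-, 10-, and 100-km
# along-network distances, and the full upstream contributing area (the union
# of local drainage polygons of all upstream segments). Corridor half-width
# on a segment is 100 m times its Strahler order plus half the predicted
# river width for that order, measured per side from the channel centerline.

#' Default order-to-width lookup table (meters)
#'
#' A monotone stand-in mapping Strahler order to predicted channel width,
#' covering orders 1-11 (small streams to very large rivers). The published
#' order-to-width model this emulates is not reproduced here; supply your own
#' table or function wherever a calibrated model is available.
#'
#' @return named numeric vector, width in meters per order 1..11.
#' @export
default_width_model <- function() {
  c(`1` = 2, `2` = 4, `3` = 8, `4` = 15, `5` = 40, `6` = 80,
    `7` = 150, `8` = 250, `9` = 400, `10` = 600, `11` = 800)
}

#' Predicted river width for a Strahler order
#'
#' @param order positive integer Strahler order(s).
#' @param width_model either a named numeric lookup table (non-decreasing in
#'   order) or a function of order returning meters. Defaults to
#'   [default_width_model()].
#' @return width in meters.
#' @export
predicted_width <- function(order, width_model = default_width_model()) {
  if (any(order < 1) || any(order != round(order))) stop("order must be a positive integer")
  if (is.function(width_model)) return(width_model(order))
  w <- width_model[as.character(order)]
  if (anyNA(w)) stop("width model not defined for order(s): ",
                     paste(order[is.na(w)], collapse = ", "))
  unname(w)
}

#' Lateral buffer half-width for a Strahler order
#'
#' Half-width (per side, from the channel centerline) of the lateral buffer
#' corridor: 100 m times the Strahler order plus half the predicted river
#' width, so the corridor always clears the channel itself.
#'
#' @inheritParams predicted_width
#' @return half-width in meters.
#' @export
buffer_halfwidth <- function(order, width_model = default_width_model()) {
  100 * order + predicted_width(order, width_model) / 2
}

#' Upstream reach within an along-network distance
#'
#' Walks the network upstream from a site, branching into every tributary at
#' confluences, and returns the set of channel portions whose along-channel
#' distance to the site is at most `max_dist_m`. Portions are half-open
#' intervals `(from_m, to_m]`-style measured from the downstream end of each
#' segment.
#'
#' @param network a `river_network`.
#' @param site a [site_position()].
#' @param max_dist_m maximum upstream along-network distance in meters (> 0).
#' @return data.frame of class `reach_set` with columns `segment_id`,
#'   `from_m`, `to_m`.
#' @export
upstream_reach <- function(network, site, max_dist_m) {
  stopifnot(max_dist_m > 0)
  seg <- network$segments
  ups <- upstream_index(network)
  start <- site_segment_index(network, site)
  # frontier entries: segment index, start position (m from downstream end),
  # remaining budget
  res_id <- character(0); res_from <- res_to <- numeric(0)
  frontier <- list(list(i = start, at = site$offset_m, budget = max_dist_m))
  while (length(frontier)) {
    nxt <- list()
    for (fr in frontier) {
      len <- seg$length_m[fr$i]
      to <- min(len, fr$at + fr$budget)
      if (to - fr$at > 1e-9) {
        res_id <- c(res_id, seg$id[fr$i])
        res_from <- c(res_from, fr$at); res_to <- c(res_to, to)
      }
      left <- fr$budget - (len - fr$at)
      if (left > 1e-9) for (u in ups[[fr$i]])
        nxt[[length(nxt) + 1L]] <- list(i = u, at = 0, budget = left)
    }
    frontier <- nxt
  }
  out <- data.frame(segment_id = res_id, from_m = res_from, to_m = res_to,
                    stringsAsFactors = FALSE)
  class(out) <- c("reach_set", "data.frame")
  out
}

#' Scale polygon container
#'
#' @param site_id identifier.
#' @param scale one of `"1km"`, `"10km"`, `"100km"`, `"full"`.
#' @param ps a `polyset` describing the region.
#' @return object of class `scale_polygon` with the precomputed union area.
#' @export
scale_polygon <- function(site_id, scale, ps) {
  area_m2 <- ps_union_area(ps)
  structure(list(site_id = as.character(site_id), scale = scale, ps = ps,
                 area_m2 = area_m2, area_km2 = area_m2 / 1e6),
            class = "scale_polygon")
}

#' @export
print.scale_polygon <- function(x, ...) {
  cat(sprintf("<scale_polygon %s/%s: %.4g km2, %d piece(s)>\n",
              x$site_id, x$scale, x$area_km2, length(x$ps$pieces)))
  invisible(x)
}

#' Buffered corridor polygon for an upstream reach
#'
#' Offsets each reach portion's polyline laterally by the segment's buffer
#' half-width on both sides, with flat (butt) caps at portion ends; outer
#' corners at polyline bends are filled with bevel joins, and overlapping
#' corridors at confluences are merged (no double-counted area).
#'
#' @param network a `river_network` with Strahler orders computed.
#' @param reach a `reach_set` from [upstream_reach()].
#' @param width_model see [predicted_width()].
#' @param site_id,scale labels carried into the result.
#' @return a `scale_polygon`.
#' @export
reach_buffer_polygon <- function(network, reach, width_model = default_width_model(),
                                 site_id = NA_character_, scale = NA_character_) {
  if (nrow(reach) == 0L) stop("empty reach")
  seg <- network$segments
  if (is.null(seg$strahler) || anyNA(seg$strahler))
    stop("Strahler orders missing; run compute_strahler() first")
  pieces <- list()
  for (r in seq_len(nrow(reach))) {
    i <- network$index[[reach$segment_id[r]]]
    if (is.null(i)) stop("unknown segment in reach: ", reach$segment_id[r])
    if (reach$to_m[r] - reach$from_m[r] <= 1e-9) {
      warning("skipping zero-length portion on segment ", reach$segment_id[r])
      next
    }
    h <- buffer_halfwidth(seg$strahler[i], width_model)
    sub <- polyline_sub(seg$polyline[[i]], reach$from_m[r], reach$to_m[r])
    if (is.null(sub) || nrow(sub) < 2L) next
    pieces <- c(pieces, corridor_pieces(sub, h))
  }
  scale_polygon(site_id, scale, polyset(pieces))
}

# rectangles per polyline edge plus bevel triangles at interior bends
corridor_pieces <- function(pl, h) {
  n <- nrow(pl)
  d <- diff(pl)
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-9
  d <- d[ok, , drop = FALSE]; len <- len[ok]
  pl <- pl[c(TRUE, ok), , drop = FALSE]
  n <- nrow(pl)
  if (n < 2L) return(list())
  ux <- d[, 1] / len; uy <- d[, 2] / len
  nx <- -uy; ny <- ux  # left normal
  out <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- pl[k, ]; b <- pl[k + 1L, ]
    off <- c(nx[k], ny[k]) * h
    out[[k]] <- rbind(a + off, a - off, b - off, b + off)
  }
  # bevel joins at interior vertices: fill the outer wedge between the two
  # edge rectangles
  if (n > 2L) for (k in seq_len(n - 2L)) {
    cr <- ux[k] * uy[k + 1L] - uy[k] * ux[k + 1L]
    if (abs(cr) < 1e-12) next
    s <- if (cr > 0) -1 else 1  # outer side: right of a left turn
    v <- pl[k + 1L, ]
    p1 <- v + s * h * c(nx[k], ny[k])
    p2 <- v + s * h * c(nx[k + 1L], ny[k + 1L])
    out[[length(out) + 1L]] <- rbind(v, p1, p2)
  }
  out
}

#' Full upstream contributing area
#'
#' Union of the local drainage polygons of every segment any part of which is
#' upstream of the site, including the site's own segment.
#'
#' @param network a `river_network` built with drainage polygons.
#' @param site a [site_position()].
#' @return a `scale_polygon` with `scale = "full"`.
#' @export
full_upstream_polygon <- function(network, site) {
  if (is.null(network$drainage)) stop("network has no drainage polygons")
  idx <- upstream_segment_indices(network, site)
  ids <- network$segments$id[idx]
  ps <- do.call(ps_bind, network$drainage[ids])
  scale_polygon(site$site_id, "full", ps)
}

#' Polygon area in square kilometers
#'
#' @param x a `polyset` or `scale_polygon`.
#' @param method `"exact"` (planar union area) or `"pixel"` (count of pixel
#'   centers inside the region times the pixel area, emulating raster-derived
#'   catchment sizes).
#' @param pixel_m pixel edge length in meters (default 90).
#' @return area in square kilometers.
#' @export
area_km2 <- function(x, method = c("exact", "pixel"), pixel_m = 90) {
  method <- match.arg(method)
  ps <- if (inherits(x, "scale_polygon")) x$ps else x
  if (!inherits(ps, "polyset")) stop("x must be a polyset or scale_polygon")
  if (ps_is_empty(ps)) return(0)
  if (method == "exact") return(ps_union_area(ps) / 1e6)
  bb <- ps_bbox(ps)
  # pixel centers on a global lattice at (i + 1/2) * pixel_m
  i0 <- floor(bb[1] / pixel_m); i1 <- ceiling(bb[3] / pixel_m)
  j0 <- floor(bb[2] / pixel_m); j1 <- ceiling(bb[4] / pixel_m)
  if (all(ps$rect)) {
    # disjointness-safe closed-form count per rectangle with half-open
    # membership (shared tile edges counted once)
    cnt <- 0
    for (k in seq_along(ps$pieces)) {
      m <- ps$pieces[[k]]
      xr <- range(m[, 1]); yr <- range(m[, 2])
      nx_ <- max(0, ceiling(xr[2] / pixel_m - 0.5) - ceiling(xr[1] / pixel_m - 0.5))
      ny_ <- max(0, ceiling(yr[2] / pixel_m - 0.5) - ceiling(yr[1] / pixel_m - 0.5))
      cnt <- cnt + nx_ * ny_
    }
    # rectangles may overlap in general polysets; fall back if they do
    if (rects_overlap(ps)) cnt <- pixel_count_enum(ps, i0, i1, j0, j1, pixel_m)
  } else {
    cnt <- pixel_count_enum(ps, i0, i1, j0, j1, pixel_m)
  }
  cnt * pixel_m^2 / 1e6
}

rects_overlap <- function(ps) {
  bb <- piece_bboxes(ps$pieces)
  n <- nrow(bb)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    if (any(bb[j, 1] < bb[i, 3] - 1e-9 & bb[j, 3] > bb[i, 1] + 1e-9 &
            bb[j, 2] < bb[i, 4] - 1e-9 & bb[j, 4] > bb[i, 2] + 1e-9))
      return(TRUE)
  }
  FALSE
}

pixel_count_enum <- function(ps, i0, i1, j0, j1, pixel_m) {
  xs <- (seq(i0, i1) + 0.5) * pixel_m
  ys <- (seq(j0, j1) + 0.5) * pixel_m
  # enumerate in x-strips to bound memory
  cnt <- 0
  step <- max(1L, floor(2e6 / length(ys)))
  for (s in seq(1L, length(xs), by = step)) {
    xx <- xs[s:min(length(xs), s + step - 1L)]
    pts <- cbind(rep(xx, each = length(ys)), rep(ys, times = length(xx)))
    cnt <- cnt + sum(ps_contains(ps, pts, half_open = TRUE))
  }
  cnt
}

#' Delineate all four upstream scales for a site
#'
#' @param network a `river_network` with Strahler orders and drainage
#'   polygons.
#' @param site a [site_position()].
#' @param scales subset of `c("1km", "10km", "100km", "full")`.
#' @param width_model see [predicted_width()].
#' @return named list of `scale_polygon` objects.
#' @export
upstream_scales <- function(network, site,
                            scales = c("1km", "10km", "100km", "full"),
                            width_model = default_width_model()) {
  dists <- c(`1km` = 1e3, `10km` = 1e4, `100km` = 1e5)
  out <- list()
  for (sc in scales) {
    out[[sc]] <- if (sc == "full") {
      full_upstream_polygon(network, site)
    } else {
      reach <- upstream_reach(network, site, dists[[sc]])
      reach_buffer_polygon(network, reach, width_model,
                           site_id = site$site_id, scale = sc)
    }
  }
  out
}
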