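# River network representation.
#
# A network is a forest of channel segments: each segment drains into at most
# one downstream segment (tributaries attach at the upstream end of their
# downstream segment, as in raster-derived hydrographies where segments break
# at confluences). Segment polylines are stored downstream-end first, so
# along-channel positions in meters are measured from the downstream end.

#' River network
#'
#' Assembles and validates a river network from a segment table. Validation
#' enforces the forest structure (no cycles, every segment drains to exactly
#' one outlet), positive lengths, and agreement between each polyline's
#' length and the declared `length_m` (relative tolerance 1e-6).
#'
#' @param segments data.frame with columns `id` (character), `downstream_id`
#'   (character or `NA` for outlets), `length_m` (> 0), optionally `strahler`,
#'   and a list-column `polyline` of n x 2 vertex matrices ordered from the
#'   downstream end to the upstream end.
#' @param drainage named list of `polyset` objects keyed by segment id: the
#'   local contributing area of each segment. Drainage regions of distinct
#'   segments must not overlap. Optional (required only for full-catchment
#'   delineation).
#' @return an object of class `river_network`.
#' @export
river_network <- function(segments, drainage = NULL) {
  segments <- as.data.frame(segments)
  req <- c("id", "downstream_id", "length_m", "polyline")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segments is missing column(s): ", paste(miss, collapse = ", "))
  segments$id <- as.character(segments$id)
  segments$downstream_id <- as.character(segments$downstream_id)
  if (anyDuplicated(segments$id)) stop("duplicate segment ids")
  if (any(segments$length_m <= 0)) stop("segment lengths must be positive")
  known <- segments$downstream_id %in% segments$id | is.na(segments$downstream_id)
  if (!all(known))
    stop("unknown downstream_id for segment(s): ",
         paste(segments$id[!known], collapse = ", "))
  # polyline lengths must match length_m
  for (i in seq_len(nrow(segments))) {
    pl <- segments$polyline[[i]]
    if (is.null(pl) || nrow(pl) < 2L) stop("segment ", segments$id[i], " has no polyline")
    len <- sum(sqrt(rowSums(diff(pl)^2)))
    if (abs(len - segments$length_m[i]) > 1e-6 * max(1, segments$length_m[i]))
      stop("polyline length of segment ", segments$id[i],
           " disagrees with length_m (", format(len), " vs ",
           format(segments$length_m[i]), ")")
  }
  net <- structure(
    list(segments = segments, drainage = drainage,
         index = stats::setNames(seq_len(nrow(segments)), segments$id)),
    class = "river_network")
  check_forest(net)
  if (!is.null(drainage)) {
    extra <- setdiff(segments$id, names(drainage))
    if (length(extra)) stop("drainage polygons missing for segment(s): ",
                            paste(utils::head(extra, 5), collapse = ", "))
  }
  net
}

#' @export
print.river_network <- function(x, ...) {
  no <- sum(is.na(x$segments$downstream_id))
  cat(sprintf("<river_network: %d segments, %d outlet(s)%s%s>\n",
              nrow(x$segments), no,
              if (!is.null(x$segments$strahler) && !anyNA(x$segments$strahler))
                sprintf(", max Strahler order %d", max(x$segments$strahler)) else "",
              if (is.null(x$drainage)) "" else ", with drainage polygons"))
  invisible(x)
}

# cycle / forest check: walk every downstream chain
check_forest <- function(net) {
  seg <- net$segments
  n <- nrow(seg)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  down <- match(seg$downstream_id, seg$id)
  for (s in seq_len(n)) {
    if (state[s] == 2L) next
    chain <- integer(0)
    cur <- s
    while (!is.na(cur)) {
      if (state[cur] == 1L)
        stop("cycle detected in downstream chain: ",
             paste(seg$id[c(chain, cur)], collapse = " -> "))
      if (state[cur] == 2L) break
      state[cur] <- 1L
      chain <- c(chain, cur)
      cur <- down[cur]
    }
    state[chain] <- 2L
  }
  invisible(TRUE)
}

# list of upstream neighbour indices per segment index
upstream_index <- function(net) {
  seg <- net$segments
  down <- match(seg$downstream_id, seg$id)
  ups <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) if (!is.na(down[i]))
    ups[[down[i]]] <- c(ups[[down[i]]], i)
  ups
}

#' Strahler stream orders
#'
#' Assigns Strahler orders to every segment: headwaters are order 1; at a
#' confluence the downstream order is the maximum of the inflow orders,
#' incremented by one when two or more inflows share that maximum.
#'
#' @param network a `river_network`.
#' @return the network with the `strahler` column filled in.
#' @export
compute_strahler <- function(network) {
  seg <- network$segments
  ups <- upstream_index(network)
  n <- nrow(seg)
  order_out <- rep(NA_integer_, n)
  indeg <- lengths(ups)
  queue <- which(indeg == 0L)
  order_out[queue] <- 1L
  down <- match(seg$downstream_id, seg$id)
  remaining <- indeg
  while (length(queue)) {
    nxt <- integer(0)
    for (i in queue) {
      d <- down[i]
      if (is.na(d)) next
      remaining[d] <- remaining[d] - 1L
      if (remaining[d] == 0L) {
        ords <- order_out[ups[[d]]]
        mx <- max(ords)
        order_out[d] <- if (sum(ords == mx) >= 2L) mx + 1L else mx
        nxt <- c(nxt, d)
      }
    }
    queue <- nxt
  }
  if (anyNA(order_out)) stop("could not order all segments (disconnected cycle?)")
  network$segments$strahler <- order_out
  network
}

#' Site position on a network
#'
#' @param site_id identifier.
#' @param segment_id id of the segment the site sits on.
#' @param offset_m distance in meters from the downstream end of the segment.
#' @return an object of class `site_position`.
#' @export
site_position <- function(site_id, segment_id, offset_m) {
  stopifnot(offset_m >= 0)
  structure(list(site_id = as.character(site_id),
                 segment_id = as.character(segment_id),
                 offset_m = as.numeric(offset_m)),
            class = "site_position")
}

site_segment_index <- function(network, site) {
  i <- network$index[[site$segment_id]]
  if (is.null(i)) stop("site ", site$site_id, ": unknown segment ", site$segment_id)
  if (site$offset_m > network$segments$length_m[i] + 1e-9)
    stop("site ", site$site_id, ": offset exceeds segment length")
  i
}

# indices of all segments any part of which lies upstream of the site
# (including the site's own segment)
upstream_segment_indices <- function(network, site) {
  ups <- upstream_index(network)
  start <- site_segment_index(network, site)
  out <- integer(0)
  queue <- start
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(ups[queue])
  }
  out
}

# point on a polyline at along-length position s (from first vertex)
polyline_point <- function(pl, s) {
  d <- sqrt(rowSums(diff(pl)^2))
  cs <- c(0, cumsum(d))
  s <- min(max(s, 0), cs[length(cs)])
  k <- findInterval(s, cs, rightmost.closed = TRUE)
  k <- min(k, length(d))
  f <- if (d[k] > 0) (s - cs[k]) / d[k] else 0
  pl[k, ] + f * (pl[k + 1L, ] - pl[k, ])
}

# sub-polyline between along-length positions a < b
polyline_sub <- function(pl, a, b) {
  d <- sqrt(rowSums(diff(pl)^2))
  cs <- c(0, cumsum(d))
  tot <- cs[length(cs)]
  a <- max(a, 0); b <- min(b, tot)
  if (b - a <= 1e-9) return(NULL)
  inner <- which(cs > a + 1e-9 & cs < b - 1e-9)
  pts <- rbind(polyline_point(pl, a),
               pl[inner, , drop = FALSE],
               polyline_point(pl, b))
  pts[c(TRUE, rowSums(abs(diff(pts))) > 1e-9), , drop = FALSE]
}
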