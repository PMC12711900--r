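# Independent oracles used to verify the package's algorithms. Every oracle
# here takes a deliberately different computational route from the
# implementation it checks: recursive descent instead of topological sweeps,
# full covariance matrices instead of Markov whitening, rasterization
# instead of exact sweeps, and the literal step-up definition instead of the
# library call.

# --- Strahler: plain recursion over the tree ---------------------------------
strahler_oracle <- function(net) {
  seg <- net$segments
  ups <- lapply(seg$id, function(id) which(seg$downstream_id == id))
  rec <- function(i) {
    if (!length(ups[[i]])) return(1L)
    ords <- vapply(ups[[i]], rec, integer(1))
    mx <- max(ords)
    if (sum(ords == mx) >= 2L) mx + 1L else mx
  }
  vapply(seq_len(nrow(seg)), rec, integer(1))
}

# --- upstream reach: per-segment distance walk (downward) --------------------
# For every segment, walk DOWN to the site accumulating distance to the
# segment's downstream end, then clip the segment to the remaining budget.
reach_oracle <- function(net, site, maxd) {
  seg <- net$segments
  idx <- stats::setNames(seq_len(nrow(seg)), seg$id)
  start <- idx[[site$segment_id]]
  down <- match(seg$downstream_id, seg$id)
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    # distance from the downstream end of segment i up-channel to the site
    d0 <- 0; reached <- i == start
    if (!reached) {
      cur <- down[i]
      while (!is.na(cur)) {
        if (cur == start) {
          d0 <- d0 + (seg$length_m[start] - site$offset_m)
          reached <- TRUE
          break
        }
        d0 <- d0 + seg$length_m[cur]
        cur <- down[cur]
      }
    }
    if (!reached) next
    if (i == start) {
      from <- site$offset_m
      to <- min(seg$length_m[i], site$offset_m + maxd)
    } else {
      # entering the downstream end of i costs d0; budget left maxd - d0
      if (d0 >= maxd) next
      from <- 0
      to <- min(seg$length_m[i], maxd - d0)
    }
    if (to - from > 1e-9)
      rows[[length(rows) + 1L]] <- data.frame(segment_id = seg$id[i],
                                              from_m = from, to_m = to)
  }
  out <- do.call(rbind, rows)
  out[order(out$segment_id), ]
}

# --- corridor area: rasterized distance-to-centerline ------------------------
# A point is in the corridor of a portion when it lies within h of an edge
# band (perpendicular projection inside the edge) or within h of an interior
# polyline vertex (the bevel-join disk, here exact). Flat caps at the ends.
corridor_raster_oracle <- function(net, reach, width_model, cell = 2) {
  seg <- net$segments
  idx <- stats::setNames(seq_len(nrow(seg)), seg$id)
  parts <- list()
  for (r in seq_len(nrow(reach))) {
    i <- idx[[reach$segment_id[r]]]
    h <- buffer_halfwidth(seg$strahler[i], width_model)
    sub <- riverpa:::polyline_sub(seg$polyline[[i]], reach$from_m[r], reach$to_m[r])
    parts[[r]] <- list(pl = sub, h = h)
  }
  allp <- do.call(rbind, lapply(parts, function(p) p$pl))
  hmax <- max(vapply(parts, function(p) p$h, 0))
  xr <- range(allp[, 1]) + c(-1, 1) * (hmax + cell)
  yr <- range(allp[, 2]) + c(-1, 1) * (hmax + cell)
  xs <- seq(xr[1], xr[2], by = cell)
  ys <- seq(yr[1], yr[2], by = cell)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  covered <- rep(FALSE, nrow(pts))
  for (p in parts) {
    pl <- p$pl; h <- p$h
    ne <- nrow(pl) - 1L
    for (e in seq_len(ne)) {
      a <- pl[e, ]; b <- pl[e + 1L, ]
      ab <- b - a; L2 <- sum(ab^2)
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / L2
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
      covered <- covered | (t >= 0 & t <= 1 & d2 <= h^2)
    }
    if (nrow(pl) > 2L) for (v in 2:(nrow(pl) - 1L)) {
      d2 <- (pts[, 1] - pl[v, 1])^2 + (pts[, 2] - pl[v, 2])^2
      covered <- covered | d2 <= h^2
    }
  }
  sum(covered) * cell^2
}

# --- percent cover: rasterized intersection ----------------------------------
percent_cover_raster_oracle <- function(scale_poly, pa_ps, cell = 5) {
  bb <- riverpa:::ps_bbox(scale_poly$ps)
  xs <- seq(bb[1] + cell / 2, bb[3], by = cell)
  ys <- seq(bb[2] + cell / 2, bb[4], by = cell)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  in_scale <- ps_contains(scale_poly$ps, pts)
  if (!any(in_scale)) return(0)
  in_pa <- ps_contains(pa_ps, pts[in_scale, , drop = FALSE])
  100 * sum(in_pa) / sum(in_scale)
}

# --- AR(1)-GLS profile likelihood: full-matrix route -------------------------
gls_full_matrix_loglik <- function(phi, years, y, method = "REML") {
  o <- order(years)
  t_ <- years[o]; y <- y[o]
  n <- length(y)
  X <- cbind(1, t_)
  p <- ncol(X)
  R <- phi^abs(outer(t_, t_, "-"))
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Ri %*% r)
  ldR <- determinant(R, logarithm = TRUE)$modulus[1]
  if (method == "REML") {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + ldR +
            determinant(XtRiX, logarithm = TRUE)$modulus[1] + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi) + n * log(s2) + ldR + n)
  }
}

# simulate an AR(1)-residual linear series at irregular integer years
ar1_series <- function(years, intercept, slope, phi, sd) {
  n <- length(years)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n) {
    r <- phi^(years[i] - years[i - 1])
    e[i] <- r * e[i - 1] + rnorm(1, 0, sd * sqrt(1 - r^2))
  }
  intercept + slope * years + e
}

sample_years <- function(n = 14, span = 20, start = 1990) {
  sort(c(start, start + span, sample(seq_len(span - 1), n - 2) + start))
}

# --- Benjamini-Hochberg: literal step-up definition --------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# --- tiny hand-built networks ------------------------------------------------
# straight vertical segments; a chain or a Y; drainage = unit tiles beside
# each segment
make_chain_net <- function(lengths = c(1000, 1000, 1000), drainage = TRUE) {
  n <- length(lengths)
  y0 <- c(0, cumsum(lengths))[1:n]
  down <- if (n > 1L) c(NA, paste0("s", seq_len(n - 1L))) else NA_character_
  seg <- data.frame(id = paste0("s", seq_len(n)),
                    downstream_id = down,
                    length_m = lengths, stringsAsFactors = FALSE)
  seg$polyline <- lapply(seq_len(n), function(i)
    rbind(c(0, y0[i]), c(0, y0[i] + lengths[i])))
  dr <- NULL
  if (drainage) {
    dr <- lapply(seq_len(n), function(i)
      polyset(list(rect_piece(100, y0[i], 600, y0[i] + lengths[i]))))
    names(dr) <- seg$id
  }
  compute_strahler(river_network(seg, dr))
}

# outlet s1 from (0,0) up to (0, len1); two headwaters joining at its top
make_y_net <- function(len1 = 1000, len2 = 600, len3 = 600) {
  a <- len2 / sqrt(2); b <- len3 / sqrt(2)
  seg <- data.frame(id = c("s1", "s2", "s3"),
                    downstream_id = c(NA, "s1", "s1"),
                    length_m = c(len1, len2, len3), stringsAsFactors = FALSE)
  seg$polyline <- list(rbind(c(0, 0), c(0, len1)),
                       rbind(c(0, len1), c(-a, len1 + a)),
                       rbind(c(0, len1), c(b, len1 + b)))
  compute_strahler(river_network(seg))
}

# balanced binary-merge tree with 2^k headwaters (for the Strahler closed form)
make_balanced_net <- function(k) {
  rows <- list()
  build <- function(x, y, depth, downstream_id) {
    id <- paste0("b", length(rows) + 1L)
    len <- 100
    rows[[length(rows) + 1L]] <<- list(id = id, downstream_id = downstream_id,
                                       length_m = len,
                                       polyline = rbind(c(x, y), c(x, y + len)))
    if (depth > 0L) {
      build(x - 2^depth, y + len, depth - 1L, id)
      build(x + 2^depth, y + len, depth - 1L, id)
    }
  }
  build(0, 0, k - 1L, NA_character_)
  seg <- data.frame(id = vapply(rows, `[[`, "", "id"),
                    downstream_id = vapply(rows, `[[`, "", "downstream_id"),
                    length_m = vapply(rows, `[[`, 0, "length_m"),
                    stringsAsFactors = FALSE)
  # polylines are vertical; lengths are straight-line so length_m matches
  seg$polyline <- lapply(rows, `[[`, "polyline")
  compute_strahler(river_network(seg))
}

# --- shared mid-size synthetic study (built once per test run) ---------------
shared_env <- new.env()
get_shared_study <- function() {
  if (is.null(shared_env$study)) {
    shared_env$study <- suppressWarnings(
      gen_study(generator_config(seed = 42, n_headwaters = 16, n_sites = 80,
                                 n_pas = 25)))
  }
  shared_env$study
}

random_net <- function(seed, n_headwaters = NULL) {
  if (is.null(n_headwaters)) n_headwaters <- sample(3:40, 1)
  suppressWarnings(gen_network(generator_config(seed = seed,
                                                n_headwaters = n_headwaters)))
}
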