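# Synthetic study generator.
#
# Generates complete studies with known ground truth: a planar river network
# (random binary-merge tree embedded without self-intersection), gridded
# local drainage areas, rectangular protected areas with establishment
# years, monitoring sites with provider assignments, and community time
# series whose true log-scale trends follow the effect structure the
# analysis estimates: a per-metric baseline plus a PA effect proportional to
# the square root of upstream cover, attenuated linearly with initial
# ecological quality (full strength at initial EQR <= 0.2, zero at >= 0.8),
# with AR(1) residuals and provider trend offsets. All randomness descends
# from one seed; each site has its own sub-stream so series can be
# regenerated independently of the geometry.

#' Generator configuration
#'
#' Defaults describe a realistic mid-size monitoring study: segment lengths
#' log-uniform on 0.8-6 km, series spanning 10-36 years with at least 7
#' sampling years (targeting means near 20 years' duration and 14 sampling
#' years), non-negative cover gain rates capped at 9 percent per year, and
#' trend effects on the log scale so that the configured percent-per-year
#' numbers are exactly what [slope_to_pct()] recovers.
#'
#' @param seed integer seed; identical configurations generate identical
#'   studies.
#' @param n_headwaters number of order-1 source segments (the network has
#'   `2 * n_headwaters - 1` segments).
#' @param n_sites number of monitoring sites.
#' @param n_providers number of data providers (regional blocks of sites).
#' @param year_range first and last calendar year of the study window.
#' @param seg_length_range segment length range in meters (log-uniform).
#' @param drain_cell_m drainage grid cell size (m).
#' @param drain_reach_m maximum lateral distance of drainage cells from the
#'   channel (m).
#' @param n_pas number of protected areas.
#' @param pa_frac_pre fraction of PAs established before the study window.
#' @param pa_size_meanlog,pa_size_sdlog lognormal parameters of PA rectangle
#'   side lengths (m).
#' @param max_gain_rate cap on realized per-site cover gain rates (percent
#'   per year).
#' @param baseline_pct named per-metric baseline trend (percent per year).
#' @param effect_pct named per-metric additional trend at 100 percent cover
#'   and low initial EQR (percent per year).
#' @param eqr0_low,eqr0_high initial-EQR range over which the PA effect
#'   attenuates from full strength to zero.
#' @param driving_scale upstream scale whose cover drives the true effect.
#' @param provider_sd_pct SD of provider trend offsets (percent per year).
#' @param site_sd_pct SD of site-level trend heterogeneity (percent per
#'   year).
#' @param phi AR(1) parameter of the residuals.
#' @param noise_sd named per-metric innovation SD on the log scale.
#' @param span_mean,span_sd target distribution of series duration (years).
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_headwaters = 24L,
                             n_sites = 150L,
                             n_providers = 6L,
                             year_range = c(1986L, 2022L),
                             seg_length_range = c(800, 6000),
                             drain_cell_m = 600,
                             drain_reach_m = 2500,
                             n_pas = 35L,
                             pa_frac_pre = 0.5,
                             pa_size_meanlog = log(1000),
                             pa_size_sdlog = 0.6,
                             max_gain_rate = 9,
                             baseline_pct = c(abundance = 0.5, richness = 1, eqr = 1.5),
                             effect_pct = c(abundance = 0, richness = 5.2, eqr = 5.2),
                             eqr0_low = 0.2, eqr0_high = 0.8,
                             driving_scale = "full",
                             provider_sd_pct = 0.5,
                             site_sd_pct = 0.3,
                             phi = 0.3,
                             noise_sd = c(abundance = 0.35, richness = 0.18, eqr = 0.12),
                             span_mean = 20, span_sd = 5.5) {
  stopifnot(n_headwaters >= 1L, max_gain_rate >= 0, phi > -1, phi < 1,
            year_range[2] > year_range[1])
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

seed_for <- function(seed, stream, i = 0L) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919 + i * 104729) %% 2147483399 + 1)
}

#' Generate a random river network
#'
#' Random binary-merge tree embedded in the plane without self-intersection
#' (bounded retries), with gently bending three-vertex polylines, log-uniform
#' segment lengths, Strahler orders, and gridded drainage polygons assigned
#' to the nearest segment (pairwise disjoint by construction).
#'
#' @param config a [generator_config()].
#' @param reseed seed the RNG from `config$seed` (set `FALSE` when called
#'   from [gen_study()], which manages the stream).
#' @return a `river_network` with Strahler orders and drainage polygons.
#' @export
gen_network <- function(config, reseed = TRUE) {
  if (reseed) set.seed(seed_for(config$seed, 1L))
  for (try_ in 1:25) {
    net <- try(gen_network_once(config), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
  stop("network embedding failed after bounded retries: ",
       attr(net, "condition")$message)
}

gen_network_once <- function(config) {
  lr <- log(config$seg_length_range)
  rows <- list()
  # each subtree draws within its own angular wedge (split proportionally to
  # leaf counts at confluences), which keeps sibling branches apart
  new_seg <- function(x, y, wlo, whi, n_leaves, downstream_id) {
    id <- sprintf("seg%03d", length(rows) + 1L)
    L <- exp(stats::runif(1, lr[1], lr[2]))
    mid <- (wlo + whi) / 2
    jit <- (whi - wlo) / 6
    a1 <- mid + stats::runif(1, -jit, jit)
    a2 <- mid + stats::runif(1, -jit, jit)
    p0 <- c(x, y)
    p1 <- p0 + L / 2 * c(cos(a1), sin(a1))
    p2 <- p1 + L / 2 * c(cos(a2), sin(a2))
    rows[[length(rows) + 1L]] <<- list(id = id, downstream_id = downstream_id,
                                       length_m = L, polyline = rbind(p0, p1, p2))
    if (n_leaves > 1L) {
      nl <- sample.int(n_leaves - 1L, 1L)
      cut_ <- wlo + (whi - wlo) * (n_leaves - nl) / n_leaves
      new_seg(p2[1], p2[2], cut_, whi, nl, id)
      new_seg(p2[1], p2[2], wlo, cut_, n_leaves - nl, id)
    }
    invisible(id)
  }
  new_seg(0, 0, pi / 2 - 1.1, pi / 2 + 1.1, config$n_headwaters, NA_character_)
  seg <- data.frame(id = vapply(rows, `[[`, "", "id"),
                    downstream_id = vapply(rows, `[[`, "", "downstream_id"),
                    length_m = vapply(rows, `[[`, 0, "length_m"),
                    stringsAsFactors = FALSE)
  seg$polyline <- lapply(rows, `[[`, "polyline")
  check_no_self_intersection(seg)
  net <- river_network(seg, drainage = gen_drainage(seg, config))
  compute_strahler(net)
}

check_no_self_intersection <- function(seg) {
  ed <- do.call(rbind, lapply(seg$polyline, piece_open_edges))
  n <- nrow(ed)
  i <- rep(seq_len(n), each = n); j <- rep(seq_len(n), times = n)
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  p1x <- ed[i, 1]; p1y <- ed[i, 2]; d1x <- ed[i, 3] - p1x; d1y <- ed[i, 4] - p1y
  q1x <- ed[j, 1]; q1y <- ed[j, 2]; d2x <- ed[j, 3] - q1x; d2y <- ed[j, 4] - q1y
  den <- d1x * d2y - d1y * d2x
  rx <- q1x - p1x; ry <- q1y - p1y
  t <- (rx * d2y - ry * d2x) / den
  u <- (rx * d1y - ry * d1x) / den
  eps <- 1e-9
  bad <- abs(den) > 1e-12 & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  if (any(bad)) stop("self-intersecting embedding")
  invisible(TRUE)
}

piece_open_edges <- function(pl) {
  n <- nrow(pl)
  cbind(pl[-n, 1], pl[-n, 2], pl[-1, 1], pl[-1, 2])
}

gen_drainage <- function(seg, config) {
  g <- config$drain_cell_m
  mids <- t(vapply(seg$polyline, function(pl) polyline_point(pl, sum(sqrt(rowSums(diff(pl)^2))) / 2),
                   numeric(2)))
  allv <- do.call(rbind, seg$polyline)
  pad <- config$drain_reach_m + g
  ix <- seq(floor((min(allv[, 1]) - pad) / g), ceiling((max(allv[, 1]) + pad) / g))
  iy <- seq(floor((min(allv[, 2]) - pad) / g), ceiling((max(allv[, 2]) + pad) / g))
  cx <- (ix + 0.5) * g; cy <- (iy + 0.5) * g
  centers <- cbind(rep(cx, times = length(cy)), rep(cy, each = length(cx)))
  d2 <- outer(centers[, 1], mids[, 1], "-")^2 + outer(centers[, 2], mids[, 2], "-")^2
  nearest <- max.col(-d2)
  near_ok <- d2[cbind(seq_len(nrow(centers)), nearest)] <= config$drain_reach_m^2
  assign <- ifelse(near_ok, nearest, NA_integer_)
  # guarantee every segment at least the cell containing its own midpoint
  for (s in seq_len(nrow(seg))) {
    if (any(assign == s, na.rm = TRUE)) next
    cell <- which.min(d2[, s])
    assign[cell] <- s
  }
  drainage <- vector("list", nrow(seg))
  names(drainage) <- seg$id
  for (s in seq_len(nrow(seg))) {
    cells <- which(assign == s)
    drainage[[s]] <- polyset(lapply(cells, function(ci) {
      rect_piece(centers[ci, 1] - g / 2, centers[ci, 2] - g / 2,
                 centers[ci, 1] + g / 2, centers[ci, 2] + g / 2)
    }))
  }
  drainage
}

#' Generate protected areas over a network
#'
#' Axis-aligned rectangles centered near random channel locations with
#' lognormal side lengths; establishment years fall before the study window
#' with probability `pa_frac_pre` and uniformly inside it otherwise. The
#' gain-rate cap is enforced at study level (see [gen_study()]), which may
#' shrink within-window PAs.
#'
#' @inheritParams gen_network
#' @param network a `river_network`.
#' @return a [pa_set()].
#' @export
gen_protected_areas <- function(network, config, reseed = TRUE) {
  if (reseed) set.seed(seed_for(config$seed, 2L))
  n <- config$n_pas
  if (n == 0L) return(pa_set(character(0), list(), integer(0)))
  seg <- network$segments
  # PAs cluster spatially (remote, low-order branches), leaving other
  # branches unprotected
  n_anchor <- max(3L, ceiling(n / 6))
  anchors <- sample.int(nrow(seg), min(n_anchor, nrow(seg)),
                        prob = 1 / seg$strahler^2)
  pick <- sample(anchors, n, replace = TRUE)
  ctr <- t(vapply(seq_len(n), function(k) {
    pl <- seg$polyline[[pick[k]]]
    polyline_point(pl, stats::runif(1, 0, seg$length_m[pick[k]])) +
      stats::rnorm(2, 0, 1200)
  }, numeric(2)))
  w <- pmin(pmax(stats::rlnorm(n, config$pa_size_meanlog, config$pa_size_sdlog), 200), 9000)
  h <- pmin(pmax(stats::rlnorm(n, config$pa_size_meanlog, config$pa_size_sdlog), 200), 9000)
  pre <- stats::runif(n) < config$pa_frac_pre
  yr <- integer(n)
  yr[pre] <- config$year_range[1] - sample.int(40L, sum(pre), replace = TRUE)
  yr[!pre] <- config$year_range[1] +
    sample.int(max(1L, diff(config$year_range) - 2L), sum(!pre), replace = TRUE)
  polys <- lapply(seq_len(n), function(k) {
    rect_piece(ctr[k, 1] - w[k] / 2, ctr[k, 2] - h[k] / 2,
               ctr[k, 1] + w[k] / 2, ctr[k, 2] + h[k] / 2)
  })
  pa_set(sprintf("pa%03d", seq_len(n)), polys, yr)
}

gen_sites <- function(network, config) {
  seg <- network$segments
  n <- config$n_sites
  if (n == 0L) {
    return(data.frame(site_id = character(0), segment_id = character(0),
                      offset_m = numeric(0), x = numeric(0), y = numeric(0),
                      latitude = numeric(0), longitude = numeric(0),
                      provider = character(0), stringsAsFactors = FALSE))
  }
  # monitoring networks oversample mid-size and larger rivers
  pick <- sample.int(nrow(seg), n, replace = TRUE,
                     prob = seg$length_m * seg$strahler^2)
  off <- stats::runif(n, 0, seg$length_m[pick])
  xy <- t(vapply(seq_len(n), function(k)
    polyline_point(seg$polyline[[pick[k]]], off[k]), numeric(2)))
  # regional providers: contiguous blocks along the x axis
  prov <- paste0("prov", as.integer(cut(rank(xy[, 1], ties.method = "first"),
                                        breaks = config$n_providers, labels = FALSE)))
  data.frame(site_id = sprintf("site%04d", seq_len(n)),
             segment_id = seg$id[pick], offset_m = off,
             x = xy[, 1], y = xy[, 2],
             latitude = 48 + xy[, 2] / 111320,
             longitude = 8 + xy[, 1] / (111320 * cos(48 * pi / 180)),
             provider = prov, stringsAsFactors = FALSE)
}

gen_sampling_years <- function(config, site_seed) {
  set.seed(site_seed)
  span <- round(stats::rnorm(1, config$span_mean, config$span_sd))
  span <- min(max(span, 10L), diff(config$year_range) - 1L)
  first <- sample.int(diff(config$year_range) - span + 1L, 1L) + config$year_range[1] - 1L
  n_yr <- min(max(7L, round(0.7 * (span + 1L))), span + 1L)
  inner <- sort(sample(seq_len(span - 1L), n_yr - 2L)) + first
  sort(c(first, inner, first + span))
}

#' Generate one site's community time series with ground truth
#'
#' True per-metric log-slope = baseline + effect * sqrt(cover proportion) *
#' w(initial EQR), where w falls linearly from 1 at `eqr0_low` to 0 at
#' `eqr0_high`; residuals are AR(1) at calendar-year gaps; abundance and
#' richness are exponentiated and rounded to counts, EQR stays positive by
#' construction.
#'
#' @param site one row of the site table (needs `site_id`, `provider`).
#' @param cover_prop cover proportion in [0, 1] at the driving scale.
#' @param years sampled calendar years.
#' @param provider_offset provider trend offset (log units per year).
#' @param config a [generator_config()].
#' @param site_seed integer sub-stream seed for this site.
#' @return list with `series` (data.frame rows) and `truth` (one-row
#'   data.frame of realized true parameters).
#' @export
gen_time_series <- function(site, cover_prop, years, provider_offset, config,
                            site_seed) {
  set.seed(site_seed)
  eqr0 <- 0.15 + 0.8 * stats::rbeta(1, 2, 2)
  w <- min(max((config$eqr0_high - eqr0) / (config$eqr0_high - config$eqr0_low), 0), 1)
  site_off <- stats::rnorm(1, 0, log1p(config$site_sd_pct / 100))
  lev0 <- c(abundance = stats::rnorm(1, log(500), 0.8),
            richness = stats::rnorm(1, log(25), 0.4),
            eqr = log(eqr0))
  n <- length(years)
  t_rel <- years - years[1]
  vals <- list()
  truth <- data.frame(site_id = site$site_id, eqr0_true = eqr0,
                      cover_prop = cover_prop, weight = w,
                      provider_offset = provider_offset, site_offset = site_off,
                      stringsAsFactors = FALSE)
  for (m in c("abundance", "richness", "eqr")) {
    slope <- log1p(config$baseline_pct[[m]] / 100) +
      log1p(config$effect_pct[[m]] / 100) * sqrt(cover_prop) * w +
      provider_offset + site_off
    sdm <- config$noise_sd[[m]]
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, sdm)
    if (n > 1) for (i in 2:n) {
      d <- t_rel[i] - t_rel[i - 1]
      r <- config$phi^d
      e[i] <- r * e[i - 1] + stats::rnorm(1, 0, sdm * sqrt(1 - r^2))
    }
    y <- lev0[[m]] + slope * t_rel + e
    vals[[m]] <- if (m == "eqr") exp(y) else round(exp(y))
    truth[[paste0("slope_", m)]] <- slope
    truth[[paste0("pct_", m)]] <- slope_to_pct(slope)
  }
  list(series = data.frame(site_id = site$site_id, year = years,
                           abundance = vals$abundance, richness = vals$richness,
                           eqr = vals$eqr, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate a complete synthetic study
#'
#' Composes network, protected areas, sites, upstream-scale polygons, lagged
#' cover records (with the gain-rate cap enforced by shrinking within-window
#' PAs in bounded rounds), and community time series with ground truth.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_study`: list with `network`, `pas`,
#'   `sites`, `scale_polys`, `cover`, `series`, `truth`, `config`.
#' @export
gen_study <- function(config) {
  set.seed(seed_for(config$seed, 1L))
  network <- gen_network(config, reseed = FALSE)
  set.seed(seed_for(config$seed, 2L))
  pas <- gen_protected_areas(network, config, reseed = FALSE)
  set.seed(seed_for(config$seed, 3L))
  sites <- gen_sites(network, config)
  # sampling years (needed before cover: cover years are lagged to the series)
  years_by_site <- lapply(seq_len(nrow(sites)), function(i)
    gen_sampling_years(config, seed_for(config$seed, 4L, i)))
  names(years_by_site) <- sites$site_id
  scale_polys <- list()
  for (i in seq_len(nrow(sites))) {
    sp <- site_position(sites$site_id[i], sites$segment_id[i], sites$offset_m[i])
    scale_polys[[sites$site_id[i]]] <- upstream_scales(network, sp)
  }
  series_range <- data.frame(
    site_id = sites$site_id,
    first_year = vapply(years_by_site, min, 0)[sites$site_id],
    last_year = vapply(years_by_site, max, 0)[sites$site_id],
    stringsAsFactors = FALSE)
  cover <- if (nrow(sites)) cover_table(scale_polys, pas, series_range) else NULL
  # calibrate: realized gain rates must respect the cap
  shrink <- 0
  while (!is.null(cover) && any(cover$gain_rate > config$max_gain_rate) &&
         shrink < 20) {
    shrink <- shrink + 1
    pas <- shrink_recent_pas(pas, config, factor = 0.8)
    cover <- cover_table(scale_polys, pas, series_range)
  }
  if (!is.null(cover) && any(cover$gain_rate > config$max_gain_rate))
    stop("gain-rate calibration failed")
  # provider trend offsets
  set.seed(seed_for(config$seed, 5L))
  provs <- sort(unique(sites$provider))
  prov_off <- stats::setNames(stats::rnorm(length(provs), 0,
                                           log1p(config$provider_sd_pct / 100)), provs)
  series <- list(); truth <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    cp <- cover$mean_pct[cover$site_id == sid &
                           cover$scale == config$driving_scale] / 100
    g <- gen_time_series(sites[i, ], cp, years_by_site[[sid]],
                         prov_off[[sites$provider[i]]], config,
                         seed_for(config$seed, 6L, i))
    series[[i]] <- g$series; truth[[i]] <- g$truth
  }
  series <- if (length(series)) do.call(rbind, series) else
    data.frame(site_id = character(0), year = integer(0), abundance = numeric(0),
               richness = numeric(0), eqr = numeric(0))
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  sites$ts_length <- if (nrow(sites))
    vapply(years_by_site, function(y) max(y) - min(y), 0)[sites$site_id] else numeric(0)
  structure(list(network = network, pas = pas, sites = sites,
                 scale_polys = scale_polys, cover = cover, series = series,
                 truth = truth, provider_offsets = prov_off, config = config),
            class = "synthetic_study")
}

shrink_recent_pas <- function(pas, config, factor = 0.8) {
  recent <- which(pas$year_established >= config$year_range[1])
  for (k in recent) {
    bb <- ps_bbox(pas$ps[[k]])
    cx <- (bb[1] + bb[3]) / 2; cy <- (bb[2] + bb[4]) / 2
    w <- (bb[3] - bb[1]) * factor; h <- (bb[4] - bb[2]) * factor
    pas$ps[[k]] <- polyset(list(rect_piece(cx - w / 2, cy - h / 2,
                                           cx + w / 2, cy + h / 2)))
  }
  pas
}

#' Regenerate a study's time series under a new seed
#'
#' Keeps the geometry, sites, sampling years, and cover records fixed and
#' redraws initial EQRs, provider offsets, true slopes, and residual noise.
#' Used for replicate simulations that condition on one realized design.
#'
#' @param study a `synthetic_study`.
#' @param seed new integer seed for the series sub-streams.
#' @return the study with fresh `series`, `truth`, and `provider_offsets`.
#' @export
regen_series <- function(study, seed) {
  config <- study$config
  sites <- study$sites
  set.seed(seed_for(seed, 5L))
  provs <- sort(unique(sites$provider))
  prov_off <- stats::setNames(stats::rnorm(length(provs), 0,
                                           log1p(config$provider_sd_pct / 100)), provs)
  series <- list(); truth <- list()
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    yrs <- sort(unique(study$series$year[study$series$site_id == sid]))
    cp <- study$cover$mean_pct[study$cover$site_id == sid &
                                 study$cover$scale == config$driving_scale] / 100
    g <- gen_time_series(sites[i, ], cp, yrs, prov_off[[sites$provider[i]]],
                         config, seed_for(seed, 6L, i))
    series[[i]] <- g$series; truth[[i]] <- g$truth
  }
  study$series <- do.call(rbind, series)
  study$truth <- do.call(rbind, truth)
  study$provider_offsets <- prov_off
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d sites, %d segments, %d PAs, %d series rows>\n",
              nrow(x$sites), nrow(x$network$segments), nrow(x$pas),
              nrow(x$series)))
  invisible(x)
}
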