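# Protected-area cover per site and upstream scale.
#
# Cover is computed for the year before the first and the year before the
# last sampling year of each site's time series (a one-year lag so the
# community has time to respond), averaged into a mean percent cover, and
# differenced into a gain rate in percent per year. Cover never declines:
# the PA layer represents establishment years only, so the dissolved union
# can only grow through time.

#' Protected-area collection
#'
#' Builds a validated PA collection from polygons and establishment years.
#' Records with an unknown establishment year and point (degenerate)
#' geometries are excluded, and the exclusions are reported in the
#' `exclusions` attribute.
#'
#' @param id character vector of PA identifiers.
#' @param polygons list of polygon rings (n x 2 vertex matrices, possibly
#'   non-convex; decomposed internally) or `polyset` objects.
#' @param year_established integer vector of establishment years (`NA` =
#'   unknown, excluded).
#' @return object of class `pa_set`: data.frame with columns `id`,
#'   `year_established` and list-column `ps`.
#' @export
pa_set <- function(id, polygons, year_established) {
  stopifnot(length(id) == length(polygons), length(id) == length(year_established))
  excl <- data.frame(id = character(0), reason = character(0))
  keep <- logical(length(id))
  ps_list <- vector("list", length(id))
  for (k in seq_along(id)) {
    if (is.na(year_established[k])) {
      excl <- rbind(excl, data.frame(id = id[k], reason = "unknown_year"))
      next
    }
    p <- polygons[[k]]
    ps <- if (inherits(p, "polyset")) p else polyset(ring_to_pieces(p))
    if (ps_is_empty(ps)) {
      excl <- rbind(excl, data.frame(id = id[k], reason = "point_geometry"))
      next
    }
    keep[k] <- TRUE
    ps_list[[k]] <- ps
  }
  out <- data.frame(id = as.character(id[keep]),
                    year_established = as.integer(year_established[keep]),
                    stringsAsFactors = FALSE)
  out$ps <- ps_list[keep]
  class(out) <- c("pa_set", "data.frame")
  attr(out, "exclusions") <- excl
  out
}

#' Dissolved protected-area layer for a given year
#'
#' Union (as a `polyset`; overlap between member PAs is handled by the
#' union-aware area machinery) of all PAs established by `year`.
#'
#' @param pas a [pa_set()].
#' @param year calendar year.
#' @return a `polyset` (empty if no PA is established by `year`).
#' @export
pa_union <- function(pas, year) {
  sel <- which(pas$year_established <= year)
  if (!length(sel)) return(polyset())
  do.call(ps_bind, pas$ps[sel])
}

#' Percent of an upstream scale covered by protected areas
#'
#' @param scale_poly a `scale_polygon`.
#' @param pa_poly a `polyset` (e.g. from [pa_union()]).
#' @return percent cover in [0, 100].
#' @export
percent_cover <- function(scale_poly, pa_poly) {
  if (!inherits(scale_poly, "scale_polygon")) stop("scale_poly must be a scale_polygon")
  if (scale_poly$area_m2 <= 0) stop("zero-area scale polygon")
  if (ps_is_empty(pa_poly)) return(0)
  inter <- ps_intersect(scale_poly$ps, pa_poly)
  min(100, 100 * ps_union_area(inter) / scale_poly$area_m2)
}

#' Time-lagged protected-area cover summary for one site and scale
#'
#' Computes percent PA cover at the year before the first and the year
#' before the last sampling year, their mean, the two-point gain rate in
#' percent per year (non-negative by construction of the PA layer), and the
#' protected / gained classifications.
#'
#' @param site_id identifier.
#' @param scale_poly a `scale_polygon` for the site.
#' @param pas a [pa_set()].
#' @param first_sample_year,last_sample_year first and last sampling years of
#'   the site's time series (`last > first`).
#' @return one-row data.frame of class `cover_record` with columns `site_id`,
#'   `scale`, `pct_first`, `pct_last`, `mean_pct`, `gain_rate`, `protected`,
#'   `gained`.
#' @export
cover_summary <- function(site_id, scale_poly, pas, first_sample_year,
                          last_sample_year) {
  if (last_sample_year <= first_sample_year)
    stop("last_sample_year must exceed first_sample_year")
  y1 <- first_sample_year - 1L
  y2 <- last_sample_year - 1L
  pct_first <- percent_cover(scale_poly, pa_union(pas, y1))
  pct_last <- percent_cover(scale_poly, pa_union(pas, y2))
  gain <- max(0, (pct_last - pct_first) / (y2 - y1))
  rec <- data.frame(site_id = as.character(site_id), scale = scale_poly$scale,
                    pct_first = pct_first, pct_last = pct_last,
                    mean_pct = (pct_first + pct_last) / 2,
                    gain_rate = gain,
                    stringsAsFactors = FALSE)
  cls <- classify_site(rec)
  rec$protected <- cls$protected
  rec$gained <- cls$gained
  class(rec) <- c("cover_record", "data.frame")
  rec
}

#' Protected / gained classification of a cover record
#'
#' A site is `protected` at a scale when its mean percent cover is above
#' zero, and `gained` when its gain rate is above zero. Assignment is made
#' independently per scale.
#'
#' @param record a `cover_record` (or any data.frame with `mean_pct` and
#'   `gain_rate`).
#' @return list with logical elements `protected` and `gained`.
#' @export
classify_site <- function(record) {
  list(protected = record$mean_pct > 0, gained = record$gain_rate > 0)
}

#' Cover table across sites and scales
#'
#' @param scale_polys nested list: per site id, a named list of
#'   `scale_polygon` objects (as from [upstream_scales()]).
#' @param pas a [pa_set()].
#' @param series_range data.frame with columns `site_id`, `first_year`,
#'   `last_year`.
#' @return data.frame with one `cover_record` row per site x scale.
#' @export
cover_table <- function(scale_polys, pas, series_range) {
  rows <- list()
  for (sid in series_range$site_id) {
    rng <- series_range[series_range$site_id == sid, ]
    for (sp in scale_polys[[sid]]) {
      rows[[length(rows) + 1L]] <-
        cover_summary(sid, sp, pas, rng$first_year, rng$last_year)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
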