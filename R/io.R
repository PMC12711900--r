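# External interfaces: GeoJSON for geometry, CSV for tabular data.
#
# Coordinates are planar projected meters throughout; GeoJSON is used as a
# structural container (FeatureCollections of LineStrings / Polygons), not
# as a geographic CRS claim. Real-data users must pre-project.

ring_close <- function(m) rbind(m, m[1, , drop = FALSE])

ps_to_multipolygon <- function(ps) {
  lapply(ps$pieces, function(m) list(apply(ring_close(m), 1, as.list)))
}

coords_to_matrix <- function(cc) {
  do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' Write a river network to GeoJSON
#'
#' Segments as a FeatureCollection of LineStrings (properties `id`,
#' `downstream_id`, `length_m`, `strahler`) and, when present, drainage
#' polygons as a parallel MultiPolygon collection keyed by segment id.
#'
#' @param network a `river_network`.
#' @param path output path for the segment file.
#' @param drainage_path optional output path for the drainage file.
#' @export
write_network_geojson <- function(network, path, drainage_path = NULL) {
  seg <- network$segments
  feats <- lapply(seq_len(nrow(seg)), function(i) {
    list(type = "Feature",
         properties = list(id = seg$id[i],
                           downstream_id = if (is.na(seg$downstream_id[i])) NULL else seg$downstream_id[i],
                           length_m = seg$length_m[i],
                           strahler = if (is.null(seg$strahler)) NULL else seg$strahler[i]),
         geometry = list(type = "LineString",
                         coordinates = apply(seg$polyline[[i]], 1, as.list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(drainage_path) && !is.null(network$drainage)) {
    dfeats <- lapply(seg$id, function(id) {
      list(type = "Feature", properties = list(id = id),
           geometry = list(type = "MultiPolygon",
                           coordinates = ps_to_multipolygon(network$drainage[[id]])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = dfeats),
                         drainage_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a river network from GeoJSON
#'
#' @param path segment GeoJSON (see [write_network_geojson()]).
#' @param drainage_path optional drainage GeoJSON.
#' @return a `river_network`.
#' @export
read_network_geojson <- function(path, drainage_path = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  seg <- data.frame(
    id = vapply(feats, function(f) as.character(f$properties$id), ""),
    downstream_id = vapply(feats, function(f) {
      d <- f$properties$downstream_id
      if (is.null(d) || length(d) == 0L) NA_character_ else as.character(d)
    }, ""),
    length_m = vapply(feats, function(f) as.numeric(f$properties$length_m), 0),
    stringsAsFactors = FALSE)
  seg$polyline <- lapply(feats, function(f) coords_to_matrix(f$geometry$coordinates))
  str_ <- vapply(feats, function(f) {
    s <- f$properties$strahler
    if (is.null(s) || length(s) == 0L) NA_integer_ else as.integer(s)
  }, 0L)
  if (!anyNA(str_)) seg$strahler <- str_
  drainage <- NULL
  if (!is.null(drainage_path)) {
    dj <- jsonlite::read_json(drainage_path)
    drainage <- list()
    for (f in dj$features) {
      pieces <- unlist(lapply(f$geometry$coordinates, function(poly)
        ring_to_pieces(coords_to_matrix(poly[[1]]))), recursive = FALSE)
      drainage[[as.character(f$properties$id)]] <- polyset(pieces)
    }
  }
  river_network(seg, drainage)
}

#' Write protected areas to GeoJSON
#'
#' @param pas a [pa_set()].
#' @param path output path.
#' @export
write_pas_geojson <- function(pas, path) {
  feats <- lapply(seq_len(nrow(pas)), function(i) {
    list(type = "Feature",
         properties = list(id = pas$id[i], year_established = pas$year_established[i]),
         geometry = list(type = "MultiPolygon",
                         coordinates = ps_to_multipolygon(pas$ps[[i]])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read protected areas from GeoJSON
#'
#' Polygon and MultiPolygon features become PA records; point geometries and
#' features without an establishment year are excluded, and the loader
#' report (counts by reason) is attached as the `exclusions` attribute and
#' printed via `message()`.
#'
#' @param path PA GeoJSON with properties `id` and `year_established`.
#' @return a [pa_set()].
#' @export
read_pas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  ids <- character(0); yrs <- integer(0); polys <- list()
  n_point <- 0L
  for (f in feats) {
    ids <- c(ids, as.character(f$properties$id))
    y <- f$properties$year_established
    yrs <- c(yrs, if (is.null(y)) NA_integer_ else as.integer(y))
    gt <- f$geometry$type
    polys[[length(polys) + 1L]] <- switch(
      gt,
      Polygon = polyset(ring_to_pieces(coords_to_matrix(f$geometry$coordinates[[1]]))),
      MultiPolygon = polyset(unlist(lapply(f$geometry$coordinates, function(poly)
        ring_to_pieces(coords_to_matrix(poly[[1]]))), recursive = FALSE)),
      { n_point <- n_point + 1L; polyset() })
  }
  out <- pa_set(ids, polys, yrs)
  excl <- attr(out, "exclusions")
  if (nrow(excl))
    message("excluded ", sum(excl$reason == "unknown_year"),
            " PA(s) with unknown establishment year and ",
            sum(excl$reason == "point_geometry"), " point-geometry PA(s)")
  out
}

#' Write scale polygons to GeoJSON for inspection
#'
#' @param scale_polys list of `scale_polygon` objects.
#' @param path output path.
#' @export
write_scales_geojson <- function(scale_polys, path) {
  feats <- lapply(scale_polys, function(sp) {
    list(type = "Feature",
         properties = list(site_id = sp$site_id, scale = sp$scale,
                           area_km2 = sp$area_km2),
         geometry = list(type = "MultiPolygon",
                         coordinates = ps_to_multipolygon(sp$ps)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write all study inputs (and truth) to a directory
#'
#' Emits the exact input formats the pipeline consumes: network and drainage
#' GeoJSON, PA GeoJSON, sites CSV, series CSV, plus `truth.csv` for
#' synthetic studies.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_geojson(study$network, file.path(dir, "network.geojson"),
                        file.path(dir, "drainage.geojson"))
  write_pas_geojson(study$pas, file.path(dir, "pas.geojson"))
  utils::write.csv(study$sites[, c("site_id", "segment_id", "offset_m",
                                   "latitude", "longitude", "provider")],
                   file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(study$series, file.path(dir, "series.csv"), row.names = FALSE)
  if (!is.null(study$truth))
    utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read study inputs from a directory
#'
#' @param dir directory written by [write_study()] (or hand-assembled in the
#'   same layout).
#' @return list with `network`, `pas`, `sites`, `series`.
#' @export
read_study_inputs <- function(dir) {
  list(network = read_network_geojson(file.path(dir, "network.geojson"),
                                      file.path(dir, "drainage.geojson")),
       pas = read_pas_geojson(file.path(dir, "pas.geojson")),
       sites = utils::read.csv(file.path(dir, "sites.csv"),
                               stringsAsFactors = FALSE),
       series = utils::read.csv(file.path(dir, "series.csv"),
                                stringsAsFactors = FALSE))
}
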