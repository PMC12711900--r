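# Pipeline orchestration.
#
# A run configuration either points at input files or embeds a generator
# configuration; the pipeline validates inputs against the inclusion
# criteria, delineates upstream scales, computes lagged PA cover, estimates
# per-site trends, runs both analysis sets across every metric x scale, and
# returns (optionally writes) the result tables with run metadata.

#' Run configuration
#'
#' @param generator a [generator_config()] (synthetic run), or `NULL` when
#'   `input_dir` is given.
#' @param input_dir directory of study inputs (see [read_study_inputs()]).
#' @param scales upstream scales to analyse.
#' @param log_policies per-metric [safe_log()] policies.
#' @param criterion `"REML"` or `"ML"` for trend fits.
#' @param alpha significance threshold on adjusted p-values.
#' @param min_n_smooth minimum subset size for smooth models.
#' @param size_method `"pixel"` (90-m pixel counting, the default) or
#'   `"exact"` for upstream catchment size.
#' @param out_dir optional output directory for result CSVs.
#' @param seed integer seed (overrides the generator's).
#' @return a `run_config` list.
#' @export
run_config <- function(generator = generator_config(), input_dir = NULL,
                       scales = c("1km", "10km", "100km", "full"),
                       log_policies = default_log_policies(),
                       criterion = "REML", alpha = 0.05, min_n_smooth = 30,
                       size_method = "pixel", out_dir = NULL, seed = NULL) {
  stopifnot(length(scales) >= 1L, alpha > 0, alpha < 1)
  if (!is.null(seed) && !is.null(generator)) generator$seed <- as.integer(seed)
  cfg <- list(generator = generator, input_dir = input_dir, scales = scales,
              log_policies = log_policies, criterion = criterion, alpha = alpha,
              min_n_smooth = min_n_smooth, size_method = size_method,
              out_dir = out_dir, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of the decisions in force for a run
#'
#' @param config a `run_config`.
#' @return character hash; changes whenever any analysis-relevant option
#'   changes.
#' @export
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Validate study inputs against the inclusion criteria
#'
#' Excludes (with reasons) time series spanning fewer than 10 years or with
#' fewer than 7 sampling years, and rejects structurally invalid rows:
#' negative counts, missing EQR, sites on unknown segments.
#'
#' @param series community series data.frame (`site_id`, `year`,
#'   `abundance`, `richness`, `eqr`).
#' @param sites site table (`site_id`, `segment_id`, ...).
#' @param network optional `river_network` for segment checks.
#' @param min_span,min_years inclusion thresholds (years).
#' @return list with `series` (included rows), `sites` (included sites), and
#'   `exclusions` (site_id, reason).
#' @export
validate_inputs <- function(series, sites, network = NULL,
                            min_span = 10, min_years = 7) {
  bad_rows <- which(series$abundance < 0 | series$richness < 0)
  if (length(bad_rows))
    stop("negative counts in series row(s): ",
         paste(utils::head(bad_rows, 5), collapse = ", "))
  excl <- data.frame(site_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- character(0)
  for (sid in unique(series$site_id)) {
    ss <- series[series$site_id == sid, ]
    reason <- NULL
    if (anyNA(ss$eqr)) reason <- "missing_eqr"
    else if (length(unique(ss$year)) < min_years) reason <- "min_sampling_years"
    else if (max(ss$year) - min(ss$year) < min_span) reason <- "min_span"
    else if (!is.null(network) && sid %in% sites$site_id &&
             !(sites$segment_id[sites$site_id == sid] %in% network$segments$id))
      reason <- "unknown_segment"
    if (is.null(reason)) keep <- c(keep, sid)
    else excl <- rbind(excl, data.frame(site_id = sid, reason = reason))
  }
  list(series = series[series$site_id %in% keep, ],
       sites = sites[sites$site_id %in% keep, ],
       exclusions = excl)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configuration: generates or loads the study,
#' validates it, computes scales, cover, and trends, and fits both analysis
#' sets over every metric x scale. Stage timings and counts are logged to
#' `message()`.
#'
#' @param config a [run_config()].
#' @param study optionally, a pre-built `synthetic_study` (skips generation).
#' @return object of class `result_bundle`: list with `cover`, `trends`,
#'   `group` (tests + means), `smooth` (tests + curves), `sizes`,
#'   `exclusions`, and `meta`.
#' @export
run_pipeline <- function(config, study = NULL) {
  t0 <- proc.time()[3]
  stage <- function(name, expr) {
    ts <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[riverpa] %-12s %6.1fs", name, proc.time()[3] - ts))
    out
  }
  if (is.null(study)) {
    study <- stage("inputs", {
      if (!is.null(config$input_dir)) {
        inp <- read_study_inputs(config$input_dir)
        net <- if (is.null(inp$network$segments$strahler))
          compute_strahler(inp$network) else inp$network
        sp <- list()
        for (i in seq_len(nrow(inp$sites))) {
          pos <- site_position(inp$sites$site_id[i], inp$sites$segment_id[i],
                               inp$sites$offset_m[i])
          sp[[inp$sites$site_id[i]]] <- upstream_scales(net, pos,
                                                        scales = config$scales)
        }
        sites <- inp$sites
        yrs <- tapply(inp$series$year, inp$series$site_id, function(y) max(y) - min(y))
        sites$ts_length <- as.numeric(yrs[sites$site_id])
        list(network = net, pas = inp$pas, sites = sites, scale_polys = sp,
             series = inp$series, cover = NULL, truth = NULL)
      } else {
        gen_study(config$generator)
      }
    })
  }
  val <- stage("validate", validate_inputs(study$series, study$sites, study$network))
  sites <- val$sites
  series_range <- do.call(rbind, lapply(split(val$series, val$series$site_id),
    function(ss) data.frame(site_id = ss$site_id[1], first_year = min(ss$year),
                            last_year = max(ss$year), stringsAsFactors = FALSE)))
  cover <- stage("cover", {
    cv <- if (!is.null(study$cover)) study$cover
          else cover_table(study$scale_polys, study$pas, series_range)
    cv[cv$site_id %in% sites$site_id & cv$scale %in% config$scales, ]
  })
  trends <- stage("trends", trend_table(val$series,
                                        policies = config$log_policies,
                                        method = config$criterion))
  sizes <- stage("sizes", data.frame(
    site_id = sites$site_id,
    size_km2 = vapply(sites$site_id, function(sid)
      area_km2(study$scale_polys[[sid]][["full"]], method = config$size_method),
      0),
    stringsAsFactors = FALSE))
  covars <- sites[, c("site_id", "latitude", "longitude", "ts_length", "provider")]
  group <- stage("group", run_group_models(trends, cover, covars,
                                           scales = config$scales,
                                           alpha = config$alpha))
  smooth <- stage("smooth", run_smooth_models(trends, cover, covars, sizes,
                                              scales = config$scales,
                                              alpha = config$alpha,
                                              min_n = config$min_n_smooth))
  meta <- list(config_hash = config_hash(config), scales = config$scales,
               n_sites = nrow(sites), n_excluded = nrow(val$exclusions),
               alpha = config$alpha, criterion = config$criterion,
               elapsed_s = unname(proc.time()[3] - t0),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  bundle <- structure(list(cover = cover, trends = trends, group = group,
                           smooth = smooth, sizes = sizes,
                           exclusions = val$exclusions, meta = meta,
                           study = study),
                      class = "result_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle: %d sites (%d excluded), %d group tests, %d smooth tests>\n",
              x$meta$n_sites, x$meta$n_excluded,
              if (is.null(x$group$tests)) 0L else nrow(x$group$tests),
              if (is.null(x$smooth$tests)) 0L else nrow(x$smooth$tests)))
  cat("  config hash:", x$meta$config_hash, "\n")
  invisible(x)
}

#' Write result tables to a directory
#'
#' One CSV per table, each carrying the config hash in a `config_hash`
#' column for traceability.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- bundle$meta$config_hash
  wr <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    df$config_hash <- h
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(bundle$cover, "cover.csv")
  wr(bundle$trends, "trends.csv")
  wr(bundle$group$tests, "group_tests.csv")
  wr(bundle$group$means, "group_means.csv")
  wr(bundle$smooth$tests, "smooth_tests.csv")
  wr(bundle$smooth$curves, "effect_curves.csv")
  wr(bundle$sizes, "sizes.csv")
  wr(bundle$exclusions, "exclusions.csv")
  jsonlite::write_json(bundle$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
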