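# Boundary and table I/O. Boundaries are read and written as GeoJSON
# (WGS84 lon/lat; GeoJSON's only CRS). All tables are plain CSV with
# lon, lat column order and distances in km throughout.

#' Read district boundaries from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features. The
#' district id is taken from the property named by `id_field` (falling
#' back to `id`, then the feature index); the display name from
#' `name_field` when present. Geometry validity and pairwise
#' interior-disjointness are enforced; rings are auto-closed and
#' degenerate vertices dropped.
#'
#' @param path Path to a GeoJSON file.
#' @param id_field,name_field Property names for district id and name.
#' @return A [district_map()].
#' @export
read_boundaries <- function(path, id_field = "district_id",
                            name_field = "name") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) &&
      !grepl("CRS84|4326", crs_name, ignore.case = TRUE))
    stop("boundaries must be in geographic WGS84 coordinates (got CRS ",
         crs_name, ")")
  feats <- gj$features
  ids <- character(length(feats))
  nms <- character(length(feats))
  polys <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("feature ", i, ": non-polygonal geometry (",
           if (is.null(g$type)) "missing" else g$type, ")")
    props <- f$properties
    id <- props[[id_field]]
    if (is.null(id)) id <- props[["id"]]
    if (is.null(id)) id <- f[["id"]]
    if (is.null(id))
      stop("feature ", i, ": no '", id_field, "' or 'id' property")
    ids[i] <- as.character(id)
    nm <- props[[name_field]]
    nms[i] <- if (is.null(nm)) ids[i] else as.character(nm)
    coords <- g$coordinates
    if (g$type == "Polygon") coords <- list(coords)
    polys[[i]] <- lapply(coords, function(part)
      lapply(part, function(ring)
        do.call(rbind, lapply(ring, function(pt)
          c(lon = pt[[1]], lat = pt[[2]])))))
  }
  district_map(ids, polys, name = nms)
}

#' Write district boundaries to GeoJSON
#'
#' @param map A [district_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(map, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  feats <- lapply(seq_along(map$district_id), function(i) {
    parts <- lapply(map$polygons[[i]], function(part)
      lapply(part, function(ring) unname(close_ring(ring))))
    list(type = "Feature",
         properties = list(district_id = map$district_id[i],
                           name = map$name[i]),
         geometry = list(type = "MultiPolygon", coordinates = parts))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an indicator record table from CSV
#'
#' Expected columns: `cluster_id`, `record_id`, `indicator`, `y`
#' (0/1/empty), `weight`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of indicator records.
#' @export
read_indicators <- function(path) {
  ind <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster_id", "record_id", "indicator", "y", "weight")
  miss <- setdiff(need, names(ind))
  if (length(miss))
    stop("indicator table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(ind$y %in% c(0, 1, NA)))
    stop("indicator y values must be 0, 1 or missing")
  ind
}

#' Run the full assignment-and-estimation pipeline
#'
#' Assigns clusters by each requested method, estimates district coverage
#' per indicator, tabulates cluster counts, and (when a truth or reference
#' estimate table is supplied) computes CCC agreement per method and
#' indicator. Deterministic given `config$seed`. When `out_dir` is given,
#' writes one CSV per table plus a `run_metadata.json` echoing the seed
#' and configuration.
#'
#' @param boundaries A [district_map()] or path to a GeoJSON file.
#' @param clusters Cluster table (data.frame) or path to CSV.
#' @param indicators Indicator table (data.frame) or path to CSV.
#' @param methods Subset of `c("A", "B", "C")`.
#' @param config A [sim_config()].
#' @param merge,exclude Passed to [merge_districts()] when non-empty.
#' @param level,ci,singleton Passed to [estimate_coverage()].
#' @param snap_km Method-C snap tolerance.
#' @param reference Optional reference estimates (`district_estimates` or
#'   data.frame with `district_id`, `indicator`, `p_hat`) to compare each
#'   method against, e.g. validated-truth estimates.
#' @param out_dir Optional output directory.
#' @return A list: `assignments`, `estimates`, `counts` (per method),
#'   `agreement` (or NULL), `map`.
#' @export
run_pipeline <- function(boundaries, clusters, indicators,
                         methods = c("A", "B", "C"),
                         config = sim_config(),
                         merge = character(), exclude = character(),
                         level = 0.95, ci = "logit",
                         singleton = "centered", snap_km = 0.5,
                         reference = NULL, out_dir = NULL) {
  map <- if (inherits(boundaries, "district_map")) boundaries
         else read_boundaries(boundaries)
  if (length(merge) || length(exclude))
    map <- merge_districts(map, merge = merge, exclude = exclude)
  if (is.character(clusters)) clusters <- read_clusters(clusters)
  else clusters <- validate_clusters(clusters)
  if (is.character(indicators)) indicators <- read_indicators(indicators)
  methods <- match.arg(methods, c("A", "B", "C"), several.ok = TRUE)

  res <- list(assignments = list(), estimates = list(), counts = list(),
              agreement = NULL, map = map)
  for (m in methods) {
    asg <- tryCatch(
      assign_clusters(clusters, map, method = m, config = config,
                      snap_km = snap_km),
      error = function(e) stop("stage assign[", m, "]: ",
                               conditionMessage(e)))
    est <- tryCatch(
      estimate_coverage(indicators, asg, clusters, level = level, ci = ci,
                        singleton = singleton),
      error = function(e) stop("stage estimate[", m, "]: ",
                               conditionMessage(e)))
    res$assignments[[m]] <- asg
    res$estimates[[m]] <- est
    res$counts[[m]] <- count_clusters_per_district(asg)
  }
  if (!is.null(reference)) {
    agr <- lapply(methods, function(m) {
      a <- agreement(res$estimates[[m]], reference, level = level)
      cbind(method = m, a)
    })
    res$agreement <- do.call(rbind, agr)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in methods) {
      utils::write.csv(as.data.frame(res$assignments[[m]]),
                       file.path(out_dir, paste0("assignments_", m, ".csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(res$estimates[[m]]),
                       file.path(out_dir, paste0("estimates_", m, ".csv")),
                       row.names = FALSE)
      utils::write.csv(res$counts[[m]],
                       file.path(out_dir, paste0("cluster_counts_", m, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(res$agreement))
      utils::write.csv(res$agreement, file.path(out_dir, "agreement.csv"),
                       row.names = FALSE)
    meta <- list(
      package = "geomaskr",
      version = as.character(utils::packageVersion("geomaskr")),
      seed = config$seed,
      config = unclass(config),
      methods = methods, level = level, ci = ci, singleton = singleton,
      merge = as.list(merge), exclude = exclude
    )
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
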