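# Synthetic geography and DHS-like survey with known truth.
#
# The generator emulates the structure the assignment methods face in a
# real pre-2009 DHS: a country partitioned into districts of varying area,
# clusters sampled within districts and stratified by urban/rural, binary
# indicators with district-level prevalence plus cluster-level
# heterogeneity on the logit scale, eligibility thinning that reproduces
# the precision hierarchy (all households report water source; only
# ~70% have an under-5 child for stunting; only ~12% have an infant 0-5
# months for exclusive breastfeeding), and geomask displacement of the
# released cluster coordinates.

#' Synthetic survey configuration
#'
#' @param grid_nx,grid_ny District grid dimensions.
#' @param cell_km District edge length in km; a vector is recycled over
#'   grid rows so row heights (hence areas) vary, mimicking the wide
#'   ADM2 area spread of real countries. Cell width is `mean(cell_km)`.
#' @param clusters_per_district Clusters sampled per district.
#' @param households_per_cluster Household records per cluster.
#' @param urban_fraction Probability a cluster is urban.
#' @param prevalence Optional named list, indicator -> numeric vector of
#'   true district prevalences (length = number of districts, row-major
#'   order). Defaults draw district prevalences uniformly from
#'   indicator-specific ranges: water (0.05, 0.6), stunting (0.3, 0.65),
#'   breastfeeding (0.2, 0.7).
#' @param cluster_sd Logit-scale between-cluster SD of prevalence.
#' @param missing_rate Per-record missingness probability per indicator.
#' @param p_child,p_infant Household eligibility rates for the child-level
#'   (stunting-like) and infant-level (breastfeeding-like) indicators.
#' @param hh_density Households per km^2, used to form district sampling
#'   fractions and hence weights.
#' @param origin_lon,origin_lat Southwest corner of the synthetic country.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_nx = 5, grid_ny = 5, cell_km = 30,
                             clusters_per_district = 20,
                             households_per_cluster = 25,
                             urban_fraction = 0.25,
                             prevalence = NULL,
                             cluster_sd = 0.3, missing_rate = 0,
                             p_child = 0.7, p_infant = 0.12,
                             hh_density = 40,
                             origin_lon = 34, origin_lat = -15,
                             seed = 1L) {
  stopifnot(grid_nx >= 1, grid_ny >= 1, all(cell_km > 0),
            clusters_per_district >= 1, households_per_cluster >= 1,
            urban_fraction >= 0, urban_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(
    list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
         cell_km = cell_km,
         clusters_per_district = as.integer(clusters_per_district),
         households_per_cluster = as.integer(households_per_cluster),
         urban_fraction = urban_fraction, prevalence = prevalence,
         cluster_sd = cluster_sd, missing_rate = missing_rate,
         p_child = p_child, p_infant = p_infant, hh_density = hh_density,
         origin_lon = origin_lon, origin_lat = origin_lat,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

KM_PER_DEG_LAT <- EARTH_RADIUS_KM * pi / 180

#' Generate a synthetic country
#'
#' A `grid_nx` x `grid_ny` grid of rectangular districts in lon/lat,
#' interior-disjoint and tiling a rectangle anchored at the configured
#' origin. Row heights follow `cell_km`, so district areas can span a wide
#' range.
#'
#' @param config A [synthetic_config()].
#' @return A [district_map()] with ids `D01`, `D02`, ... in row-major
#'   order from the southwest corner.
#' @export
generate_country <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  heights_km <- rep_len(config$cell_km, config$grid_ny)
  width_km <- mean(config$cell_km)
  dlat <- heights_km / KM_PER_DEG_LAT
  dlon <- width_km / (KM_PER_DEG_LAT * cos(config$origin_lat * pi / 180))
  lat_edges <- config$origin_lat + cumsum(c(0, dlat))
  lon_edges <- config$origin_lon + (0:config$grid_nx) * dlon
  n <- config$grid_nx * config$grid_ny
  ids <- sprintf("D%0*d", max(2, nchar(n)), seq_len(n))
  polys <- vector("list", n)
  k <- 0
  for (iy in seq_len(config$grid_ny)) {
    for (ix in seq_len(config$grid_nx)) {
      k <- k + 1
      polys[[k]] <- cbind(
        lon = lon_edges[c(ix, ix + 1, ix + 1, ix)],
        lat = lat_edges[c(iy, iy, iy + 1, iy + 1)]
      )
    }
  }
  district_map(ids, polys)
}

default_prevalence_ranges <- list(
  water = c(0.05, 0.60),
  stunting = c(0.30, 0.65),
  breastfeeding = c(0.20, 0.70)
)

# sample one point uniformly inside a district geometry (rejection in bbox)
sample_point_in_geom <- function(geom) {
  bb <- geom_bbox(geom)
  for (i in 1:10000) {
    p <- c(stats::runif(1, bb[1], bb[3]), stats::runif(1, bb[2], bb[4]))
    if (point_in_geom(geom, p[1], p[2])) return(p)
  }
  stop("failed to sample a point inside the district geometry")
}

#' Generate a synthetic survey with known truth
#'
#' Samples cluster locations uniformly within districts, marks clusters
#' urban/rural, assigns district x urban/rural strata and weights equal to
#' the inverse within-district sampling fraction, and simulates household
#' indicator records: y ~ Bernoulli(invlogit(logit(prev_district) + u)),
#' with a Normal(0, cluster_sd^2) cluster effect u, per-indicator
#' eligibility thinning and optional missingness.
#'
#' @param map A [district_map()] (typically from [generate_country()]).
#' @param config A [synthetic_config()].
#' @return A list with `clusters` (cluster table with *true* locations and
#'   `true_district`), `indicators` (long record table: `cluster_id`,
#'   `record_id`, `indicator`, `y`, `weight`), and `truth` (district
#'   prevalence table).
#' @export
generate_survey <- function(map, config) {
  stopifnot(inherits(map, "district_map"), inherits(config, "synthetic_config"))
  ids <- map$district_id
  nd <- length(ids)
  with_seed(derive_seed(config$seed, "synthetic-survey"), {
    prev <- config$prevalence
    if (is.null(prev)) {
      prev <- lapply(default_prevalence_ranges, function(rg)
        stats::runif(nd, rg[1], rg[2]))
    }
    stopifnot(all(vapply(prev, length, 1L) == nd))
    indicators <- names(prev)
    elig <- c(1, config$p_child, config$p_infant)[
      seq_along(indicators)]  # first indicator is household-level
    names(elig) <- indicators

    cl_rows <- list(); ind_rows <- list()
    cid <- 0
    for (d in seq_len(nd)) {
      area <- polygon_area_km2(map$polygons[[d]])
      n_hh_sampled <- config$clusters_per_district *
        config$households_per_cluster
      weight_d <- max(config$hh_density * area, n_hh_sampled) / n_hh_sampled
      for (j in seq_len(config$clusters_per_district)) {
        cid <- cid + 1
        p <- sample_point_in_geom(map$polygons[[d]])
        urban <- stats::runif(1) < config$urban_fraction
        cluster_id <- sprintf("C%05d", cid)
        cl_rows[[cid]] <- data.frame(
          cluster_id = cluster_id, lon = p[1], lat = p[2], urban = urban,
          stratum_id = paste0(ids[d], ":", if (urban) "urban" else "rural"),
          weight = weight_d, true_district = ids[d]
        )
        nh <- config$households_per_cluster
        for (ind in indicators) {
          u <- stats::rnorm(1, 0, config$cluster_sd)
          eligible <- stats::runif(nh) < elig[ind]
          ne <- sum(eligible)
          if (ne == 0) next
          p_c <- stats::plogis(stats::qlogis(prev[[ind]][d]) + u)
          y <- as.numeric(stats::runif(ne) < p_c)
          if (config$missing_rate > 0)
            y[stats::runif(ne) < config$missing_rate] <- NA
          ind_rows[[length(ind_rows) + 1]] <- data.frame(
            cluster_id = cluster_id,
            record_id = paste0(cluster_id, ":", ind, ":",
                               which(eligible)),
            indicator = ind, y = y, weight = weight_d
          )
        }
      }
    }
    truth <- data.frame(
      district_id = rep(ids, length(indicators)),
      indicator = rep(indicators, each = nd),
      prevalence = unlist(prev, use.names = FALSE)
    )
    list(clusters = do.call(rbind, cl_rows),
         indicators = do.call(rbind, ind_rows),
         truth = truth)
  })
}

#' Apply the geomask to true cluster locations
#'
#' Displaces each cluster once under the geomask model (uniform distance
#' up to the urban/rural cap, uniform bearing). With
#' `constrain_within_district = TRUE` the post-2009 DHS protocol is
#' emulated: displacements are redrawn until the released point stays in
#' the cluster's true district (up to 1000 redraws).
#'
#' The DHS protocol has always kept displaced coordinates inside the
#' country; with `constrain_within_country = TRUE` (the default whenever a
#' map is supplied) displacements are likewise redrawn until the released
#' point lies in some district of the map.
#'
#' @param clusters Cluster table with true `lon`/`lat` (and
#'   `true_district` when constraining).
#' @param config A [sim_config()] supplying caps and seed.
#' @param map A [district_map()]; required when constraining.
#' @param constrain_within_district Keep displacements within the true
#'   district.
#' @param constrain_within_country Keep displacements within the union of
#'   districts.
#' @return The cluster table with `lon`/`lat` replaced by the geomasked
#'   coordinates and the originals kept as `true_lon`/`true_lat`.
#' @export
apply_geomask <- function(clusters, config = sim_config(), map = NULL,
                          constrain_within_district = FALSE,
                          constrain_within_country = !is.null(map)) {
  stopifnot(inherits(config, "sim_config"))
  if (constrain_within_district &&
      (is.null(map) || is.null(clusters$true_district)))
    stop("constraining requires a map and a true_district column")
  if (constrain_within_country && is.null(map))
    stop("constraining within the country requires a map")
  out <- clusters
  out$true_lon <- clusters$lon
  out$true_lat <- clusters$lat
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    d_max <- if (as.logical(cl$urban)) config$d_max_urban_km else
      config$d_max_rural_km
    pt <- with_seed(derive_seed(config$seed, paste0("mask:", cl$cluster_id)), {
      for (try in 1:1000) {
        dr <- draw_displacement(1, d_max, area_uniform = config$area_uniform)
        p <- offset_point(cl$lon, cl$lat, dr$bearing, dr$distance)
        if (constrain_within_district) {
          if (identical(locate_point(map, p$lon, p$lat),
                        as.character(cl$true_district))) break
        } else if (constrain_within_country) {
          if (!is.na(locate_point(map, p$lon, p$lat))) break
        } else break
        p <- NULL
      }
      p
    })
    if (is.null(pt))
      stop("redraw cap exceeded for cluster '", cl$cluster_id, "'")
    out$lon[i] <- pt$lon
    out$lat[i] <- pt$lat
  }
  out
}

#' Assignment from known true districts
#'
#' Wraps a synthetic cluster table's `true_district` column as a
#' `district_assignment`, so validated-truth estimates can be computed
#' with the same estimation path as methods A/B/C.
#'
#' @param clusters Cluster table with `cluster_id` and `true_district`.
#' @return A `district_assignment` with method `"truth"`.
#' @export
assignment_from_truth <- function(clusters) {
  out <- data.frame(cluster_id = as.character(clusters$cluster_id),
                    district_id = as.character(clusters$true_district),
                    proportion = 1)
  structure(out, method = "truth",
            class = c("district_assignment", "data.frame"))
}
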